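test_that("floor-and-log maps 0 -> 0, 1024 -> 10, sub-1 values -> 0", {
  tab <- make_tiny_table(matrix(c(0, 1024, 0.3, 7,
                                  2, 1, 0.99, 4096), 2, 4, byrow = TRUE),
                         labels = c(0, 1))
  out <- floor_and_log(tab)
  expect_equal(unname(out$intensities[1, ]), c(0, 10, 0, log2(7)))
  expect_equal(unname(out$intensities[2, ]), c(1, 0, 0, 12))
  expect_true(all(out$intensities >= 0))
  # applied once only: the provenance flag blocks a second application
  expect_error(floor_and_log(out), "already been applied")
  # and the composition would not be idempotent: log2 of a log2 value
  # differs whenever the first pass yields values above 1
  expect_false(isTRUE(all.equal(log2(pmax(out$intensities, 1)),
                                out$intensities)))
  expect_error(floor_and_log(make_tiny_table(matrix(c(-1, 2), 1, 2),
                                             labels = 0)),
               "non-negative")
})

test_that("percentile scores match the mean-rank oracle", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    p <- sample(2:6, 1)
    x <- matrix(sample(1:8, n * p, replace = TRUE) * 1.0, n, p)  # many ties
    labels <- c(0, 0, sample(0:1, n - 2, replace = TRUE))
    tab <- make_tiny_table(x, labels = labels)
    norm <- percentile_normalize(tab)
    ctrl <- which(labels == 0)
    for (j in seq_len(p)) {
      expected <- vapply(x[, j], oracle_percentile, numeric(1), x[ctrl, j])
      expect_equal(unname(norm$values[, j]), expected)
    }
  }
})

test_that("percentile normalization follows the control-distribution conventions", {
  # query 2.5 against controls (1,2,3,4) scores 50; above all -> 100, below all -> 0
  x <- matrix(c(1, 2, 3, 4, 2.5, 9, 0.5), 7, 1)
  tab <- make_tiny_table(x, labels = c(0, 0, 0, 0, 1, 1, 1))
  norm <- percentile_normalize(tab)
  expect_equal(unname(norm$values[5:7, 1]), c(50, 100, 0))
  # all controls tied: a query equal to them scores 50
  x2 <- matrix(c(3, 3, 3, 3, 7), 5, 1)
  norm2 <- percentile_normalize(make_tiny_table(x2, labels = c(0, 0, 0, 0, 1)))
  expect_equal(unname(norm2$values[, 1]), c(50, 50, 50, 50, 100))
  # distinct control values self-score with mean exactly 50
  set.seed(2)
  x3 <- matrix(rnorm(40), 20, 2)
  norm3 <- percentile_normalize(make_tiny_table(x3, labels = rep(0:1, 10)))
  expect_equal(colMeans(norm3$values[rep(0:1, 10) == 0, ]), c(ft01 = 50, ft02 = 50),
               tolerance = 1e-9)
  expect_true(all(norm3$values >= 0 & norm3$values <= 100))
})

test_that("percentile normalization is invariant to strictly increasing transforms", {
  set.seed(4)
  x <- matrix(rexp(60 * 8), 60, 8)
  labels <- rep(c(0, 1), 30)
  batches <- rep(c("A", "B"), each = 30)
  t1 <- make_tiny_table(x, labels = labels, batches = batches)
  t2 <- make_tiny_table(exp(3 * x) + 5, labels = labels, batches = batches)
  expect_identical(percentile_normalize(t1)$values,
                   percentile_normalize(t2)$values)
})

test_that("batches are normalized separately and small control counts error", {
  set.seed(6)
  x <- matrix(rnorm(40 * 3, mean = rep(c(0, 5), each = 20)), 40, 3)
  labels <- rep(rep(c(0, 1), each = 10), 2)
  batches <- rep(c("b1", "b2"), each = 20)
  tab <- make_tiny_table(x, labels = labels, batches = batches)
  per_batch <- percentile_normalize(tab)
  pooled <- percentile_normalize(tab, per_batch = FALSE)
  expect_false(identical(per_batch$values, pooled$values))
  # batch offsets vanish after per-batch normalization: control means are 50
  # in both batches despite the shifted second batch
  for (b in c("b1", "b2")) {
    rows <- batches == b & labels == 0
    expect_equal(unname(colMeans(per_batch$values[rows, ])), rep(50, 3))
  }
  bad <- make_tiny_table(x, labels = c(0, rep(1, 19), labels[21:40]),
                         batches = batches)
  expect_error(percentile_normalize(bad), "batch 'b1'")
  expect_error(percentile_normalize(per_batch), "feature_table")
})

test_that("prevalence filter keeps features detected in more than the cutoff", {
  x <- matrix(0, 100, 3)
  x[1, 1] <- 10          # 1% of samples
  x[1:6, 2] <- 10        # 6% of samples
  x[, 3] <- 0            # never detected
  tab <- make_tiny_table(x, labels = rep(c(0, 1), 50))
  kept <- prevalence_filter(tab, 0.05)
  expect_equal(kept$features$feature_id, "ft02")
  # min_fraction 0 drops only all-missing features
  kept0 <- prevalence_filter(tab, 0)
  expect_equal(kept0$features$feature_id, c("ft01", "ft02"))
})

test_that("dataset combination concatenates features over shared samples", {
  set.seed(9)
  ids <- sprintf("s%02d", 1:12)
  t1 <- feature_table(matrix(runif(12 * 4, 1, 10), 12, 4),
                      labels = rep(c(0, 1), 6),
                      features = data.frame(feature_id = paste0("a", 1:4),
                                            mz = 100 + 1:4, rt = 1:4 * 10),
                      sample_ids = ids)
  t2 <- feature_table(matrix(runif(10 * 6, 1, 10), 10, 6),
                      labels = rep(c(0, 1), 5),
                      features = data.frame(feature_id = paste0("b", 1:6),
                                            mz = 200 + 1:6, rt = 1:6 * 10),
                      sample_ids = ids[1:10])
  comb <- combine_datasets(list(pos = t1, neg = t2))
  expect_equal(dim(comb), c(10L, 10L))
  expect_true(all(startsWith(comb$features$feature_id[1:4], "pos_")))
  # single table is the identity
  expect_identical(combine_datasets(list(t1)), t1)
  # label conflict errors with the offending sample id
  t3 <- t2
  t3$labels[1] <- 1L - t3$labels[1]
  expect_error(combine_datasets(list(t1, t3)), "conflicting labels")
  t4 <- t2
  t4$sample_ids <- paste0("x", t4$sample_ids)
  rownames(t4$intensities) <- t4$sample_ids
  expect_error(combine_datasets(list(t1, t4)), "no shared sample ids")
})

test_that("one-vs-one expansion produces all pairwise binary tables", {
  set.seed(10)
  mk <- function(k, n_per) {
    make_tiny_table(matrix(runif(k * n_per * 3, 1, 10), k * n_per, 3),
                    labels = rep(seq_len(k) - 1, each = n_per))
  }
  expect_length(one_vs_one_splits(mk(3, 4)), 3)
  expect_length(one_vs_one_splits(mk(5, 2)), 10)
  two <- one_vs_one_splits(mk(2, 4))
  expect_length(two, 1)
  expect_equal(two[[1]]$labels, rep(c(0L, 1L), each = 4))
  splits <- one_vs_one_splits(mk(3, 4))
  expect_named(splits, c("0_vs_1", "0_vs_2", "1_vs_2"))
  expect_equal(unique(splits[["1_vs_2"]]$labels), c(0L, 1L))
  expect_equal(nrow(splits[["1_vs_2"]]$intensities), 8)
  expect_error(one_vs_one_splits(mk(1, 4)), "single class")
})

test_that("replicate dropping keeps one deterministic sample per individual", {
  x <- matrix(1:12 * 1.0, 6, 2)
  tab <- make_tiny_table(x, labels = c(0, 0, 0, 1, 1, 1))
  map <- c(s01 = "p1", s02 = "p1", s03 = "p1", s04 = "p2", s05 = "p3",
           s06 = "p3")
  out <- drop_replicates(tab, map)
  expect_equal(out$sample_ids, c("s01", "s04", "s05"))
  expect_identical(drop_replicates(tab, map), out)
  # all-distinct individuals: identity on rows
  map2 <- setNames(paste0("q", 1:6), tab$sample_ids)
  expect_equal(drop_replicates(tab, map2)$sample_ids, tab$sample_ids)
  expect_error(drop_replicates(tab, map[1:3]), "replicate_map")
})

test_that("combine-then-split commutes with split-then-combine on shared samples", {
  set.seed(12)
  ids <- sprintf("s%02d", 1:18)
  labs <- rep(0:2, each = 6)
  mk <- function(prefix, p) {
    feature_table(matrix(runif(18 * p, 1, 10), 18, p), labels = labs,
                  features = data.frame(feature_id = paste0(prefix, 1:p),
                                        mz = 100 + 1:p, rt = 1:p * 5),
                  sample_ids = ids)
  }
  t1 <- mk("a", 3); t2 <- mk("b", 4)
  a <- one_vs_one_splits(combine_datasets(list(d1 = t1, d2 = t2)))
  b <- lapply(seq_along(a), function(i) {
    combine_datasets(list(d1 = one_vs_one_splits(t1)[[i]],
                          d2 = one_vs_one_splits(t2)[[i]]))
  })
  for (i in seq_along(a)) {
    expect_equal(a[[i]]$intensities, b[[i]]$intensities)
    expect_equal(a[[i]]$labels, b[[i]]$labels)
  }
})
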