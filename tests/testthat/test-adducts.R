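test_that("window registries carry the printed bounds, four per mode, disjoint", {
  pos <- window_registry("positive")
  neg <- window_registry("negative")
  expect_equal(nrow(pos), 4)
  expect_equal(nrow(neg), 4)
  expect_setequal(pos$label, c("1x13C", "2x13C", "Na+", "K+"))
  expect_setequal(neg$label, c("1x13C", "2x13C", "H2O_loss", "Cl-"))
  expect_equal(unname(unlist(pos[pos$label == "1x13C", c("low", "high")])),
               c(0.994, 1.012))
  expect_equal(unname(unlist(pos[pos$label == "Na+", c("low", "high")])),
               c(21.975, 21.985))
  expect_equal(unname(unlist(pos[pos$label == "K+", c("low", "high")])),
               c(37.954, 37.962))
  expect_equal(unname(unlist(neg[neg$label == "Cl-", c("low", "high")])),
               c(35.969, 35.985))
  expect_equal(unname(unlist(neg[neg$label == "H2O_loss", c("low", "high")])),
               c(18.006, 18.016))
  expect_equal(unname(unlist(neg[neg$label == "2x13C", c("low", "high")])),
               c(1.998, 2.016))
  for (reg in list(pos, neg)) {
    for (i in seq_len(nrow(reg) - 1)) {
      expect_lt(reg$high[i], reg$low[i + 1])  # pairwise disjoint intervals
    }
  }
  expect_error(window_registry("circular"))
})

make_annot_table <- function(mz, rt, significant) {
  n_f <- length(mz)
  x <- matrix(runif(6 * n_f, 1, 100), 6, n_f)
  tab <- feature_table(x, labels = c(0, 0, 0, 1, 1, 1),
                       features = data.frame(
                         feature_id = sprintf("f%02d", seq_len(n_f)),
                         mz = mz, rt = rt),
                       sample_ids = sprintf("s%d", 1:6))
  sig <- data.frame(feature_id = tab$features$feature_id,
                    u_stat = 0, p_value = 0.5, q_value = 0.5,
                    enrichment = 1, significant = significant,
                    stringsAsFactors = FALSE)
  class(sig) <- c("significance_table", "data.frame")
  list(tab = tab, sig = sig)
}

test_that("features are linked by mass window and retention-time gate", {
  set.seed(70)
  d <- make_annot_table(
    mz = c(200.000, 201.003, 221.980, 201.003, 200.000, 150.000),
    rt = c(300, 305, 306, 320, 299, 303),
    significant = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  map <- explain_features(d$tab, d$sig, mode = "positive")
  # 13C isotope and Na+ adduct inside the gate are linked
  expect_true(any(map$links$child_id == "f02" &
                  map$links$window_label == "1x13C"))
  expect_true(any(map$links$child_id == "f03" &
                  map$links$window_label == "Na+"))
  # rt gap of 20 s blocks the same mass offset
  expect_false("f04" %in% map$links$child_id)
  # zero mass difference is never an isotope/adduct
  expect_false("f05" %in% map$links$child_id)
  # lighter features are never explained by a heavier parent
  expect_false("f06" %in% map$links$child_id)
  expect_equal(map$fraction_explained, 2 / 5)
})

test_that("window and gate boundaries follow inclusive/strict conventions", {
  set.seed(71)
  d <- make_annot_table(
    mz = c(100, 100.994, 100.993, 101.012, 101.013, 100.994, 100.994),
    rt = c(500, 500, 500, 500, 500, 514.999, 515),
    significant = c(TRUE, rep(FALSE, 6)))
  map <- explain_features(d$tab, d$sig, mode = "positive")
  expect_true("f02" %in% map$links$child_id)    # 0.994: inclusive low bound
  expect_false("f03" %in% map$links$child_id)   # 0.993: outside
  expect_true("f04" %in% map$links$child_id)    # 1.012: inclusive high bound
  expect_false("f05" %in% map$links$child_id)   # 1.013: outside
  expect_true("f06" %in% map$links$child_id)    # rt gap 14.999 < 15
  expect_false("f07" %in% map$links$child_id)   # rt gap 15 is out (strict)
})

test_that("children default to non-significant features; a child may have several parents", {
  set.seed(72)
  # f03 is 0.999 above f01 and 1.003 above f02, so both significant parents
  # explain it through the 1x13C window
  d2 <- make_annot_table(
    mz = c(99.004, 99.000, 100.003, 120),
    rt = c(400, 402, 401, 900),
    significant = c(TRUE, TRUE, FALSE, FALSE))
  map <- explain_features(d2$tab, d2$sig, mode = "positive")
  kids <- map$links[map$links$child_id == "f03", ]
  expect_setequal(kids$parent_id, c("f01", "f02"))   # both parents kept
  expect_equal(map$explained_ids, "f03")              # counted once
  # significant features are not children by default, but can be inspected
  d3 <- make_annot_table(mz = c(100, 101.002), rt = c(100, 101),
                         significant = c(TRUE, TRUE))
  expect_equal(nrow(explain_features(d3$tab, d3$sig, "positive")$links), 0)
  expect_equal(nrow(explain_features(d3$tab, d3$sig, "positive",
                                     children = "all")$links), 1)
})

test_that("the map is invariant to feature column order", {
  set.seed(73)
  cfg <- generator_config(n_controls = 20, n_cases = 20, n_features = 50,
                          n_markers = 3, marker_effect = 4,
                          n_satellites_per_marker = 2, seed = 29)
  g <- generate_table(cfg)
  norm <- percentile_normalize(floor_and_log(g$table))
  sig <- significance_on_training_fold(norm)
  map1 <- explain_features(norm, sig, "positive")
  perm <- sample(ncol(norm$values))
  norm2 <- norm
  norm2$values <- norm2$values[, perm]
  norm2$features <- norm2$features[perm, ]
  map2 <- explain_features(norm2, sig[perm, ], "positive")
  expect_equal(map1$links, map2$links)
  expect_equal(map1$explained_ids, map2$explained_ids)
})

test_that("planted satellite links are recovered on synthetic data", {
  cfg <- generator_config(n_controls = 40, n_cases = 40, n_features = 60,
                          n_markers = 3, marker_effect = 4,
                          n_satellites_per_marker = 2, satellite_noise_sd = 8,
                          seed = 37)
  g <- generate_table(cfg)
  norm <- percentile_normalize(floor_and_log(g$table))
  sig <- significance_on_training_fold(norm)
  map <- explain_features(norm, sig, "positive")
  truth_links <- g$truth$satellite_links
  sig_ids <- sig$feature_id[sig$significant]
  eligible <- truth_links[truth_links$parent_id %in% sig_ids &
                            !(truth_links$satellite_id %in% sig_ids), ]
  expect_gt(nrow(eligible), 0)
  got <- paste(map$links$parent_id, map$links$child_id)
  # recall: every eligible planted link is found
  expect_true(all(paste(eligible$parent_id, eligible$satellite_id) %in% got))
  # precision: with rejection-sampled background mz, planted links from
  # marker parents are the only links out of markers
  marker_links <- map$links[map$links$parent_id %in% g$truth$marker_ids, ]
  planted <- paste(truth_links$parent_id, truth_links$satellite_id)
  expect_true(all(paste(marker_links$parent_id, marker_links$child_id) %in%
                    planted))
  expect_error(fraction_explained(map, 1), "n_nonsignificant")
  expect_equal(fraction_explained(map, 50),
               length(map$explained_ids) / 50)
})
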