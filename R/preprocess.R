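#' Floor intensities at 1 and apply the binary log transform
#'
#' Missing and sub-1 peak intensities are set to 1, then `log2` is applied,
#' so absent peaks map to exactly 0 and all outputs are non-negative. The
#' transform must be applied once; a provenance flag guards against double
#' application (the composition is not idempotent on the log scale).
#'
#' @param table a [feature_table()] with raw intensities.
#' @return the table with log2 values and provenance `"floor_log"` appended.
#' @export
floor_and_log <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if ("floor_log" %in% table$provenance) {
    stop("floor_and_log has already been applied to this table", call. = FALSE)
  }
  x <- table$intensities
  check_that(all(x >= 0), "intensities", "must be non-negative")
  x[x < 1] <- 1
  table$intensities <- log2(x)
  table$provenance <- c(table$provenance, "floor_log")
  table
}

#' Percentile normalization against the control distribution
#'
#' Rank-based batch correction: within each batch, every sample's value for
#' a feature becomes the percentile of that value within the batch's
#' *control* distribution for the feature — mean-rank convention,
#' `100 * (#controls below + 0.5 * #controls equal) / #controls`, so values
#' below all controls map to 0, above all to 100, and a control scored
#' against an all-tied control set maps to 50. Each batch is normalized
#' separately and the batches are then recombined in the original sample
#' order. The output depends on ranks only, so any strictly increasing
#' per-feature transform of the input leaves it bit-identical.
#'
#' @param table a [feature_table()], normally after [floor_and_log()].
#' @param per_batch normalize each batch separately (default); with
#'   `per_batch = FALSE` or no batch labels the whole table is one batch.
#' @return object of class `normalized_table` with `values` in \[0, 100\].
#' @export
percentile_normalize <- function(table, per_batch = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  if ("percentile_normalize" %in% table$provenance) {
    stop("percentile normalization has already been applied", call. = FALSE)
  }
  x <- table$intensities
  batches <- if (per_batch && !is.null(table$batches)) table$batches
             else rep("all", nrow(x))
  out <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (b in unique(batches)) {
    rows <- which(batches == b)
    ctrl <- rows[table$labels[rows] == 0L]
    if (length(ctrl) < 2) {
      stop(sprintf("batch '%s' has fewer than 2 control samples", b),
           call. = FALSE)
    }
    for (j in seq_len(ncol(x))) {
      sc <- sort(x[ctrl, j])
      q <- x[rows, j]
      n_le <- findInterval(q, sc)
      n_lt <- findInterval(q, sc, left.open = TRUE)
      out[rows, j] <- 100 * (n_lt + 0.5 * (n_le - n_lt)) / length(sc)
    }
  }
  structure(
    list(values = out, labels = table$labels, batches = table$batches,
         features = table$features, sample_ids = table$sample_ids,
         provenance = c(table$provenance, "percentile_normalize")),
    class = c("normalized_table"))
}

#' @method print normalized_table
#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("<normalized_table> %d samples x %d features (percentiles in [0,100])\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.normalized_table <- function(x) dim(x$values)

#' Drop rarely detected features
#'
#' Removes features detected in at most `min_fraction` of samples, keeping
#' the surviving feature order. Detection means raw intensity >= 1 (or a
#' positive log value if the table is already floored and log-transformed).
#'
#' @param table a [feature_table()].
#' @param min_fraction detection fraction a feature must exceed to be kept.
#' @return the filtered table.
#' @export
prevalence_filter <- function(table, min_fraction = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  check_that(min_fraction >= 0 && min_fraction <= 1, "min_fraction",
             "must be in [0,1]")
  x <- table$intensities
  detected <- if ("floor_log" %in% table$provenance) x > 0 else x >= 1
  frac <- colMeans(detected)
  subset_table(table, feature_ids = table$features$feature_id[frac > min_fraction])
}

#' Combine feature tables measured on the same individuals
#'
#' Concatenates the feature axes of several tables (e.g. positive and
#' negative ionization runs of one study) over the samples they share, so
#' each individual contributes a single combined feature vector. Feature ids
#' are prefixed with the source table's name to stay unique.
#'
#' @param tables named (or unnamed) list of [feature_table()]s sharing
#'   sample ids with identical labels per id.
#' @return a single combined `feature_table`.
#' @export
combine_datasets <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "feature_table")))
  if (length(tables) == 1) return(tables[[1]])
  nms <- names(tables) %||% sprintf("d%d", seq_along(tables))
  nms[nms == ""] <- sprintf("d%d", which(nms == ""))
  shared <- Reduce(intersect, lapply(tables, `[[`, "sample_ids"))
  if (!length(shared)) stop("no shared sample ids across tables", call. = FALSE)
  shared <- sort(shared)
  lab_ref <- NULL
  parts <- vector("list", length(tables))
  featl <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    rows <- match(shared, t$sample_ids)
    lab <- t$labels[rows]
    if (is.null(lab_ref)) lab_ref <- lab
    if (!identical(lab, lab_ref)) {
      bad <- shared[which(lab != lab_ref)[1]]
      stop(sprintf("conflicting labels for sample id '%s'", bad),
           call. = FALSE)
    }
    f <- t$features
    f$feature_id <- paste(nms[i], f$feature_id, sep = "_")
    featl[[i]] <- f
    m <- t$intensities[rows, , drop = FALSE]
    colnames(m) <- f$feature_id
    parts[[i]] <- m
  }
  feature_table(do.call(cbind, parts), labels = lab_ref,
                features = do.call(rbind, featl), sample_ids = shared)
}

#' Expand a multiclass table into all one-versus-one binary tables
#'
#' For k classes, returns the k(k-1)/2 pairwise comparisons; within each,
#' the lower class code becomes 0 and the higher 1, other samples excluded.
#'
#' @param table a [feature_table()] with >= 2 classes.
#' @return named list of binary `feature_table`s (`"a_vs_b"`).
#' @export
one_vs_one_splits <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  classes <- sort(unique(table$labels))
  if (length(classes) < 2) stop("table has a single class", call. = FALSE)
  if (length(classes) == 2) {
    out <- table
    out$labels <- as.integer(out$labels == classes[2])
    res <- list(out)
    names(res) <- sprintf("%d_vs_%d", classes[1], classes[2])
    return(res)
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    rows <- which(table$labels %in% pr)
    sub <- subset_table(table, samples = rows)
    sub$labels <- as.integer(sub$labels == pr[2])
    sub
  })
  names(res) <- vapply(pairs, function(pr) sprintf("%d_vs_%d", pr[1], pr[2]),
                       character(1))
  res
}

#' Keep one sample per individual
#'
#' When technical replicates are present, retains exactly one sample per
#' individual — the first by sorted sample id, a deterministic stand-in for
#' an arbitrary choice.
#'
#' @param table a [feature_table()].
#' @param replicate_map named character vector, sample_id -> individual id,
#'   covering every sample.
#' @return the de-replicated table.
#' @export
drop_replicates <- function(table, replicate_map) {
  stopifnot(inherits(table, "feature_table"))
  check_that(all(table$sample_ids %in% names(replicate_map)),
             "replicate_map", "must cover all sample ids")
  indiv <- replicate_map[table$sample_ids]
  keep_ids <- vapply(split(table$sample_ids, indiv),
                     function(s) sort(s)[1], character(1))
  subset_table(table, samples = which(table$sample_ids %in% keep_ids))
}
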