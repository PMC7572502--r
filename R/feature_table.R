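#' Construct a feature table
#'
#' The universal container passed between pipeline stages: a samples x
#' features matrix of non-negative peak intensities with per-sample labels
#' and optional batch identifiers, and per-feature mass-to-charge ratio
#' (Daltons) and retention time (seconds) metadata.
#'
#' @param intensities numeric matrix, samples in rows, features in columns.
#' @param labels integer class per sample; 0 = control, 1 = case (small
#'   integers for multiclass tables).
#' @param features data.frame with columns `feature_id`, `mz`, `rt`.
#' @param sample_ids unique character identifiers, one per row.
#' @param batches optional per-sample batch identifier.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(intensities, labels, features, sample_ids,
                          batches = NULL) {
  intensities <- as.matrix(intensities)
  labels <- as.integer(labels)
  sample_ids <- as.character(sample_ids)
  check_that(nrow(intensities) == length(labels), "labels",
             "length must equal number of rows")
  check_that(nrow(intensities) == length(sample_ids), "sample_ids",
             "length must equal number of rows")
  check_that(!anyDuplicated(sample_ids), "sample_ids", "must be unique")
  check_that(is.data.frame(features) &&
               all(c("feature_id", "mz", "rt") %in% names(features)),
             "features", "needs columns feature_id, mz, rt")
  check_that(ncol(intensities) == nrow(features), "features",
             "one row per intensity column")
  check_that(!anyDuplicated(features$feature_id), "features",
             "feature_id must be unique")
  check_that(all(features$mz > 0), "features", "mz must be > 0")
  check_that(all(features$rt >= 0), "features", "rt must be >= 0")
  if (!is.null(batches)) {
    batches <- as.character(batches)
    check_that(length(batches) == length(labels), "batches",
               "length must equal number of samples")
  }
  features$feature_id <- as.character(features$feature_id)
  rownames(features) <- NULL
  dimnames(intensities) <- list(sample_ids, features$feature_id)
  structure(
    list(intensities = intensities, labels = labels, batches = batches,
         features = features[, c("feature_id", "mz", "rt")],
         sample_ids = sample_ids, provenance = character()),
    class = "feature_table"
  )
}

#' @method print feature_table
#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (!is.null(x$batches)) {
    cat("  batches:", length(unique(x$batches)), "\n")
  }
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

# shared row/column subsetting for feature_table and normalized_table
subset_table <- function(table, samples = NULL, feature_ids = NULL) {
  mat_name <- if (inherits(table, "normalized_table")) "values" else "intensities"
  m <- table[[mat_name]]
  if (is.null(samples)) samples <- seq_len(nrow(m))
  keep_f <- if (is.null(feature_ids)) {
    rep(TRUE, nrow(table$features))
  } else {
    table$features$feature_id %in% feature_ids
  }
  table[[mat_name]] <- m[samples, keep_f, drop = FALSE]
  table$labels <- table$labels[samples]
  table$sample_ids <- table$sample_ids[samples]
  if (!is.null(table$batches)) table$batches <- table$batches[samples]
  table$features <- table$features[keep_f, , drop = FALSE]
  rownames(table$features) <- NULL
  table
}

#' Write a feature table to CSV with a JSON sidecar
#'
#' The CSV holds samples as rows with leading `sample_id`, `label`, `batch`
#' columns; feature columns are named `mz_<mz>_rt_<rt>`. Feature metadata
#' (and, when supplied, the generator's ground truth) go to a JSON sidecar
#' so round-trips are lossless.
#'
#' @param table a `feature_table`.
#' @param csv_path output CSV path.
#' @param sidecar_path output JSON path; default replaces the extension.
#' @param truth optional `ground_truth` to embed in the sidecar.
#' @return invisibly, the CSV path.
#' @export
write_feature_table <- function(table, csv_path,
                                sidecar_path = sub("\\.csv$", ".json", csv_path),
                                truth = NULL) {
  stopifnot(inherits(table, "feature_table"))
  f <- table$features
  colnames <- sprintf("mz_%.4f_rt_%.1f", f$mz, f$rt)
  df <- data.frame(sample_id = table$sample_ids, label = table$labels,
                   batch = table$batches %||% NA_character_,
                   check.names = FALSE)
  mat <- table$intensities
  dimnames(mat) <- NULL
  df <- cbind(df, as.data.frame(mat))
  names(df)[-(1:3)] <- colnames
  utils::write.csv(df, csv_path, row.names = FALSE)
  side <- list(features = f, provenance = table$provenance)
  if (!is.null(truth)) {
    side$ground_truth <- list(
      marker_ids = truth$marker_ids,
      satellite_links = truth$satellite_links,
      diffuse_ids = truth$diffuse_ids,
      theoretical_auc = truth$theoretical_auc
    )
  }
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(csv_path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param csv_path CSV path.
#' @param sidecar_path JSON sidecar path.
#' @return a `feature_table`; any embedded ground truth is attached as
#'   attribute `"ground_truth"`.
#' @export
read_feature_table <- function(csv_path,
                               sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  feats <- as.data.frame(side$features)
  batches <- if (all(is.na(df$batch))) NULL else as.character(df$batch)
  tab <- feature_table(as.matrix(df[, -(1:3), drop = FALSE]),
                       labels = df$label, features = feats,
                       sample_ids = df$sample_id, batches = batches)
  tab$provenance <- as.character(side$provenance %||% character())
  if (!is.null(side$ground_truth)) {
    gt <- side$ground_truth
    attr(tab, "ground_truth") <- structure(
      list(marker_ids = as.character(gt$marker_ids),
           satellite_links = as.data.frame(gt$satellite_links),
           diffuse_ids = as.character(gt$diffuse_ids),
           theoretical_auc = gt$theoretical_auc),
      class = "ground_truth")
  }
  tab
}
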