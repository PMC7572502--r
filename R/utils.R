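#' Rank-based ROC-AUC
#'
#' Probability that a randomly chosen case scores above a randomly chosen
#' control, computed from mid-ranks (ties count 1/2). Equivalent to the
#' normalized Mann-Whitney U statistic of the case scores.
#'
#' @param y_true 0/1 labels (1 = case).
#' @param y_score numeric scores, higher = more case-like.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, y_score) {
  stopifnot(length(y_true) == length(y_score))
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("roc_auc: both classes must be present in y_true")
  }
  r <- rank(y_score)
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deterministic stratified fold assignment: within each class, indices are
# shuffled with the current RNG stream and dealt round-robin, so every fold
# holds both classes whenever each class has >= k members.
stratified_folds <- function(labels, k) {
  stopifnot(k >= 2L)
  folds <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# validation helper: stop with the offending field named
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
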