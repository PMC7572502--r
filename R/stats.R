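table_values <- function(table) {
  if (inherits(table, "normalized_table")) table$values else table$intensities
}

#' Two-sided Mann-Whitney U test
#'
#' U is the number of (control, case) pairs where the control value is
#' larger (ties count 1/2). The exact null distribution is used when both
#' groups have at most 8 observations and no ties are present; otherwise the
#' normal approximation with tie and continuity correction. A fully tied
#' comparison carries no information and returns p = 1.
#'
#' @param x,y numeric values of the two groups (both non-empty).
#' @return list with `u_stat` and two-sided `p_value`.
#' @export
mwu_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty",
                                     call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    return(list(u_stat = length(x) * length(y) / 2, p_value = 1))
  }
  exact <- !ties && length(x) <= 8 && length(y) <= 8
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = !exact))
  p <- ht$p.value
  if (is.nan(p)) p <- 1
  list(u_stat = unname(ht$statistic), p_value = min(p, 1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (Q-values): `q_(i) = min_{j >= i} p_(j) * m / j`
#' clipped at 1, returned in the input order.
#'
#' @param p_values p-values in \[0, 1\].
#' @return Q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  check_that(all(p_values >= 0 & p_values <= 1), "p_values",
             "must lie in [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Case/control enrichment factor
#'
#' Mean value in the cases divided by the mean value in the controls.
#' Undefined (NaN) when the control mean is zero.
#'
#' @param x control values.
#' @param y case values.
#' @return dimensionless ratio.
#' @export
enrichment_factor <- function(x, y) {
  mx <- mean(x)
  if (mx == 0) return(NaN)
  mean(y) / mx
}

#' Per-feature significance on a training partition
#'
#' Runs the two-sided MW-U test on every feature of the supplied (training)
#' table, adjusts with BH-FDR across its features, and flags Q < 0.05 as
#' significant. Called inside the cross-validation loop on the outer
#' training fold so test samples never influence feature selection, and on
#' the complete table for the non-significant-feature regimes.
#'
#' @param train a `normalized_table` (or `feature_table`) with both classes.
#' @return data.frame of class `significance_table` with columns
#'   `feature_id`, `u_stat`, `p_value`, `q_value`, `enrichment`,
#'   `significant`.
#' @export
significance_on_training_fold <- function(train) {
  x <- table_values(train)
  lab <- train$labels
  if (length(unique(lab)) < 2) {
    stop("training partition holds a single class", call. = FALSE)
  }
  ctrl <- lab == 0L
  case <- lab == 1L
  res <- vapply(seq_len(ncol(x)), function(j) {
    t <- mwu_test(x[ctrl, j], x[case, j])
    c(t$u_stat, t$p_value, enrichment_factor(x[ctrl, j], x[case, j]))
  }, numeric(3))
  q <- bh_fdr(res[2, ])
  out <- data.frame(feature_id = train$features$feature_id,
                    u_stat = res[1, ], p_value = res[2, ], q_value = q,
                    enrichment = res[3, ], significant = q < 0.05,
                    stringsAsFactors = FALSE)
  class(out) <- c("significance_table", "data.frame")
  out
}

#' Specify a feature-selection regime
#'
#' The five regimes compared by the pipeline: `all` features;
#' `significant_only` (Q < 0.05, recomputed within each training fold);
#' `top_k_significant` (the k smallest-Q significant features — fewer when
#' fewer are significant); `nonsignificant_only` (Q >= 0.05, significance
#' from the complete data set); and `nonsignificant_no_satellites`
#' (additionally drop features explained as isotopes/adducts of significant
#' features).
#'
#' @param kind regime name.
#' @param k top-k cutoff; required for `top_k_significant`.
#' @param explanation_map an [explain_features()] map; required for
#'   `nonsignificant_no_satellites`.
#' @return object of class `regime_spec`.
#' @export
regime_spec <- function(kind = c("all", "significant_only",
                                 "top_k_significant", "nonsignificant_only",
                                 "nonsignificant_no_satellites"),
                        k = NULL, explanation_map = NULL) {
  kind <- match.arg(kind)
  if (kind == "top_k_significant") {
    check_that(!is.null(k) && k > 0, "k", "must be a positive count")
  }
  if (kind == "nonsignificant_no_satellites") {
    # the map may be attached later by the pipeline (it depends on the data);
    # apply_regime() requires it at application time
    check_that(is.null(explanation_map) ||
                 inherits(explanation_map, "explanation_map"),
               "explanation_map", "must be an explanation_map when supplied")
  } else {
    check_that(is.null(explanation_map), "explanation_map",
               sprintf("not used by the %s regime", kind))
  }
  structure(list(kind = kind, k = k, explanation_map = explanation_map),
            class = "regime_spec")
}

#' Apply a feature-selection regime to a table
#'
#' Subsets the table's features according to the regime and the supplied
#' significance table. Top-k ties on Q are broken lexicographically by
#' feature id for determinism. An empty result is legal and triggers the
#' degenerate AUC = 0.5 convention downstream.
#'
#' @param table a `normalized_table` (or `feature_table`).
#' @param sig a `significance_table` aligned to `table`'s features.
#' @param spec a [regime_spec()].
#' @return the subsetted table.
#' @export
apply_regime <- function(table, sig, spec) {
  stopifnot(inherits(spec, "regime_spec"))
  check_that(identical(as.character(sig$feature_id),
                       table$features$feature_id),
             "sig", "must be aligned to the table's features")
  keep <- switch(
    spec$kind,
    all = sig$feature_id,
    significant_only = sig$feature_id[sig$significant],
    top_k_significant = {
      s <- sig[sig$significant, , drop = FALSE]
      s <- s[order(s$q_value, s$feature_id), , drop = FALSE]
      utils::head(s$feature_id, spec$k)
    },
    nonsignificant_only = sig$feature_id[!sig$significant],
    nonsignificant_no_satellites = {
      check_that(inherits(spec$explanation_map, "explanation_map"),
                 "explanation_map",
                 "required to apply the nonsignificant_no_satellites regime")
      ids <- sig$feature_id[!sig$significant]
      setdiff(ids, spec$explanation_map$explained_ids)
    })
  subset_table(table, feature_ids = keep)
}
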