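#' Configure an end-to-end experiment
#'
#' Bundles data sets, feature regimes and the evaluation protocol for
#' [run_experiment()]. Each data set may be a `feature_table`, a
#' [generator_config()] (generated at run time), or a path to a CSV written
#' by [write_feature_table()].
#'
#' @param datasets named list of inputs (names become `dataset_id`s).
#' @param regimes named list of [regime_spec()]s (at least one).
#' @param protocol a [cv_protocol()].
#' @param ionization_mode mode for isotope/adduct annotation.
#' @param rt_gate_s retention-time gate for annotation, seconds.
#' @param min_fraction prevalence-filter threshold.
#' @param per_batch normalize each batch separately when batches exist.
#' @param output_dir optional directory; when set, the consolidated report
#'   CSV and per-cell JSON files are written there.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(datasets, regimes, protocol = cv_protocol(),
                              ionization_mode = c("positive", "negative"),
                              rt_gate_s = 15, min_fraction = 0.05,
                              per_batch = TRUE, output_dir = NULL) {
  ionization_mode <- match.arg(ionization_mode)
  check_that(is.list(datasets) && length(datasets) >= 1, "datasets",
             "need at least one data set")
  check_that(is.list(regimes) && length(regimes) >= 1 &&
               all(vapply(regimes, inherits, logical(1), "regime_spec")),
             "regimes", "need at least one regime_spec")
  if (is.null(names(datasets))) {
    names(datasets) <- sprintf("dataset%d", seq_along(datasets))
  }
  if (is.null(names(regimes))) {
    names(regimes) <- vapply(regimes, `[[`, character(1), "kind")
  }
  structure(list(datasets = datasets, regimes = regimes, protocol = protocol,
                 ionization_mode = ionization_mode, rt_gate_s = rt_gate_s,
                 min_fraction = min_fraction, per_batch = per_batch,
                 output_dir = output_dir),
            class = "experiment_config")
}

resolve_dataset <- function(input) {
  if (inherits(input, "feature_table")) {
    list(table = input, truth = attr(input, "ground_truth"))
  } else if (inherits(input, "generator_config")) {
    generate_table(input)
  } else if (is.character(input) && length(input) == 1) {
    tab <- read_feature_table(input)
    list(table = tab, truth = attr(tab, "ground_truth"))
  } else {
    stop("dataset input must be a feature_table, generator_config or CSV path",
         call. = FALSE)
  }
}

preprocess_dataset <- function(table, config) {
  tab <- prevalence_filter(table, config$min_fraction)
  tab <- floor_and_log(tab)
  percentile_normalize(tab, per_batch = config$per_batch)
}

#' Run every (data set, regime) cell of an experiment
#'
#' Each data set is preprocessed once (prevalence filter, floor + binary
#' log, percentile normalization), per-feature significance is computed on
#' the complete data set, and an isotope/adduct explanation map is built
#' when a regime needs one. Regimes `all`, `significant_only` and
#' `top_k_significant` recompute significance within each outer training
#' fold; the non-significant regimes remove the complete-data significant
#' features (and, for `nonsignificant_no_satellites`, the explained
#' features) before the nested CV. A failing cell is reported with its
#' error, never silently dropped.
#'
#' @param config an [experiment_config()].
#' @return object of class `comparison_report`: `rows` (one per cell, with
#'   mean/SD/CI AUC, feature counts, the fraction of used features that are
#'   significant, and the fraction of non-significant features explained as
#'   isotopes/adducts) and `deltas` (`AUC(all) - AUC(regime)` per data set
#'   where both cells succeeded). Evaluation results are attached as
#'   attribute `"results"`, ground truths as `"truths"`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  results <- list()
  truths <- list()
  for (ds in names(config$datasets)) {
    prep <- tryCatch({
      d <- resolve_dataset(config$datasets[[ds]])
      norm <- preprocess_dataset(d$table, config)
      sig_full <- significance_on_training_fold(norm)
      needs_map <- any(vapply(config$regimes, `[[`, character(1), "kind") ==
                         "nonsignificant_no_satellites")
      map <- if (needs_map) {
        explain_features(norm, sig_full, mode = config$ionization_mode,
                         rt_gate_s = config$rt_gate_s)
      }
      truths[[ds]] <- d$truth
      list(norm = norm, sig = sig_full, map = map)
    }, error = function(e) e)

    for (rg in names(config$regimes)) {
      spec <- config$regimes[[rg]]
      cell <- if (inherits(prep, "error")) {
        prep
      } else {
        tryCatch(
          run_cell(prep$norm, prep$sig, prep$map, spec, config$protocol),
          error = function(e) e)
      }
      if (inherits(cell, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_id = ds, regime = rg, status = "failed",
          mean_auc = NA_real_, sd_auc = NA_real_, ci95 = NA_real_,
          n_features_input = NA_integer_, n_features_used = NA_integer_,
          fraction_significant_used = NA_real_,
          fraction_explained = NA_real_,
          error = conditionMessage(cell), stringsAsFactors = FALSE)
      } else {
        results[[paste(ds, rg, sep = ".")]] <- cell$result
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_id = ds, regime = rg, status = "ok",
          mean_auc = cell$result$mean_auc, sd_auc = cell$result$sd_auc,
          ci95 = cell$result$ci95_halfwidth,
          n_features_input = cell$n_input,
          n_features_used = cell$result$n_nonzero,
          fraction_significant_used = cell$frac_sig_used,
          fraction_explained = if (is.null(prep$map)) NA_real_ else
            prep$map$fraction_explained,
          error = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  rows <- do.call(rbind, rows)
  deltas <- NULL
  all_rows <- rows[rows$regime == "all" & rows$status == "ok", ]
  if (nrow(all_rows)) {
    other <- rows[rows$regime != "all" & rows$status == "ok", ]
    other$delta_auc <- all_rows$mean_auc[match(other$dataset_id,
                                               all_rows$dataset_id)] -
      other$mean_auc
    deltas <- other[!is.na(other$delta_auc),
                    c("dataset_id", "regime", "delta_auc")]
    rownames(deltas) <- NULL
  }
  report <- structure(list(rows = rows, deltas = deltas),
                      class = "comparison_report")
  attr(report, "results") <- results
  attr(report, "truths") <- truths
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

run_cell <- function(norm, sig_full, map, spec, protocol) {
  n_input <- ncol(norm$values)
  result <- if (spec$kind %in% c("significant_only", "top_k_significant")) {
    nested_cv_l1lr(norm, protocol, regime = spec)
  } else if (spec$kind == "all") {
    nested_cv_l1lr(norm, protocol)
  } else {
    if (spec$kind == "nonsignificant_no_satellites" &&
        is.null(spec$explanation_map)) {
      spec$explanation_map <- map
    }
    reduced <- apply_regime(norm, sig_full, spec)
    n_input <- ncol(reduced$values)
    nested_cv_l1lr(reduced, protocol)
  }
  frac_sig_used <- NA_real_
  if (!result$degenerate && result$n_nonzero > 0) {
    used <- names(result$mean_coefficients)[result$mean_coefficients != 0]
    sig_ids <- sig_full$feature_id[sig_full$significant]
    frac_sig_used <- mean(used %in% sig_ids)
  }
  list(result = result, n_input = n_input, frac_sig_used = frac_sig_used)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$rows, file.path(dir, "report.csv"),
                   row.names = FALSE)
  if (!is.null(report$deltas)) {
    utils::write.csv(report$deltas, file.path(dir, "deltas.csv"),
                     row.names = FALSE)
  }
  results <- attr(report, "results")
  for (nm in names(results)) {
    r <- results[[nm]]
    jsonlite::write_json(
      list(cell = nm, mean_auc = r$mean_auc, sd_auc = r$sd_auc,
           ci95_halfwidth = r$ci95_halfwidth,
           per_shuffle_auc = r$per_shuffle_auc, secondary = r$secondary,
           n_nonzero = r$n_nonzero, degenerate = r$degenerate),
      file.path(dir, paste0("cell_", gsub("[^A-Za-z0-9._-]", "_", nm),
                            ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @method print comparison_report
#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d cells (%d ok, %d failed)\n",
              nrow(x$rows), sum(x$rows$status == "ok"),
              sum(x$rows$status == "failed")))
  print(x$rows[, c("dataset_id", "regime", "status", "mean_auc", "sd_auc",
                   "n_features_used")], row.names = FALSE)
  invisible(x)
}

#' Sweep the top-k significant-feature cutoff
#'
#' Evaluates models restricted to the k most significant features (smallest
#' Q, within-fold) for each k, alongside the all-features and
#' all-significant baselines. When fewer than k features are significant,
#' only those are used, so curves plateau once k exceeds the significant
#' count. The returned report carries attribute `"k_attainment"`: for each
#' k, the fraction of data sets whose complete-data significant-feature
#' count reaches it.
#'
#' @param config an [experiment_config()]; its `regimes` are replaced by the
#'   sweep regimes.
#' @param ks top-k cutoffs.
#' @return a `comparison_report`.
#' @export
top_k_sweep <- function(config, ks = c(5, 10, 50, 100)) {
  stopifnot(inherits(config, "experiment_config"))
  regimes <- c(list(all = regime_spec("all"),
                    significant_only = regime_spec("significant_only")),
               stats::setNames(lapply(ks, function(k)
                 regime_spec("top_k_significant", k = k)),
                 sprintf("top_%d", ks)))
  config$regimes <- regimes
  report <- run_experiment(config)
  n_sig <- vapply(names(config$datasets), function(ds) {
    d <- tryCatch(resolve_dataset(config$datasets[[ds]]),
                  error = function(e) NULL)
    if (is.null(d)) return(NA_integer_)
    norm <- preprocess_dataset(d$table, config)
    sum(significance_on_training_fold(norm)$significant)
  }, integer(1))
  attr(report, "k_attainment") <- vapply(ks, function(k)
    mean(n_sig >= k, na.rm = TRUE), numeric(1))
  names(attr(report, "k_attainment")) <- sprintf("top_%d", ks)
  report
}
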