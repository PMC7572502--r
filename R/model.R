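#' Nested cross-validation protocol
#'
#' Stratified 5-fold outer / 3-fold inner nested cross-validation with the
#' inverse-regularization grid C = \{2, 5, 20, 50, 100\} for L1 logistic
#' regression, scored by ROC-AUC in the inner loop, repeated over
#' `n_shuffles` independent full-data shuffles. `C` is on the sklearn scale
#' (penalty weight 1/C on the L1 norm of the coefficients against the summed
#' log-loss); internally it maps to a glmnet lambda of `1 / (C * n_train)`.
#'
#' @param outer_folds,inner_folds stratified fold counts (>= 2).
#' @param c_grid positive inverse-regularization strengths.
#' @param n_shuffles independent repetitions on shuffled data.
#' @param seed base seed; shuffle i uses `seed + i`.
#' @return object of class `cv_protocol`.
#' @export
cv_protocol <- function(outer_folds = 5, inner_folds = 3,
                        c_grid = c(2, 5, 20, 50, 100), n_shuffles = 30,
                        seed = 1L) {
  check_that(outer_folds >= 2, "outer_folds", "must be >= 2")
  check_that(inner_folds >= 2, "inner_folds", "must be >= 2")
  check_that(length(c_grid) >= 1 && all(c_grid > 0), "c_grid",
             "must be non-empty and positive")
  check_that(n_shuffles >= 1, "n_shuffles", "must be >= 1")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 c_grid = c_grid, n_shuffles = as.integer(n_shuffles),
                 scoring = "roc_auc", seed = as.integer(seed)),
            class = "cv_protocol")
}

# Fit the L1-LR path at the lambdas implied by the C grid. glmnet needs >= 2
# columns; a zero variance pad column is added (its coefficient is always 0)
# and stripped from the returned coefficients.
fit_l1lr_path <- function(X, y, c_grid) {
  n <- nrow(X)
  lambdas <- 1 / (c_grid * n)
  pad <- ncol(X) == 1L
  if (pad) X <- cbind(X, 0)
  fit <- suppressWarnings(
    glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                   alpha = 1, lambda = sort(unique(lambdas), decreasing = TRUE),
                   standardize = FALSE))
  list(fit = fit, lambdas = lambdas, pad = pad)
}

predict_l1lr <- function(path, newx, c_index) {
  if (path$pad) newx <- cbind(newx, 0)
  as.numeric(stats::predict(path$fit, newx = newx,
                            s = path$lambdas[c_index], type = "response"))
}

coef_l1lr <- function(path, c_index) {
  b <- as.numeric(stats::coef(path$fit, s = path$lambdas[c_index]))[-1]
  if (path$pad) b <- b[1]
  b
}

#' Confusion-matrix and ranking metrics for one test fold
#'
#' ROC-AUC from the continuous scores; balanced accuracy, Matthews
#' correlation coefficient, sensitivity, specificity and precision from the
#' 2x2 confusion matrix of the hard predictions (probability threshold 0.5
#' upstream). MCC is 0 when its denominator vanishes; precision is NaN when
#' nothing is predicted positive.
#'
#' @param y_true 0/1 labels containing both classes.
#' @param y_score continuous case scores.
#' @param y_pred hard 0/1 predictions.
#' @return named list: `auc`, `balanced_accuracy`, `mcc`, `sensitivity`,
#'   `specificity`, `precision`.
#' @export
fold_metrics <- function(y_true, y_score, y_pred) {
  stopifnot(length(y_true) == length(y_score),
            length(y_true) == length(y_pred))
  auc <- roc_auc(y_true, y_score)
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- tp / (tp + fp)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(auc = auc, balanced_accuracy = (sens + spec) / 2, mcc = mcc,
       sensitivity = sens, specificity = spec, precision = prec)
}

#' Summarize per-shuffle AUCs
#'
#' Mean and SD over the shuffle AUCs; the 95% confidence half-width uses the
#' average outer-test-fold size as the effective sample size,
#' `1.96 * sd / sqrt(avg_test_n)`, to reflect the larger uncertainty of
#' small data sets. A single-element list has SD 0 by convention.
#'
#' @param per_shuffle_auc non-empty numeric vector.
#' @param avg_test_n average test-fold size (>= 1).
#' @return list with `mean`, `sd`, `ci95_halfwidth`.
#' @export
summarize_shuffles <- function(per_shuffle_auc, avg_test_n) {
  check_that(length(per_shuffle_auc) >= 1, "per_shuffle_auc",
             "must be non-empty")
  check_that(avg_test_n >= 1, "avg_test_n", "must be >= 1")
  s <- if (length(per_shuffle_auc) == 1) 0 else stats::sd(per_shuffle_auc)
  list(mean = mean(per_shuffle_auc), sd = s,
       ci95_halfwidth = 1.96 * s / sqrt(avg_test_n))
}

#' Nested cross-validated evaluation of L1 logistic regression
#'
#' For each of `n_shuffles` shuffles: the samples are permuted, split into
#' stratified outer folds, the inner stratified CV picks C from the grid by
#' ROC-AUC, the model is refit on the outer-training fold and scored on the
#' held-out fold. When a within-fold regime (`significant_only` or
#' `top_k_significant`) is given, per-feature significance is recomputed on
#' each outer-training fold only, so the test fold never influences feature
#' selection. Fold AUCs are averaged per shuffle and then across shuffles;
#' test AUCs below 0.5 are retained as observed. Feature coefficients are
#' averaged over every trained model (zero for unselected features). A table
#' (or within-fold selection) with no features yields the degenerate
#' convention: AUC fixed at exactly 0.5, no model trained.
#'
#' @param table a `normalized_table` (or `feature_table`) with binary 0/1
#'   labels and at least `outer_folds` samples per class.
#' @param protocol a [cv_protocol()].
#' @param regime optional within-fold [regime_spec()] (`all`,
#'   `significant_only` or `top_k_significant`); the non-significant regimes
#'   use complete-data significance and must be applied to the table before
#'   calling (see [run_experiment()]).
#' @return object of class `evaluation_result`.
#' @export
nested_cv_l1lr <- function(table, protocol = cv_protocol(), regime = NULL) {
  stopifnot(inherits(protocol, "cv_protocol"))
  X <- table_values(table)
  y <- table$labels
  check_that(all(y %in% c(0L, 1L)) && length(unique(y)) == 2, "table",
             "labels must be binary 0/1 with both classes present")
  if (!is.null(regime)) {
    stopifnot(inherits(regime, "regime_spec"))
    if (regime$kind %in% c("nonsignificant_only",
                           "nonsignificant_no_satellites")) {
      stop(paste("non-significant regimes use complete-data significance;",
                 "apply_regime() the table first (see run_experiment())"),
           call. = FALSE)
    }
    if (regime$kind == "all") regime <- NULL
  }
  if (ncol(X) == 0L) {
    return(degenerate_result(protocol, reason = "empty feature set"))
  }
  min_class <- min(sum(y == 0L), sum(y == 1L))
  if (min_class < protocol$outer_folds) {
    stop(sprintf("smallest class has %d samples, fewer than %d outer folds",
                 min_class, protocol$outer_folds), call. = FALSE)
  }
  feature_ids <- table$features$feature_id
  n <- length(y)
  per_shuffle <- numeric(protocol$n_shuffles)
  fold_rows <- list()
  coef_sum <- stats::setNames(numeric(ncol(X)), feature_ids)
  n_models <- 0L

  for (s in seq_len(protocol$n_shuffles)) {
    res_s <- withr::with_seed(protocol$seed + s, {
      perm <- sample.int(n)
      folds <- stratified_folds(y[perm], protocol$outer_folds)
      fold_out <- vector("list", protocol$outer_folds)
      for (f in seq_len(protocol$outer_folds)) {
        test_idx <- perm[folds == f]
        train_idx <- perm[folds != f]
        keep <- seq_len(ncol(X))
        if (!is.null(regime)) {
          tr_tab <- subset_table(table, samples = train_idx)
          sig <- significance_on_training_fold(tr_tab)
          kept_ids <- apply_regime(tr_tab, sig, regime)$features$feature_id
          keep <- match(kept_ids, feature_ids)
        }
        if (length(keep) == 0L) {
          fold_out[[f]] <- list(auc = 0.5, metrics = NULL,
                                coefs = NULL, test_n = length(test_idx))
          next
        }
        Xtr <- X[train_idx, keep, drop = FALSE]
        ytr <- y[train_idx]
        # inner stratified CV selects C by ROC-AUC (first best on ties)
        inner <- stratified_folds(ytr, protocol$inner_folds)
        auc_c <- matrix(NA_real_, protocol$inner_folds,
                        length(protocol$c_grid))
        for (g in seq_len(protocol$inner_folds)) {
          itr <- inner != g
          path <- fit_l1lr_path(Xtr[itr, , drop = FALSE], ytr[itr],
                                protocol$c_grid)
          for (ci in seq_along(protocol$c_grid)) {
            pr <- predict_l1lr(path, Xtr[!itr, , drop = FALSE], ci)
            auc_c[g, ci] <- roc_auc(ytr[!itr], pr)
          }
        }
        best_c <- which.max(colMeans(auc_c))
        path <- fit_l1lr_path(Xtr, ytr, protocol$c_grid)
        pr <- predict_l1lr(path, X[test_idx, keep, drop = FALSE], best_c)
        m <- fold_metrics(y[test_idx], pr, as.integer(pr > 0.5))
        b <- stats::setNames(numeric(ncol(X)), feature_ids)
        b[keep] <- coef_l1lr(path, best_c)
        fold_out[[f]] <- list(auc = m$auc, metrics = m, coefs = b,
                              test_n = length(test_idx),
                              best_c = protocol$c_grid[best_c],
                              n_features = length(keep))
      }
      fold_out
    })
    per_shuffle[s] <- mean(vapply(res_s, `[[`, numeric(1), "auc"))
    for (f in seq_along(res_s)) {
      r <- res_s[[f]]
      if (!is.null(r$coefs)) {
        coef_sum <- coef_sum + r$coefs
        n_models <- n_models + 1L
      }
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        shuffle = s, fold = f, auc = r$auc,
        balanced_accuracy = r$metrics$balanced_accuracy %||% NA_real_,
        mcc = r$metrics$mcc %||% NA_real_,
        sensitivity = r$metrics$sensitivity %||% NA_real_,
        specificity = r$metrics$specificity %||% NA_real_,
        precision = r$metrics$precision %||% NA_real_,
        test_n = r$test_n, best_c = r$best_c %||% NA_real_,
        n_features = r$n_features %||% 0L)
    }
  }

  folds_df <- do.call(rbind, fold_rows)
  avg_test_n <- mean(folds_df$test_n)
  summ <- summarize_shuffles(per_shuffle, avg_test_n)
  mean_coef <- if (n_models > 0) coef_sum / n_models else coef_sum
  secondary <- vapply(c("balanced_accuracy", "mcc", "sensitivity",
                        "specificity", "precision"),
                      function(col) mean(folds_df[[col]], na.rm = TRUE),
                      numeric(1))
  structure(
    list(per_shuffle_auc = per_shuffle, mean_auc = summ$mean,
         sd_auc = summ$sd, ci95_halfwidth = summ$ci95_halfwidth,
         avg_test_n = avg_test_n, secondary = as.list(secondary),
         mean_coefficients = mean_coef,
         n_nonzero = sum(mean_coef != 0), degenerate = FALSE,
         folds = folds_df, protocol = protocol),
    class = "evaluation_result")
}

degenerate_result <- function(protocol, reason) {
  structure(
    list(per_shuffle_auc = rep(0.5, protocol$n_shuffles), mean_auc = 0.5,
         sd_auc = 0, ci95_halfwidth = 0, avg_test_n = NA_real_,
         secondary = list(balanced_accuracy = NA_real_, mcc = NA_real_,
                          sensitivity = NA_real_, specificity = NA_real_,
                          precision = NA_real_),
         mean_coefficients = numeric(0), n_nonzero = 0L, degenerate = TRUE,
         folds = NULL, protocol = protocol, reason = reason),
    class = "evaluation_result")
}

#' @method print evaluation_result
#' @export
print.evaluation_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<evaluation_result> degenerate (%s): AUC recorded as 0.5\n",
                x$reason))
    return(invisible(x))
  }
  cat(sprintf("<evaluation_result> mean AUC %.3f +/- %.3f (SD over %d shuffles), 95%% CI half-width %.3f\n",
              x$mean_auc, x$sd_auc, length(x$per_shuffle_auc),
              x$ci95_halfwidth))
  cat(sprintf("  nonzero averaged coefficients: %d of %d features\n",
              x$n_nonzero, length(x$mean_coefficients)))
  invisible(x)
}

#' Names of implemented classifiers
#'
#' The evaluation harness is classifier-agnostic; only L1-regularized
#' logistic regression is implemented here. Other classifier names error
#' explicitly rather than silently falling back.
#'
#' @return character vector of registered names.
#' @export
classifier_registry <- function() c("l1lr")

#' Evaluate a registered classifier under the nested-CV harness
#'
#' @param name classifier name; see [classifier_registry()].
#' @param table,protocol,regime as in [nested_cv_l1lr()].
#' @return an `evaluation_result`.
#' @export
evaluate_classifier <- function(name, table, protocol = cv_protocol(),
                                regime = NULL) {
  known <- c("l1lr", "plsda", "rf", "svm", "knn", "nb")
  if (!name %in% known) {
    stop(sprintf("unknown classifier '%s'; known names: %s", name,
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  if (!name %in% classifier_registry()) {
    stop(sprintf("classifier '%s' is not implemented; available: %s", name,
                 paste(classifier_registry(), collapse = ", ")),
         call. = FALSE)
  }
  nested_cv_l1lr(table, protocol, regime)
}
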