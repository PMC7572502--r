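#' Configuration for the synthetic feature-table generator
#'
#' Defines a case/control LC/GC-MS-like study on the binary-log scale: a
#' minority of marker features with an additive case shift, satellite
#' features that track their parent marker's log-intensity and sit at an
#' isotope/adduct mass offset within 15 s retention time, optional diffuse
#' weak signal spread over many background features, multiplicative (i.e.
#' additive-in-log) batch effects, and missing values reported as 0.
#'
#' @param n_controls,n_cases samples per class.
#' @param n_features total feature count.
#' @param n_markers features carrying the main case/control shift.
#' @param marker_effect additive case shift on the log2 scale.
#' @param n_satellites_per_marker satellites planted per marker.
#' @param satellite_window_labels window labels (see [window_registry()])
#'   cycled over when placing satellite mz offsets; default: all windows
#'   valid for `ionization_mode`.
#' @param satellite_noise_sd log2 SD of satellite-specific noise added to
#'   the parent's log-intensity; default `0.1 * noise_sd` (correlation with
#'   the parent > 0.9).
#' @param diffuse_signal_fraction fraction of background features given a
#'   weak shift of `diffuse_effect` (random sign).
#' @param diffuse_effect log2-scale magnitude of the diffuse shift.
#' @param n_batches number of batches; samples are dealt round-robin within
#'   class so every batch holds both classes.
#' @param batch_effect_sd log2 SD of per-batch, per-feature offsets.
#' @param noise_sd within-group log2 SD (must be > 0).
#' @param missing_rate probability an intensity is masked (reported as 0).
#' @param ionization_mode `"positive"` or `"negative"`.
#' @param rt_jitter_max_s satellite retention-time jitter bound in seconds;
#'   keep below the 15 s annotation gate.
#' @param avoid_satellite_windows when TRUE (default), background and marker
#'   mz/rt values are rejection-sampled so that no unplanned feature pair
#'   falls inside an annotation window at close retention time — planted
#'   satellite links are then the only true links.
#' @param seed integer seed; one RNG stream per table.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_controls = 50, n_cases = 50, n_features = 200,
                             n_markers = 3, marker_effect = 1,
                             n_satellites_per_marker = 0,
                             satellite_window_labels = NULL,
                             satellite_noise_sd = NULL,
                             diffuse_signal_fraction = 0, diffuse_effect = 0.3,
                             n_batches = 1, batch_effect_sd = 0,
                             noise_sd = 1, missing_rate = 0,
                             ionization_mode = c("positive", "negative"),
                             rt_jitter_max_s = 14,
                             avoid_satellite_windows = TRUE,
                             seed = 1L) {
  ionization_mode <- match.arg(ionization_mode)
  counts <- c(n_controls = n_controls, n_cases = n_cases,
              n_features = n_features, n_markers = n_markers,
              n_satellites_per_marker = n_satellites_per_marker,
              n_batches = n_batches)
  for (nm in names(counts)) {
    check_that(length(counts[[nm]]) == 1 && counts[[nm]] >= 0 &&
                 counts[[nm]] == round(counts[[nm]]), nm,
               "must be a non-negative integer count")
  }
  check_that(n_batches >= 1, "n_batches", "must be >= 1")
  check_that(n_markers + n_markers * n_satellites_per_marker <= n_features,
             "n_markers", "markers plus satellites exceed n_features")
  check_that(noise_sd > 0, "noise_sd", "must be > 0")
  check_that(batch_effect_sd >= 0, "batch_effect_sd", "must be >= 0")
  check_that(missing_rate >= 0 && missing_rate <= 1, "missing_rate",
             "must be a probability in [0,1]")
  check_that(diffuse_signal_fraction >= 0 && diffuse_signal_fraction <= 1,
             "diffuse_signal_fraction", "must be a fraction in [0,1]")
  check_that(rt_jitter_max_s > 0, "rt_jitter_max_s", "must be > 0 seconds")
  registry <- window_registry(ionization_mode)
  if (is.null(satellite_window_labels)) {
    satellite_window_labels <- registry$label
  }
  check_that(all(satellite_window_labels %in% registry$label),
             "satellite_window_labels",
             sprintf("must be valid for %s mode: %s", ionization_mode,
                     paste(registry$label, collapse = ", ")))
  satellite_noise_sd <- satellite_noise_sd %||% (0.1 * noise_sd)
  check_that(satellite_noise_sd > 0, "satellite_noise_sd", "must be > 0")
  structure(
    list(n_controls = n_controls, n_cases = n_cases, n_features = n_features,
         n_markers = n_markers, marker_effect = marker_effect,
         n_satellites_per_marker = n_satellites_per_marker,
         satellite_window_labels = satellite_window_labels,
         satellite_noise_sd = satellite_noise_sd,
         diffuse_signal_fraction = diffuse_signal_fraction,
         diffuse_effect = diffuse_effect, n_batches = n_batches,
         batch_effect_sd = batch_effect_sd, noise_sd = noise_sd,
         missing_rate = missing_rate, ionization_mode = ionization_mode,
         rt_jitter_max_s = rt_jitter_max_s,
         avoid_satellite_windows = avoid_satellite_windows,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Closed-form ROC-AUC of a single Gaussian marker
#'
#' For equal-variance Gaussian log-intensities with case/control mean
#' difference `delta` and within-group SD `sigma`, the probability that a
#' random case exceeds a random control is `pnorm(delta / (sigma * sqrt(2)))`.
#' Used as the Bayes-optimal single-marker benchmark for generated tables.
#'
#' @param delta log2-scale mean shift.
#' @param sigma log2-scale within-group SD (> 0).
#' @return AUC in (0, 1); 0.5 at `delta = 0`.
#' @export
theoretical_auc <- function(delta, sigma) {
  check_that(all(sigma > 0), "sigma", "must be > 0")
  stats::pnorm(delta / (sigma * sqrt(2)))
}

#' Generate a synthetic case/control feature table with known ground truth
#'
#' Log2 intensities are Gaussian around per-feature baselines drawn in
#' \[8, 24\] (typical detector log-counts); markers add `marker_effect` to
#' cases, diffuse features add `diffuse_effect` with random sign, and each
#' satellite copies its parent marker's per-sample log-intensity plus a
#' fixed dimming offset and satellite-specific noise, so it correlates with
#' the parent. Satellite mz sits strictly inside its named window relative
#' to the parent, rt within `rt_jitter_max_s`. Batch offsets are additive in
#' log space. Intensities below 1 or hit by `missing_rate` are reported 0.
#' Identical configs (including seed) give byte-identical output.
#'
#' @param config a [generator_config()].
#' @return list with `table` (a [feature_table()]) and `truth` (class
#'   `ground_truth`: `marker_ids`, `satellite_links` data.frame
#'   `(parent_id, satellite_id, window_label)`, `diffuse_ids`,
#'   `theoretical_auc` of the strongest marker).
#' @export
generate_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_table_impl(config))
}

generate_table_impl <- function(cfg) {
  n <- cfg$n_controls + cfg$n_cases
  check_that(n >= 2, "n_controls", "need at least 2 samples in total")
  labels <- rep(c(0L, 1L), c(cfg$n_controls, cfg$n_cases))
  p <- cfg$n_features
  n_sat <- cfg$n_markers * cfg$n_satellites_per_marker
  n_plain <- p - n_sat               # markers + background
  registry <- window_registry(cfg$ionization_mode)

  ids <- sprintf("F%04d", seq_len(p))
  marker_idx <- seq_len(cfg$n_markers)
  plain_idx <- seq_len(n_plain)
  sat_idx <- if (n_sat > 0) n_plain + seq_len(n_sat) else integer()

  # mz/rt for markers and background; optional rejection sampling keeps any
  # unplanned pair out of the annotation windows at close retention time
  mz <- numeric(p)
  rt <- numeric(p)
  guard_rt <- 15 + 2 * cfg$rt_jitter_max_s
  for (j in plain_idx) {
    repeat {
      cand_mz <- stats::runif(1, 70, 1000)
      cand_rt <- stats::runif(1, 30, 1200)
      if (!cfg$avoid_satellite_windows || j == 1L) break
      prev <- seq_len(j - 1L)
      near <- prev[abs(rt[prev] - cand_rt) < guard_rt]
      if (!length(near)) break
      d <- abs(cand_mz - mz[near])  # windows are positive offsets: |diff| covers both directions
      in_win <- any(vapply(seq_len(nrow(registry)), function(w) {
        any(d >= registry$low[w] - 0.02 & d <= registry$high[w] + 0.02)
      }, logical(1)))
      if (!in_win) break
    }
    mz[j] <- cand_mz
    rt[j] <- cand_rt
  }

  # per-sample log2 intensities for markers and background
  mu <- stats::runif(n_plain, 8, 24)
  shift <- numeric(n_plain)
  shift[marker_idx] <- cfg$marker_effect
  n_background <- n_plain - cfg$n_markers
  diffuse_pos <- integer()
  if (cfg$diffuse_signal_fraction > 0 && n_background > 0) {
    n_diff <- floor(cfg$diffuse_signal_fraction * n_background)
    diffuse_pos <- cfg$n_markers + sort(sample.int(n_background, n_diff))
    shift[diffuse_pos] <- cfg$diffuse_effect *
      sample(c(-1, 1), n_diff, replace = TRUE)
  }
  L <- matrix(stats::rnorm(n * n_plain, sd = cfg$noise_sd), n, n_plain)
  L <- sweep(L, 2, mu, "+") + outer(labels, shift)

  # satellites: parent log-intensity + dimming constant + small noise
  links <- NULL
  if (n_sat > 0) {
    win_labels <- rep_len(cfg$satellite_window_labels,
                          cfg$n_satellites_per_marker)
    Lsat <- matrix(0, n, n_sat)
    parent_of <- rep(marker_idx, each = cfg$n_satellites_per_marker)
    wl <- rep(list(win_labels), cfg$n_markers)
    wl <- unlist(wl)
    for (s in seq_len(n_sat)) {
      pj <- parent_of[s]
      w <- registry[registry$label == wl[s], ]
      eps <- 1e-6 * (w$high - w$low)
      col <- sat_idx[s]
      mz[col] <- mz[pj] + stats::runif(1, w$low + eps, w$high - eps)
      rt[col] <- max(0, rt[pj] + stats::runif(1, -cfg$rt_jitter_max_s,
                                              cfg$rt_jitter_max_s))
      dim_off <- stats::runif(1, -3, -1)
      Lsat[, s] <- L[, pj] + dim_off +
        stats::rnorm(n, sd = cfg$satellite_noise_sd)
    }
    L <- cbind(L, Lsat)
    links <- data.frame(parent_id = ids[parent_of],
                        satellite_id = ids[sat_idx],
                        window_label = wl, stringsAsFactors = FALSE)
  }

  # batches: round-robin within class; offsets additive in log space
  batches <- NULL
  if (cfg$n_batches > 1) {
    batches <- character(n)
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      batches[idx] <- sprintf("B%d", rep_len(seq_len(cfg$n_batches),
                                             length(idx)))
    }
    off <- matrix(stats::rnorm(cfg$n_batches * p, sd = cfg$batch_effect_sd),
                  cfg$n_batches, p)
    L <- L + off[match(batches, sprintf("B%d", seq_len(cfg$n_batches))), ,
                 drop = FALSE]
  }

  intens <- 2^L
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n * p) < cfg$missing_rate, n, p)
    intens[mask] <- 0
  }
  intens[intens < 1] <- 0

  feats <- data.frame(feature_id = ids, mz = mz, rt = rt,
                      stringsAsFactors = FALSE)
  perm <- sample.int(p)   # shuffle column order; ids travel with columns
  tab <- feature_table(intens[, perm, drop = FALSE], labels = labels,
                       features = feats[perm, , drop = FALSE],
                       sample_ids = sprintf("S%04d", seq_len(n)),
                       batches = batches)
  truth <- structure(
    list(marker_ids = ids[marker_idx],
         satellite_links = links %||%
           data.frame(parent_id = character(), satellite_id = character(),
                      window_label = character(), stringsAsFactors = FALSE),
         diffuse_ids = if (length(diffuse_pos)) ids[diffuse_pos] else character(),
         theoretical_auc = theoretical_auc(abs(cfg$marker_effect),
                                           cfg$noise_sd)),
    class = "ground_truth")
  list(table = tab, truth = truth)
}

#' @method print ground_truth
#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d markers, %d satellite links, %d diffuse features\n",
    length(x$marker_ids), nrow(x$satellite_links), length(x$diffuse_ids)))
  cat(sprintf("  theoretical single-marker AUC: %.4f\n", x$theoretical_auc))
  invisible(x)
}
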