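#' Mass-difference windows for isotope/adduct annotation
#'
#' Returns the windows (Daltons, offsets relative to the assumed
#' \[M-H\]- or \[M+H\]+ ion of a significant feature) used to explain a
#' heavier feature as a putative isotope or adduct. Both modes carry the two
#' 13C isotopologue windows; positive mode adds Na+ and K+ replacement
#' offsets, negative mode Cl- attachment and water loss. Bounds are
#' inclusive. Windows within a mode are pairwise disjoint (asserted).
#'
#' @param mode `"positive"` or `"negative"` ionization.
#' @return data.frame with columns `label`, `low`, `high`, `mode`.
#' @export
window_registry <- function(mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  iso <- data.frame(
    label = c("1x13C", "2x13C"),
    low = c(0.994, 1.998), high = c(1.012, 2.016),
    mode = "both", stringsAsFactors = FALSE)
  extra <- if (mode == "positive") {
    data.frame(label = c("Na+", "K+"),
               low = c(21.975, 37.954), high = c(21.985, 37.962),
               mode = "positive", stringsAsFactors = FALSE)
  } else {
    data.frame(label = c("H2O_loss", "Cl-"),
               low = c(18.006, 35.969), high = c(18.016, 35.985),
               mode = "negative", stringsAsFactors = FALSE)
  }
  reg <- rbind(iso, extra)
  reg <- reg[order(reg$low), ]
  rownames(reg) <- NULL
  stopifnot(all(reg$low < reg$high),
            all(reg$high[-nrow(reg)] < reg$low[-1]))  # disjoint
  reg
}

#' Explain features as putative isotopes/adducts of significant features
#'
#' For every significant "parent" feature, any other feature is linked as a
#' putative isotope or adduct when the retention times are strictly less
#' than `rt_gate_s` apart and the mass difference `mz_child - mz_parent` is
#' non-zero and lies inside one of the mode's windows (inclusive bounds).
#' Only positive offsets are tested: a feature lighter than the parent is
#' never explained by it. Following the use of such maps for non-significant
#' feature accounting, children are restricted to non-significant features
#' by default; `children = "all"` keeps every gated link for diagnostics.
#'
#' @param table a [feature_table()] (or normalized table) carrying mz/rt.
#' @param sig a significance table from [significance_on_training_fold()],
#'   aligned to `table`'s features.
#' @param mode ionization mode for [window_registry()].
#' @param rt_gate_s retention-time gate in seconds (strict `<`).
#' @param children `"nonsignificant"` (default) or `"all"`.
#' @return object of class `explanation_map`: `links` data.frame
#'   `(parent_id, child_id, window_label)`, `explained_ids` (unique
#'   children), `fraction_explained` of non-significant features.
#' @export
explain_features <- function(table, sig, mode = c("positive", "negative"),
                             rt_gate_s = 15,
                             children = c("nonsignificant", "all")) {
  mode <- match.arg(mode)
  children <- match.arg(children)
  feats <- table$features
  check_that(!is.null(feats) && all(c("mz", "rt") %in% names(feats)) &&
               !anyNA(feats$mz) && !anyNA(feats$rt),
             "table", "features must carry complete mz and rt metadata")
  check_that(identical(as.character(sig$feature_id), feats$feature_id),
             "sig", "must be aligned to the table's features")
  reg <- window_registry(mode)
  parents <- which(sig$significant)
  eligible <- if (children == "nonsignificant") !sig$significant else
    rep(TRUE, nrow(feats))
  out <- vector("list", length(parents))
  for (k in seq_along(parents)) {
    i <- parents[k]
    d_mz <- feats$mz - feats$mz[i]
    d_rt <- abs(feats$rt - feats$rt[i])
    hit <- rep(NA_character_, nrow(feats))
    for (w in seq_len(nrow(reg))) {
      # bounds inclusive at the printed precision; the 1e-9 Da guard keeps
      # binary floating-point representation from excluding exact bounds
      in_w <- d_mz >= reg$low[w] - 1e-9 & d_mz <= reg$high[w] + 1e-9
      hit[in_w] <- reg$label[w]
    }
    ok <- !is.na(hit) & d_rt < rt_gate_s & d_mz != 0 & eligible
    ok[i] <- FALSE
    if (any(ok)) {
      out[[k]] <- data.frame(parent_id = feats$feature_id[i],
                             child_id = feats$feature_id[ok],
                             window_label = hit[ok],
                             stringsAsFactors = FALSE)
    }
  }
  links <- do.call(rbind, out) %||%
    data.frame(parent_id = character(), child_id = character(),
               window_label = character(), stringsAsFactors = FALSE)
  links <- links[order(links$parent_id, links$child_id), , drop = FALSE]
  rownames(links) <- NULL
  explained <- sort(unique(links$child_id))
  n_nonsig <- sum(!sig$significant)
  structure(
    list(links = links, explained_ids = explained,
         fraction_explained = fraction_explained_count(length(explained),
                                                       n_nonsig)),
    class = "explanation_map")
}

fraction_explained_count <- function(n_explained, n_nonsignificant) {
  if (n_nonsignificant == 0) return(0)
  n_explained / n_nonsignificant
}

#' Fraction of non-significant features explained by a map
#'
#' @param map an `explanation_map`.
#' @param n_nonsignificant total number of non-significant features; must be
#'   at least the number of explained features. Defined as 0 when there are
#'   no non-significant features.
#' @return fraction in \[0, 1\].
#' @export
fraction_explained <- function(map, n_nonsignificant) {
  check_that(n_nonsignificant >= length(map$explained_ids),
             "n_nonsignificant", "cannot be below the explained count")
  fraction_explained_count(length(map$explained_ids), n_nonsignificant)
}

#' @method print explanation_map
#' @export
print.explanation_map <- function(x, ...) {
  cat(sprintf("<explanation_map> %d links, %d explained features (%.1f%% of non-significant)\n",
              nrow(x$links), length(x$explained_ids),
              100 * x$fraction_explained))
  invisible(x)
}
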