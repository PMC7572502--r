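# Independent oracles, deliberately written from first principles and kept
# separate from the package's implementation paths.

# Benjamini-Hochberg step-up, brute force from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, clipped at 1, in input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
# U counts (x, y) pairs with x > y (ties 1/2).
oracle_mwu_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

oracle_mwu_exact_p <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  u_obs <- oracle_mwu_u(x, y)
  picks <- utils::combn(length(z), n1)
  u_all <- apply(picks, 2, function(ix) oracle_mwu_u(z[ix], z[-ix]))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Mean-rank percentile of a query within a control set, by direct counting.
oracle_percentile <- function(q, controls) {
  100 * (sum(controls < q) + 0.5 * sum(controls == q)) / length(controls)
}

# a small fully in-code feature table for unit tests
make_tiny_table <- function(intensities, labels, batches = NULL,
                            mz = NULL, rt = NULL) {
  p <- ncol(intensities)
  feature_table(
    intensities, labels = labels,
    features = data.frame(feature_id = sprintf("ft%02d", seq_len(p)),
                          mz = mz %||% (100 + seq_len(p)),
                          rt = rt %||% (60 * seq_len(p))),
    sample_ids = sprintf("s%02d", seq_len(nrow(intensities))),
    batches = batches)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
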