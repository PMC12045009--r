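# Independent oracles the implementation is checked against.

# exhaustive K=2 grid search over simplex directions (p, 1-p), profiling
# out the nonnegative overall scale c in min_c ||c * Z d - y||: estimated
# proportions are invariant to bulk scale, so the oracle must be too
grid_search_k2 <- function(Z, y, step = 1e-4) {
  p <- seq(0, 1, by = step)
  ss <- vapply(p, function(pi) {
    zd <- Z %*% c(pi, 1 - pi)
    c_opt <- max(0, sum(zd * y) / sum(zd * zd))
    sum((c_opt * zd - y)^2)
  }, numeric(1))
  p[which.min(ss)]
}

# brute-force mean-ratio definition: per gene, target mean over the
# maximum of the other types' means
brute_force_mean_ratio <- function(means, target) {
  out <- numeric(nrow(means))
  for (g in seq_len(nrow(means))) {
    tgt <- means[g, target]
    denom <- -Inf
    for (k in colnames(means)) if (k != target)
      denom <- max(denom, means[g, k])
    out[g] <- if (denom > 0) tgt / denom else if (tgt > 0) Inf else 0
  }
  stats::setNames(out, rownames(means))
}
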