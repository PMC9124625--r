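# Independent oracles, kept deliberately naive.

# Definitional near-maximum oracle: the largest in-mask dose d such that the
# volume receiving >= d is at least v (checked by direct counting over the
# distinct dose values).
oracle_dmax <- function(doses, voxel_cc, v) {
  if (v == 0) return(max(doses))
  cand <- sort(unique(doses), decreasing = TRUE)
  for (d in cand) {
    if (sum(doses >= d) * voxel_cc >= v) return(d)
  }
  min(doses)
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (no ties, no zeros), matching the classical exact convention:
# double the smaller tail, capped at 1.
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12, !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  tdist <- as.vector(signs %*% rk)
  tobs <- sum(rk[d > 0])
  lo <- mean(tdist <= tobs)
  hi <- mean(tdist >= tobs)
  min(1, 2 * min(lo, hi))
}

# Brute-force cumulative DVH counting at given bin doses.
oracle_dvh_counts <- function(doses, voxel_cc, bins)
  vapply(bins, function(b) sum(doses >= b) * voxel_cc, numeric(1))
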