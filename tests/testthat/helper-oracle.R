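# Independent brute-force oracles. These deliberately avoid the package's
# partition bookkeeping: every quantity is recomputed from the raw histogram
# at every step (no caching, no incremental updates).

oracle_energy <- function(h, lo, hi) {
  if (lo == hi) return(0)  # single support point: zero variance exactly
  g <- lo:hi
  p <- h$probs[g + 1L]
  w <- sum(p)
  if (w == 0) return(0)
  mu <- sum(g * p) / w
  w * (sum((g - mu)^2 * p) / w)
}

# No-cache reimplementation of the merge loop: all region energies are
# recomputed from scratch in every iteration. Same selection rules as the
# package (min energy, ties to smallest lo; absorb the smaller-energy
# neighbour, ties left; boundary regions take their only neighbour).
oracle_merge <- function(h, T) {
  lo <- 0:255
  hi <- 0:255
  steps <- vector("list", 255L - T)
  for (it in seq_len(255L - T)) {
    n <- length(lo)
    en <- vapply(seq_len(n), function(k) oracle_energy(h, lo[k], hi[k]),
                 numeric(1))
    k <- which(en == min(en))[1L]
    j <- if (k == 1L) 2L
         else if (k == n) n - 1L
         else if (en[k - 1L] <= en[k + 1L]) k - 1L else k + 1L
    a <- min(k, j); b <- max(k, j)
    steps[[it]] <- data.frame(
      iteration = it,
      selected_lo = lo[k], selected_hi = hi[k],
      neighbor_lo = lo[j], neighbor_hi = hi[j],
      merged_lo = lo[a], merged_hi = hi[b],
      merged_energy = oracle_energy(h, lo[a], hi[b])
    )
    hi[a] <- hi[b]
    lo <- lo[-b]
    hi <- hi[-b]
  }
  list(thresholds = hi[-length(hi)], trace = do.call(rbind, steps))
}

# thresholds the oracle state would report after stopping at T thresholds:
# prefix of the same run, reconstructed by replaying the trace
oracle_thresholds_at <- function(h, trace, T) {
  lo <- 0:255
  hi <- 0:255
  for (it in seq_len(255L - T)) {
    b_lo <- trace$neighbor_lo[it]
    s_lo <- trace$selected_lo[it]
    a <- which(lo == min(s_lo, b_lo))
    b <- a + 1L
    hi[a] <- hi[b]
    lo <- lo[-b]
    hi <- hi[-b]
  }
  hi[-length(hi)]
}

# Textbook single-threshold Otsu: scan all 255 candidate thresholds,
# maximizing between-class variance computed from first principles.
oracle_otsu_scan <- function(h) {
  g <- 0:255
  muG <- sum(g * h$probs)
  best_t <- -1L
  best_v <- -Inf
  for (t in 0:254) {
    p0 <- h$probs[1:(t + 1)]
    p1 <- h$probs[(t + 2):256]
    w0 <- sum(p0); w1 <- sum(p1)
    v <- 0
    if (w0 > 0) v <- v + w0 * (sum(0:t * p0) / w0 - muG)^2
    if (w1 > 0) v <- v + w1 * (sum((t + 1):255 * p1) / w1 - muG)^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  list(threshold = best_t, bcv = best_v)
}
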