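# Fixtures built in code; no files on disk.

# the 4-level hand-worked histogram: counts (2, 2, 1, 3) on grays 0..3
hand_hist <- function() {
  gray_histogram(c(2, 2, 1, 3, rep(0, 252)))
}

# random 256-bin histogram; lambda > ~30 gives strictly positive counts
# (no exact energy ties away from zero), small lambda stresses empty bins
random_histogram <- function(seed, lambda = 5) {
  withr::with_seed(seed, {
    counts <- rpois(256, lambda)
    if (sum(counts) == 0) counts[1] <- 1
    gray_histogram(counts)
  })
}
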