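test_that("apply_thresholds follows the inclusive-left boundary rule", {
  expect_equal(apply_thresholds(matrix(c(0, 255), 1), 127),
               matrix(c(0L, 1L), 1))
  # g <= t is class 0
  expect_equal(apply_thresholds(matrix(10, 2, 2), 10), matrix(0L, 2, 2))
  img <- matrix(c(0, 0, 1, 1, 2, 3, 3, 3), 2, 4)
  lab <- apply_thresholds(img, 1)
  expect_equal(as.vector(table(lab)), c(4L, 4L))
  lab2 <- apply_thresholds(img, c(0, 1))
  expect_equal(as.vector(table(lab2)), c(2L, 2L, 4L))
  expect_equal(max(lab2), 2L)  # classes 0..P

  expect_error(apply_thresholds(img, c(3, 2)), "increasing")
  expect_error(apply_thresholds(img, c(2, 2)), "increasing")
  expect_error(apply_thresholds(img, 300), "\\[0, 254\\]")
})

test_that("uniformity matches the hand-worked value and its degenerate cases", {
  img <- matrix(c(0, 0, 1, 1, 2, 3, 3, 3), 2, 4)
  # P = 2: within-class squared deviations sum to 0.75, N = 8, range^2 = 9
  expect_equal(uniformity_U(img, c(0, 1)), 1 - 2 * 0.75 / 72, tolerance = 1e-12)
  # P = 1: prefactor 2(P-1) = 0 under the default reading
  expect_equal(uniformity_U(img, 1), 1)
  # piecewise-constant classes are perfectly uniform for any prefactor
  pc <- matrix(c(10, 10, 200, 200), 2, 2)
  for (pref in c("2(P-1)", "2sqrtP", "2P-1"))
    expect_equal(uniformity_U(pc, c(50, 150), prefactor = pref), 1)

  expect_error(uniformity_U(matrix(5, 2, 2), 10), "zero gray range")
})

test_that("prefactor variants scale the same within-class sum", {
  img <- matrix(c(0, 0, 1, 1, 2, 3, 3, 3), 2, 4)
  base <- (1 - uniformity_U(img, c(0, 1))) / 2          # s / (N range^2)
  expect_equal(1 - uniformity_U(img, c(0, 1), prefactor = "2sqrtP"),
               2 * sqrt(2) * base, tolerance = 1e-12)
  expect_equal(1 - uniformity_U(img, c(0, 1), prefactor = "2P-1"),
               3 * base, tolerance = 1e-12)
})

test_that("uniformity is label-permutation invariant and never exceeds 1", {
  fx <- synth_image(fixture_modes("three_mode"), c(64, 64), seed = 8)
  thr <- c(88L, 162L)
  lab <- apply_thresholds(fx$image, thr)
  u <- uniformity_U(fx$image, thr, labels = lab)
  expect_lte(u, 1)
  relab <- matrix(c(5L, 0L, 9L)[lab + 1L], nrow(lab))  # arbitrary relabelling
  expect_equal(uniformity_U(fx$image, thr, labels = relab), u)
})

test_that("injecting within-class noise never increases uniformity", {
  fx <- synth_image(fixture_modes("two_mode"), c(64, 64), seed = 4)
  img <- fx$image
  thr <- 125L
  u0 <- uniformity_U(img, thr)
  for (seed in 1:5) {
    noisy <- withr::with_seed(seed, {
      lab <- apply_thresholds(img, thr)
      # push pixels away from their class mean without crossing the threshold
      mu <- tapply(as.numeric(img), lab, mean)
      delta <- sample(0:6, length(img), replace = TRUE)
      away <- ifelse(as.numeric(img) >= mu[as.character(lab)], delta, -delta)
      v <- as.numeric(img) + away
      v <- ifelse(lab == 0, pmin(v, thr), pmax(v, thr + 1))
      matrix(as.integer(pmin(255, pmax(0, v))), nrow(img))
    })
    expect_identical(apply_thresholds(noisy, thr),
                     apply_thresholds(img, thr))
    expect_lte(uniformity_U(noisy, thr), u0 + 1e-12)
  }
})

test_that("segment_gray ties thresholds, labels and uniformity together", {
  fx <- synth_image(fixture_modes("two_mode"), c(64, 64), seed = 2)
  seg_m <- segment_gray(fx$image, T = 1, method = "merge")
  seg_o <- segment_gray(fx$image, T = 1, method = "otsu")
  for (seg in list(seg_m, seg_o)) {
    expect_length(seg$thresholds, 1)
    expect_identical(seg$labels, apply_thresholds(fx$image, seg$thresholds))
    expect_lte(seg$uniformity, 1)
  }
  # histogram input: thresholds only
  seg_h <- segment_gray(build_histogram(fx$image), T = 1, method = "merge")
  expect_identical(seg_h$thresholds, seg_m$thresholds)
  expect_null(seg_h$labels)
  expect_true(is.na(seg_h$uniformity))
})
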