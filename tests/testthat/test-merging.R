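test_that("initialization yields 256 zero-energy singletons covering [0,255]", {
  h <- hand_hist()
  p <- initialize_partition(h)
  expect_equal(n_regions(p), 256)
  expect_true(all(p$lo == p$hi))
  expect_equal(p$energy, rep(0, 256))
  expect_equal(thresholds_from_partition(p), 0:254)
  expect_equal(p$omega[1], 1 / 8 * 2)
  expect_equal(sum(p$omega), 1, tolerance = 1e-12)
  validate_partition(p, recompute = TRUE)

  # point mass: one region holds everything
  pm <- initialize_partition(gray_histogram(c(1, rep(0, 255))))
  expect_equal(pm$omega[1], 1)
  expect_equal(sum(pm$omega[-1]), 0)
})

test_that("minimum-energy selection breaks ties toward the lowest gray", {
  h <- hand_hist()
  p <- initialize_partition(h)
  expect_equal(select_min_energy_region(p), 1)  # all energies tied at 0

  # unique minimum
  p$energy <- c(0.5, 0.1, 0.9, rep(1, 253))
  expect_equal(select_min_energy_region(p), 2)
  # tie among nonzero energies
  p$energy <- c(0.0625, 0, 0, rep(1, 253))
  expect_equal(select_min_energy_region(p), 2)
})

test_that("the absorbed neighbour is the lower-energy one, ties to the left", {
  h <- hand_hist()
  p <- initialize_partition(h)
  p$energy <- c(0.0625, 1, 0, rep(2, 253))
  expect_equal(choose_merge_neighbor(p, 2), 3)    # right is smaller
  p$energy <- c(0, 1, 0.5, rep(2, 253))
  expect_equal(choose_merge_neighbor(p, 2), 1)    # left is smaller
  p$energy[c(1, 3)] <- 0.5                        # tie -> left
  expect_equal(choose_merge_neighbor(p, 2), 1)
  expect_equal(choose_merge_neighbor(p, 1), 2)    # boundary regions
  expect_equal(choose_merge_neighbor(p, 256), 255)
})

test_that("merge_once reproduces the hand-simulated first two iterations", {
  h <- hand_hist()
  p <- initialize_partition(h)

  m1 <- merge_once(p)
  expect_equal(m1$step$selected_lo, 0)
  expect_equal(m1$step$neighbor_lo, 1)
  expect_equal(m1$step$merged_lo, 0)
  expect_equal(m1$step$merged_hi, 1)
  expect_equal(m1$step$merged_energy, 0.125)
  expect_equal(n_regions(m1$partition), 255)

  m2 <- merge_once(m1$partition)
  expect_equal(m2$step$selected_lo, 2)   # min D = 0, lowest gray
  expect_equal(m2$step$neighbor_lo, 3)   # right neighbour D 0 < left 0.125
  expect_equal(m2$step$merged_hi, 3)
  expect_equal(m2$step$merged_energy, 0.09375)

  # conservation after each merge
  expect_equal(sum(m2$partition$omega), 1, tolerance = 1e-12)
  validate_partition(m2$partition, recompute = TRUE)
})

test_that("run_merging removes exactly one threshold per iteration", {
  h <- random_histogram(7)
  for (T in c(1, 3, 100, 254)) {
    res <- run_merging(h, T)
    expect_length(res$thresholds, T)
    expect_equal(nrow(res$trace), 255 - T)
    expect_equal(res$iterations, 255 - T)
    expect_equal(n_regions(res$partition), T + 1)
    expect_true(!is.unsorted(res$thresholds, strictly = TRUE))
    # every step merges adjacent intervals
    tr <- res$trace
    adjacent <- (tr$selected_hi + 1 == tr$neighbor_lo) |
                (tr$neighbor_hi + 1 == tr$selected_lo)
    expect_true(all(adjacent))
  }
  expect_error(run_merging(h, 0), "invalid threshold count")
  expect_error(run_merging(h, 255), "invalid threshold count")
})

test_that("run_merging isolates the populated support on the embedded 4-level histogram", {
  res <- run_merging(hand_hist(), T = 1)
  expect_equal(res$thresholds, 1L)  # single threshold between gray 1 and 2
})

test_that("merging is deterministic and audit-clean", {
  h <- random_histogram(42)
  a <- run_merging(h, 4, audit = TRUE)
  b <- run_merging(h, 4)
  expect_identical(a$thresholds, b$thresholds)
  expect_identical(a$trace, b$trace)
})

test_that("energy-evaluation count is linear in the gray-level count, not in T", {
  h <- random_histogram(9)
  evals <- vapply(c(1, 2, 5, 50, 254),
                  function(T) run_merging(h, T)$energy_evals, numeric(1))
  expect_true(all(evals <= 2 * 256))
  expect_equal(evals, 256 + (255 - c(1, 2, 5, 50, 254)))
})

test_that("the no-cache oracle produces an identical trace and thresholds", {
  for (seed in 1:3) {
    h <- random_histogram(seed, lambda = if (seed %% 2) 3 else 40)
    impl <- run_merging(h, 1)
    orc <- oracle_merge(h, 1)
    expect_identical(impl$trace[, colnames(orc$trace)], orc$trace)
    expect_identical(as.integer(impl$thresholds), as.integer(orc$thresholds))
  }
})

test_that("merge trace exports to CSV with one row per iteration", {
  res <- run_merging(random_histogram(5), 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(res, f)
  tr <- read.csv(f)
  expect_equal(nrow(tr), 252)
  expect_named(tr, c("iteration", "selected_lo", "selected_hi",
                     "neighbor_lo", "neighbor_hi", "merged_energy"))
})
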