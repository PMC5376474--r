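#' Select the region with minimum energy
#'
#' Returns the index of a region whose energy D equals the minimum over all
#' current regions. Ties are broken by the smallest starting gray level
#' (i.e., the first such region in gray-level order), which keeps the whole
#' merge sequence deterministic.
#'
#' @param p a `gray_partition` with at least two regions.
#' @return integer region index (1-based).
#' @export
select_min_energy_region <- function(p) {
  stopifnot(inherits(p, "gray_partition"))
  if (n_regions(p) < 2L) stop("nothing to merge: partition has a single region")
  which.min(p$energy)
}

#' Choose which neighbour absorbs the selected region
#'
#' The selected region merges with the adjacent region of smaller energy;
#' with both neighbour energies equal, the left neighbour is used. Regions at
#' the gray-level boundaries (containing 0 or 255) have a single neighbour
#' and merge with it unconditionally.
#'
#' @param p a `gray_partition` with at least two regions.
#' @param k index of the selected region.
#' @return integer index of the neighbour to merge with.
#' @export
choose_merge_neighbor <- function(p, k) {
  stopifnot(inherits(p, "gray_partition"))
  n <- n_regions(p)
  if (n < 2L) stop("nothing to merge: partition has a single region")
  if (k < 1L || k > n) stop("invalid region index")
  if (k == 1L) return(2L)
  if (k == n) return(n - 1L)
  if (p$energy[k - 1L] <= p$energy[k + 1L]) k - 1L else k + 1L
}

#' Perform one merge iteration
#'
#' Selects the minimum-energy region, merges it with its chosen neighbour,
#' and replaces the pair by a single region whose statistics are computed
#' fresh from the histogram over the union interval. Exactly one threshold is
#' removed. All other regions are untouched: a merge cannot change any other
#' region's mass, mean or variance, so only the merged region's energy is
#' (re)computed — this is what keeps the total work linear in the number of
#' gray levels.
#'
#' @param p a `gray_partition` with at least two regions.
#' @return list with `partition` (one region fewer) and `step`, a one-row
#'   data frame recording the merge: `selected_lo`, `selected_hi`,
#'   `neighbor_lo`, `neighbor_hi`, `merged_lo`, `merged_hi`, `merged_energy`.
#' @export
merge_once <- function(p) {
  k <- select_min_energy_region(p)
  j <- choose_merge_neighbor(p, k)
  a <- min(k, j); b <- max(k, j)
  r <- region_stats(p$histogram, p$lo[a], p$hi[b])
  step <- data.frame(
    selected_lo = p$lo[k], selected_hi = p$hi[k],
    neighbor_lo = p$lo[j], neighbor_hi = p$hi[j],
    merged_lo = r$lo, merged_hi = r$hi,
    merged_energy = r$energy
  )
  keep <- seq_len(n_regions(p))[-b]
  p$lo <- p$lo[keep]; p$hi <- p$hi[keep]
  p$omega <- p$omega[keep]; p$mu <- p$mu[keep]
  p$sigma2 <- p$sigma2[keep]; p$energy <- p$energy[keep]
  p$lo[a] <- r$lo; p$hi[a] <- r$hi
  p$omega[a] <- r$omega; p$mu[a] <- r$mu
  p$sigma2[a] <- r$sigma2; p$energy[a] <- r$energy
  p$energy_evals <- p$energy_evals + 1L
  list(partition = p, step = step)
}

#' Run the histogram region-merging loop
#'
#' The core algorithm: the histogram is initialized to 256 singleton regions
#' and, at each iteration, the region with minimum energy
#' \eqn{D_k = \omega_k\sigma_k^2} is merged into the lower-energy adjacent
#' region, removing one threshold, until `T` thresholds remain. A full run
#' therefore performs exactly `255 - T` iterations, and at most 255 — the
#' iteration count does not grow with `T`, which is what makes the method
#' linear in the number of gray levels where exhaustive multilevel
#' thresholding is combinatorial.
#'
#' @param h a [gray_histogram()] (or anything accepted by
#'   [build_histogram()] when `h` is an image matrix).
#' @param T requested number of thresholds, in `[1, 254]`.
#' @param audit if `TRUE`, re-verify every cached region statistic against a
#'   fresh [region_stats()] recomputation after every iteration (slow; for
#'   testing on small instances).
#' @return an object of class `merge_result`: list with
#'   \describe{
#'     \item{thresholds}{strictly increasing integer vector of length `T`}
#'     \item{partition}{the final `gray_partition` (`T + 1` regions)}
#'     \item{trace}{data frame, one row per iteration (`iteration`,
#'       `selected_lo/hi`, `neighbor_lo/hi`, `merged_lo/hi`,
#'       `merged_energy`)}
#'     \item{iterations}{`255 - T`}
#'     \item{energy_evals}{total region-energy evaluations performed
#'       (256 at initialization plus one per merge, so at most 511)}
#'   }
#' @export
#' @examples
#' h <- gray_histogram(c(2, 2, 1, 3, rep(0, 252)))
#' run_merging(h, T = 1)$thresholds
run_merging <- function(h, T, audit = FALSE) {
  if (is.matrix(h)) h <- build_histogram(h)
  stopifnot(inherits(h, "gray_histogram"))
  T <- as.integer(T)
  if (length(T) != 1L || is.na(T) || T < 1L || T > 254L)
    stop("invalid threshold count: T must be in [1, 254]")
  p <- initialize_partition(h)
  n_steps <- 255L - T
  # preallocated trace columns; the loop body mirrors merge_once() without
  # the per-step data-frame overhead
  sel_lo <- sel_hi <- nb_lo <- nb_hi <- mg_lo <- mg_hi <- integer(n_steps)
  mg_en <- numeric(n_steps)
  for (it in seq_len(n_steps)) {
    k <- select_min_energy_region(p)
    j <- choose_merge_neighbor(p, k)
    a <- min(k, j); b <- max(k, j)
    r <- region_stats(p$histogram, p$lo[a], p$hi[b])
    sel_lo[it] <- p$lo[k]; sel_hi[it] <- p$hi[k]
    nb_lo[it] <- p$lo[j]; nb_hi[it] <- p$hi[j]
    mg_lo[it] <- r$lo; mg_hi[it] <- r$hi; mg_en[it] <- r$energy
    keep <- seq_len(n_regions(p))[-b]
    p$lo <- p$lo[keep]; p$hi <- p$hi[keep]
    p$omega <- p$omega[keep]; p$mu <- p$mu[keep]
    p$sigma2 <- p$sigma2[keep]; p$energy <- p$energy[keep]
    p$lo[a] <- r$lo; p$hi[a] <- r$hi
    p$omega[a] <- r$omega; p$mu[a] <- r$mu
    p$sigma2[a] <- r$sigma2; p$energy[a] <- r$energy
    p$energy_evals <- p$energy_evals + 1L
    if (audit) validate_partition(p, recompute = TRUE, tol = 1e-9)
  }
  trace <- data.frame(
    iteration = seq_len(n_steps),
    selected_lo = sel_lo, selected_hi = sel_hi,
    neighbor_lo = nb_lo, neighbor_hi = nb_hi,
    merged_lo = mg_lo, merged_hi = mg_hi,
    merged_energy = mg_en
  )
  structure(
    list(thresholds = thresholds_from_partition(p),
         partition = p,
         trace = trace,
         iterations = n_steps,
         energy_evals = p$energy_evals),
    class = "merge_result"
  )
}

#' @export
print.merge_result <- function(x, ...) {
  cat("Histogram region merging:", x$iterations, "iterations,",
      x$energy_evals, "energy evaluations\n")
  cat("thresholds:", paste(x$thresholds, collapse = ", "), "\n")
  invisible(x)
}

#' Write a merge trace to CSV
#'
#' One row per iteration: `iteration`, `selected_lo`, `selected_hi`,
#' `neighbor_lo`, `neighbor_hi`, `merged_energy`.
#'
#' @param result a `merge_result` from [run_merging()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  stopifnot(inherits(result, "merge_result"))
  cols <- c("iteration", "selected_lo", "selected_hi",
            "neighbor_lo", "neighbor_hi", "merged_energy")
  utils::write.csv(result$trace[, cols], path, row.names = FALSE)
  invisible(path)
}
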