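#' Initialize the singleton partition
#'
#' Starts the merge loop: every gray level 0..255 is its own region, so the
#' partition has 256 regions and 255 thresholds. Singleton regions have zero
#' variance, hence zero energy.
#'
#' @param h a [gray_histogram()].
#' @return an object of class `gray_partition`: parallel vectors `lo`, `hi`,
#'   `omega`, `mu`, `sigma2`, `energy` (one element per region, in gray-level
#'   order), the histogram, and `energy_evals`, a running count of region
#'   energy evaluations (256 at initialization, +1 per merge).
#' @export
initialize_partition <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  g <- 0:255
  structure(
    list(lo = g, hi = g,
         omega = h$probs, mu = as.numeric(g),
         sigma2 = numeric(256L), energy = numeric(256L),
         histogram = h,
         energy_evals = 256L),
    class = "gray_partition"
  )
}

#' Number of regions in a partition
#' @param p a `gray_partition`.
#' @return integer region count.
#' @export
n_regions <- function(p) length(p$lo)

#' @export
print.gray_partition <- function(x, ...) {
  cat("gray_partition:", n_regions(x), "regions,",
      n_regions(x) - 1L, "thresholds\n")
  invisible(x)
}

#' Read thresholds off a partition's internal boundaries
#'
#' The thresholds are the upper endpoints of all regions but the last:
#' a pixel of gray g belongs to class j when
#' `thresholds[j] < g <= thresholds[j+1]` (class 0: `g <= thresholds[1]`).
#'
#' @param p a `gray_partition`.
#' @return strictly increasing integer vector of length `n_regions(p) - 1`.
#' @export
thresholds_from_partition <- function(p) {
  stopifnot(inherits(p, "gray_partition"))
  n <- n_regions(p)
  if (n < 2L) return(integer(0))
  as.integer(p$hi[-n])
}

#' Check a partition's structural invariants
#'
#' Verifies coverage of \[0, 255\] by adjacent non-overlapping regions, unit
#' total mass, and (optionally) that every cached region statistic matches a
#' fresh [region_stats()] recomputation from the histogram.
#'
#' @param p a `gray_partition`.
#' @param recompute if `TRUE`, audit cached omega/mu/sigma2/energy against
#'   fresh recomputation.
#' @param tol numeric tolerance for the audit comparisons.
#' @return `p`, invisibly; errors on any violation.
#' @export
validate_partition <- function(p, recompute = FALSE, tol = 1e-9) {
  stopifnot(inherits(p, "gray_partition"))
  n <- n_regions(p)
  if (p$lo[1L] != 0L || p$hi[n] != 255L)
    stop("partition does not cover [0, 255]")
  if (n > 1L && any(p$lo[-1L] != p$hi[-n] + 1L))
    stop("regions are not adjacent and gap-free")
  if (any(p$hi < p$lo)) stop("region with hi < lo")
  if (abs(sum(p$omega) - 1) > 1e-9)
    stop("region masses do not sum to 1")
  if (recompute) {
    for (k in seq_len(n)) {
      r <- region_stats(p$histogram, p$lo[k], p$hi[k])
      dev <- max(abs(p$omega[k] - r$omega), abs(p$mu[k] - r$mu),
                 abs(p$sigma2[k] - r$sigma2), abs(p$energy[k] - r$energy))
      if (dev > tol)
        stop(sprintf("cached stats of region [%d, %d] deviate by %g from fresh recomputation",
                     p$lo[k], p$hi[k], dev))
    }
  }
  invisible(p)
}
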