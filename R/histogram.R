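#' Construct a 256-bin gray-level histogram
#'
#' A `gray_histogram` holds the per-level pixel counts of an 8-bit image,
#' the total pixel count \eqn{N = M \times N_c}, and the derived
#' probabilities \eqn{P_i = \mathrm{counts}_i / N}. All region statistics and
#' both segmentation methods operate on this object.
#'
#' @param counts numeric vector of exactly 256 nonnegative integer pixel
#'   counts, one per gray level 0..255.
#' @return an object of class `gray_histogram` with fields `counts`,
#'   `total_pixels` and `probs` (which sum to 1).
#' @seealso [build_histogram()] to tally an image, [read_histogram_txt()] to
#'   read the plain-text histogram format.
#' @export
#' @examples
#' h <- gray_histogram(c(2, 2, 1, 3, rep(0, 252)))
#' h$total_pixels
gray_histogram <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 256L)
    stop("histogram must have exactly 256 bins, got ", length(counts))
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  n <- sum(counts)
  if (n <= 0) stop("histogram is empty (all counts zero)")
  structure(
    list(counts = counts, total_pixels = n, probs = counts / n),
    class = "gray_histogram"
  )
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- which(x$counts > 0) - 1L
  cat("gray_histogram:", format(x$total_pixels, big.mark = ","),
      "pixels, support [", min(nz), ",", max(nz), "],",
      length(nz), "nonempty levels\n")
  invisible(x)
}

#' Tally an 8-bit grayscale image into a histogram
#'
#' @param image matrix (or array/vector) of integer gray levels in 0..255.
#' @return a [gray_histogram()].
#' @export
#' @examples
#' build_histogram(matrix(c(0, 0, 255, 255), 2, 2))
build_histogram <- function(image) {
  v <- as.vector(image)
  if (length(v) == 0) stop("empty input")
  if (anyNA(v) || any(v < 0 | v > 255) || any(v != floor(v)))
    stop("not 8-bit gray: values must be integers in [0, 255]")
  gray_histogram(tabulate(as.integer(v) + 1L, nbins = 256L))
}

#' Statistics of a contiguous gray-level region
#'
#' Computes, for the inclusive gray-level interval `[lo, hi]`, the
#' probability mass \eqn{\omega = \sum_{i=lo}^{hi} P_i}, the mean gray
#' \eqn{\mu = \sum i P_i / \omega}, the variance
#' \eqn{\sigma^2 = \sum (i-\mu)^2 P_i / \omega}, and the region energy
#' \eqn{D = \omega\sigma^2}. Low energy marks a region as carrying little
#' information — little mass, little gray-level change — and therefore as the
#' next merge candidate.
#'
#' Empty regions (\eqn{\omega = 0}) get `mu = (lo + hi)/2` by convention,
#' `sigma2 = 0` and `energy = 0`, keeping every quantity finite and making
#' empty regions maximally mergeable.
#'
#' @param h a [gray_histogram()].
#' @param lo,hi inclusive integer interval bounds, `0 <= lo <= hi <= 255`.
#' @return an object of class `gray_region`: list with `lo`, `hi`, `omega`,
#'   `mu`, `sigma2`, `energy`.
#' @export
#' @examples
#' h <- gray_histogram(c(2, 2, 1, 3, rep(0, 252)))
#' region_stats(h, 0, 1)  # omega 0.5, mu 0.5, sigma2 0.25, energy 0.125
region_stats <- function(h, lo, hi) {
  stopifnot(inherits(h, "gray_histogram"))
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo > hi) stop("invalid interval: lo > hi")
  if (lo < 0L || hi > 255L) stop("interval outside [0, 255]")
  g <- lo:hi
  p <- h$probs[g + 1L]
  omega <- sum(p)
  if (lo == hi) {
    # a single support point has zero variance exactly (no rounding residue)
    mu <- as.numeric(lo)
    sigma2 <- 0
  } else if (omega > 0) {
    mu <- sum(g * p) / omega
    sigma2 <- sum((g - mu)^2 * p) / omega
  } else {
    mu <- (lo + hi) / 2
    sigma2 <- 0
  }
  structure(
    list(lo = lo, hi = hi, omega = omega, mu = mu, sigma2 = sigma2,
         energy = omega * sigma2),
    class = "gray_region"
  )
}

#' @export
print.gray_region <- function(x, ...) {
  cat(sprintf("gray_region [%d, %d]: omega %.6g, mu %.6g, sigma2 %.6g, D %.6g\n",
              x$lo, x$hi, x$omega, x$mu, x$sigma2, x$energy))
  invisible(x)
}

#' Global (full-range) gray variance of a histogram
#'
#' Variance of the whole gray-level distribution; equals between-class plus
#' mass-weighted within-class variance for any partition of \[0, 255\].
#'
#' @param h a [gray_histogram()].
#' @return a single nonnegative number (gray^2).
#' @export
global_variance <- function(h) {
  region_stats(h, 0L, 255L)$sigma2
}
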