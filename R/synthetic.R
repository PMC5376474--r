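#' Specify Gaussian mixture modes for synthetic fixtures
#'
#' Builds and validates the mode table for the synthetic generator, which
#' emulates the multimodal intensity distributions of MR brain images: 2 to 5
#' Gaussian modes on the 8-bit gray axis.
#'
#' @param mean numeric vector of mode means (gray levels, ascending, in
#'   \[0, 255\]).
#' @param sd numeric vector of mode standard deviations (> 0), recycled.
#' @param weight numeric vector of mixing proportions summing to 1, recycled.
#' @return a data frame of class `mode_spec` with columns `mean`, `sd`,
#'   `weight`.
#' @export
#' @examples
#' mode_spec(c(60, 180), sd = 10, weight = 0.5)
mode_spec <- function(mean, sd, weight) {
  k <- length(mean)
  if (k < 2L) stop("at least 2 modes required (no threshold exists otherwise)")
  if (k > 5L) stop("at most 5 modes supported")
  sd <- rep_len(sd, k)
  weight <- rep_len(weight, k)
  if (any(sd <= 0)) stop("mode sds must be positive")
  if (abs(sum(weight) - 1) > 1e-9) stop("mode weights must sum to 1")
  if (is.unsorted(mean, strictly = TRUE))
    stop("mode means must be strictly ascending")
  if (any(mean < 0 | mean > 255)) stop("mode means must lie in [0, 255]")
  structure(data.frame(mean = mean, sd = sd, weight = weight),
            class = c("mode_spec", "data.frame"))
}

#' Canonical benchmark mixtures
#'
#' The two fixture families used throughout the package's tests and the
#' reproduction script, both at exactly 6-sd separation between consecutive
#' mode means — the tightest spacing at which the inter-mode valley is still
#' a well-defined gray-level location (wider spacing empties the valley bins
#' entirely, making any threshold inside the gap equivalent).
#'
#' @param type `"two_mode"` (means 80/170, sd 15, equal weights) or
#'   `"three_mode"` (means 50/125/200, sd 12.5, weights 0.4/0.3/0.3).
#' @return a [mode_spec()].
#' @export
fixture_modes <- function(type = c("two_mode", "three_mode")) {
  type <- match.arg(type)
  switch(type,
         two_mode   = mode_spec(c(80, 170), sd = 15, weight = 0.5),
         three_mode = mode_spec(c(50, 125, 200), sd = 12.5,
                                weight = c(0.4, 0.3, 0.3)))
}

#' Gaussian mixture density on the gray axis
#'
#' @param x gray levels (numeric vector).
#' @param modes a [mode_spec()].
#' @return mixture density values at `x`.
#' @export
mixture_density <- function(x, modes) {
  stopifnot(inherits(modes, "mode_spec"))
  d <- numeric(length(x))
  for (j in seq_len(nrow(modes)))
    d <- d + modes$weight[j] * stats::dnorm(x, modes$mean[j], modes$sd[j])
  d
}

#' Ground-truth valley thresholds of a mixture
#'
#' For each pair of consecutive modes, the integer gray level minimizing the
#' analytic mixture density between the two mode means (ties to the smaller
#' gray). Valleys — not Bayes boundaries — are the ground truth because they
#' are what histogram-shape methods can see; for equal-sd modes the two
#' coincide.
#'
#' @param modes a [mode_spec()].
#' @return integer vector of `nrow(modes) - 1` thresholds.
#' @export
#' @examples
#' valley_thresholds(mode_spec(c(60, 180), 10, 0.5))  # 120
valley_thresholds <- function(modes) {
  stopifnot(inherits(modes, "mode_spec"))
  k <- nrow(modes)
  vapply(seq_len(k - 1L), function(j) {
    grid <- ceiling(modes$mean[j]):floor(modes$mean[j + 1L])
    grid[which.min(mixture_density(grid, modes))]
  }, integer(1))
}

# draw n pixels from the mixture, rounded and clipped to [0, 255]
draw_mixture <- function(n, modes) {
  comp <- sample.int(nrow(modes), n, replace = TRUE, prob = modes$weight)
  g <- round(stats::rnorm(n, modes$mean[comp], modes$sd[comp]))
  as.integer(pmin(255, pmax(0, g)))
}

#' Generate a synthetic MR-like grayscale image
#'
#' Pixels are drawn i.i.d. from the Gaussian mixture, rounded and clipped to
#' \[0, 255\]. The returned ground-truth thresholds are the analytic density
#' valleys from [valley_thresholds()]. The same seed reproduces the same
#' image bit-for-bit; the global RNG state is left untouched.
#'
#' @param modes a [mode_spec()] with 2–5 modes.
#' @param shape integer `c(rows, cols)`; at least 64 x 64 recommended so the
#'   histogram is well populated.
#' @param seed integer seed (optional; without it the current RNG stream is
#'   used).
#' @return an object of class `synthetic_image`: list with `image` (integer
#'   matrix), `thresholds` (ground truth), and `modes`.
#' @export
#' @examples
#' fx <- synth_image(fixture_modes("two_mode"), shape = c(64, 64), seed = 1)
#' fx$thresholds
synth_image <- function(modes, shape = c(128L, 128L), seed = NULL) {
  stopifnot(inherits(modes, "mode_spec"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) stop("invalid shape")
  n <- prod(shape)
  g <- if (is.null(seed)) draw_mixture(n, modes)
       else withr::with_seed(as.integer(seed), draw_mixture(n, modes))
  structure(
    list(image = matrix(g, nrow = shape[1L], ncol = shape[2L]),
         thresholds = valley_thresholds(modes),
         modes = modes),
    class = "synthetic_image"
  )
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat("synthetic_image:", nrow(x$image), "x", ncol(x$image), "pixels,",
      nrow(x$modes), "modes, ground-truth thresholds",
      paste(x$thresholds, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic mixture histogram directly
#'
#' Same sampling model as [synth_image()] but tallied straight into a
#' [gray_histogram()] — the faster fixture for merge-loop tests. Ground-truth
#' valleys come from [valley_thresholds()] on the same `modes`.
#'
#' @param modes a [mode_spec()].
#' @param total_pixels number of pixels to draw (> 0).
#' @param seed integer seed (optional).
#' @return a [gray_histogram()].
#' @export
synth_histogram <- function(modes, total_pixels = 65536L, seed = NULL) {
  stopifnot(inherits(modes, "mode_spec"))
  total_pixels <- as.integer(total_pixels)
  if (is.na(total_pixels) || total_pixels <= 0L)
    stop("total_pixels must be positive")
  g <- if (is.null(seed)) draw_mixture(total_pixels, modes)
       else withr::with_seed(as.integer(seed), draw_mixture(total_pixels, modes))
  gray_histogram(tabulate(g + 1L, nbins = 256L))
}
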