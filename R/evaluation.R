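#' Apply thresholds to an image, producing a label map
#'
#' A pixel of gray g gets class j (0-based) when
#' `thresholds[j] < g <= thresholds[j+1]`, with class 0 for
#' `g <= thresholds[1]` and the last class for `g > thresholds[T]` — the
#' inclusive-left convention used throughout the package.
#'
#' @param image matrix of integer gray levels in 0..255.
#' @param thresholds strictly increasing integer vector in \[0, 254\].
#' @return integer matrix of the same dimensions with class indices
#'   `0 .. length(thresholds)`.
#' @export
#' @examples
#' apply_thresholds(matrix(c(0, 255), 1), thresholds = 127)
apply_thresholds <- function(image, thresholds) {
  thresholds <- check_thresholds(thresholds)
  v <- as.vector(image)
  if (length(v) == 0) stop("empty input")
  if (anyNA(v) || any(v < 0 | v > 255) || any(v != floor(v)))
    stop("not 8-bit gray: values must be integers in [0, 255]")
  lab <- findInterval(v - 0.5, thresholds)
  out <- matrix(as.integer(lab),
                nrow = if (is.matrix(image)) nrow(image) else 1L)
  out
}

#' Segmentation uniformity index U
#'
#' Scores a segmentation by its within-class gray homogeneity relative to the
#' image's dynamic range:
#' \deqn{U = 1 - c(P)\,\frac{\sum_j \sum_{i \in R_j} (f_i - \mu_j)^2}
#'                          {N (f_{max} - f_{min})^2}}
#' where P is the number of thresholds, the outer sum runs over all induced
#' classes R_j, \eqn{f_i} is the gray of pixel i, \eqn{\mu_j} the mean gray of
#' class j, N the pixel count and \eqn{f_{max}}, \eqn{f_{min}} the image's
#' extreme grays. U is at most 1 and larger is better; it equals 1 exactly
#' when every class is internally constant (or the prefactor vanishes).
#'
#' The prefactor c(P) is selectable because published variants of the measure
#' differ: `"2(P-1)"` (default) gives \eqn{2(P-1)}, `"2sqrtP"` the classical
#' \eqn{2\sqrt{P}}, and `"2P-1"` gives \eqn{2P - 1}.
#'
#' @param image matrix of integer gray levels in 0..255; must not be constant
#'   (the dynamic range normalizes the score).
#' @param thresholds strictly increasing integer vector in \[0, 254\].
#' @param labels optional precomputed label map (any labelling inducing the
#'   same pixel grouping gives the same U); defaults to
#'   `apply_thresholds(image, thresholds)`.
#' @param prefactor which prefactor variant to use.
#' @return a single number `<= 1`.
#' @export
#' @examples
#' img <- matrix(c(0, 0, 1, 1, 2, 3, 3, 3), 2, 4)
#' uniformity_U(img, thresholds = c(0, 1))
uniformity_U <- function(image, thresholds, labels = NULL,
                         prefactor = c("2(P-1)", "2sqrtP", "2P-1")) {
  prefactor <- match.arg(prefactor)
  thresholds <- check_thresholds(thresholds)
  f <- as.numeric(image)
  if (length(f) == 0) stop("empty input")
  fmax <- max(f); fmin <- min(f)
  if (fmax == fmin) stop("undefined uniformity (zero gray range)")
  if (is.null(labels)) labels <- apply_thresholds(image, thresholds)
  lab <- as.vector(labels)
  if (length(lab) != length(f)) stop("labels do not match image dimensions")
  mu <- tapply(f, lab, mean)
  s <- sum((f - mu[as.character(lab)])^2)
  P <- length(thresholds)
  cP <- switch(prefactor,
               "2(P-1)" = 2 * (P - 1),
               "2sqrtP" = 2 * sqrt(P),
               "2P-1"   = 2 * P - 1)
  1 - cP * s / (length(f) * (fmax - fmin)^2)
}

#' Segment a grayscale image in one call
#'
#' Front door tying the pieces together: builds the histogram, runs the
#' requested method ([run_merging()] or [otsu_exhaustive()]), applies the
#' thresholds, and scores the result with [uniformity_U()] when an image (not
#' a bare histogram) was supplied.
#'
#' @param x an image matrix of integer grays 0..255, or a
#'   [gray_histogram()] (then no label map or uniformity is produced).
#' @param T requested number of thresholds.
#' @param method `"merge"` (histogram region merging) or `"otsu"`
#'   (exhaustive between-class-variance search, capped at 4 thresholds).
#' @param prefactor uniformity prefactor variant, see [uniformity_U()].
#' @param audit passed to [run_merging()].
#' @return an object of class `segmentation`: list with `method`,
#'   `thresholds`, `labels` (or NULL), `uniformity` (or NA for histogram
#'   input / constant image), and the full method `result` (`merge_result`
#'   or `otsu_result`).
#' @export
#' @examples
#' set.seed(1)
#' img <- matrix(sample(c(40:60, 190:210), 64 * 64, TRUE), 64, 64)
#' segment_gray(img, T = 1, method = "merge")
segment_gray <- function(x, T, method = c("merge", "otsu"),
                         prefactor = "2(P-1)", audit = FALSE) {
  method <- match.arg(method)
  is_image <- is.matrix(x)
  h <- if (is_image) build_histogram(x) else x
  stopifnot(inherits(h, "gray_histogram"))
  res <- switch(method,
                merge = run_merging(h, T, audit = audit),
                otsu  = otsu_exhaustive(h, T))
  thr <- res$thresholds
  labels <- NULL
  u <- NA_real_
  if (is_image) {
    labels <- apply_thresholds(x, thr)
    if (max(x) > min(x))
      u <- uniformity_U(x, thr, labels = labels, prefactor = prefactor)
  }
  structure(
    list(method = method, thresholds = thr, labels = labels,
         uniformity = u, result = res),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat("segmentation (", x$method, "): thresholds ",
      paste(x$thresholds, collapse = ", "), sep = "")
  if (!is.na(x$uniformity)) cat(sprintf(", uniformity U = %.4f", x$uniformity))
  cat("\n")
  invisible(x)
}
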