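#' Exhaustive multilevel Otsu thresholding
#'
#' Reference comparator: finds the threshold tuple maximizing the
#' between-class variance \eqn{\sum_k \omega_k (\mu_k - \mu_G)^2} by
#' exhaustive search over all strictly increasing `T`-tuples in \[0, 254\].
#' The search space has `choose(255, T)` candidates, so the cost grows
#' combinatorially with `T`; the default cap of 4 thresholds keeps a run in
#' the seconds range. Ties are broken to the lexicographically smallest
#' tuple. Class conventions match [run_merging()] (class k covers grays
#' `t[k-1]+1 .. t[k]`), so threshold lists from the two methods are directly
#' comparable.
#'
#' @param h a [gray_histogram()] or an image matrix.
#' @param T number of thresholds, `1 <= T <= cap`.
#' @param cap maximum `T` accepted by the exhaustive search (default 4).
#' @return an object of class `otsu_result`: list with `thresholds`
#'   (increasing integer vector), `between_class_variance` (gray^2), and
#'   `candidates` (number of tuples evaluated, `choose(255, T)`).
#' @export
#' @examples
#' h <- gray_histogram(c(4, 1, 1, 4, rep(0, 252)))
#' otsu_exhaustive(h, T = 1)  # threshold 1, between-class variance 1.69
otsu_exhaustive <- function(h, T, cap = 4L) {
  if (is.matrix(h)) h <- build_histogram(h)
  stopifnot(inherits(h, "gray_histogram"))
  T <- as.integer(T)
  if (length(T) != 1L || is.na(T) || T < 1L)
    stop("invalid threshold count: T must be a positive integer")
  if (T > cap)
    stop("exhaustive search capped at ", cap,
         " thresholds (cost grows combinatorially); raise `cap` explicitly to override")
  res <- otsu_search_cpp(h$probs, T)
  structure(
    list(thresholds = as.integer(res$thresholds),
         between_class_variance = res$objective,
         candidates = res$candidates),
    class = "otsu_result"
  )
}

#' @export
print.otsu_result <- function(x, ...) {
  cat("Exhaustive Otsu:", format(x$candidates, big.mark = ","),
      "candidate tuples\n")
  cat(sprintf("thresholds: %s (between-class variance %.6g)\n",
              paste(x$thresholds, collapse = ", "), x$between_class_variance))
  invisible(x)
}

#' Between-class variance of a threshold tuple
#'
#' Evaluates Otsu's objective \eqn{\sum_k \omega_k(\mu_k - \mu_G)^2} for one
#' candidate tuple, summing over the `length(thresholds) + 1` classes the
#' tuple induces. Useful for checking the total-variance decomposition:
#' between-class variance plus [within_class_energy()] equals
#' [global_variance()] for every tuple.
#'
#' @param h a [gray_histogram()].
#' @param thresholds strictly increasing integer vector in \[0, 254\].
#' @return a single nonnegative number (gray^2).
#' @export
between_class_variance <- function(h, thresholds) {
  stopifnot(inherits(h, "gray_histogram"))
  check_thresholds(thresholds)
  muG <- region_stats(h, 0L, 255L)$mu
  b <- c(-1L, as.integer(thresholds), 255L)
  s <- 0
  for (k in seq_len(length(b) - 1L)) {
    r <- region_stats(h, b[k] + 1L, b[k + 1L])
    s <- s + r$omega * (r$mu - muG)^2
  }
  s
}

#' Total within-class energy of a threshold tuple
#'
#' \eqn{\sum_k \omega_k \sigma_k^2} over the classes induced by the tuple —
#' the sum of region energies D of the corresponding partition.
#'
#' @inheritParams between_class_variance
#' @return a single nonnegative number (gray^2).
#' @export
within_class_energy <- function(h, thresholds) {
  stopifnot(inherits(h, "gray_histogram"))
  check_thresholds(thresholds)
  b <- c(-1L, as.integer(thresholds), 255L)
  s <- 0
  for (k in seq_len(length(b) - 1L)) {
    s <- s + region_stats(h, b[k] + 1L, b[k + 1L])$energy
  }
  s
}

# shared validation of user-supplied threshold vectors
check_thresholds <- function(thresholds) {
  if (length(thresholds) == 0) stop("no thresholds supplied")
  if (anyNA(thresholds) || any(thresholds != floor(thresholds)))
    stop("thresholds must be integers")
  if (any(thresholds < 0 | thresholds > 254))
    stop("thresholds must lie in [0, 254]")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  invisible(as.integer(thresholds))
}
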