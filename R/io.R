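#' Read an 8-bit grayscale image
#'
#' Supports PNG, TIFF and PGM (both ASCII `P2` and binary `P5`).
#' Multi-channel inputs are rejected — there is no silent RGB-to-gray
#' conversion, because the algorithm is defined on a single 256-level
#' intensity axis.
#'
#' @param path image file; format inferred from the extension
#'   (`.png`, `.tif`/`.tiff`, `.pgm`).
#' @return integer matrix of gray levels 0..255.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png" || ext %in% c("tif", "tiff")) {
    a <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(a)) == 3L && dim(a)[3L] > 1L)
      stop("not 8-bit gray: multi-channel image (", dim(a)[3L],
           " channels); convert to grayscale first")
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    img <- matrix(as.integer(round(a * 255)), nrow = nrow(a))
  } else if (ext == "pgm") {
    img <- read_pgm(path)
  } else {
    stop("unsupported image format: .", ext, " (use PNG, TIFF or PGM)")
  }
  if (any(img < 0L | img > 255L)) stop("not 8-bit gray")
  img
}

# Minimal PGM reader: P2 (ASCII) and P5 (binary), maxval <= 255.
read_pgm <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  nbytes <- length(raw)
  is_space <- function(b) b %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  next_token <- function() {
    repeat {
      while (pos <= nbytes && is_space(raw[pos])) pos <<- pos + 1L
      if (pos <= nbytes && raw[pos] == as.raw(0x23)) {  # '#' comment to EOL
        while (pos <= nbytes && raw[pos] != as.raw(0x0a)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= nbytes && !is_space(raw[pos])) pos <<- pos + 1L
    if (start > nbytes) stop("malformed PGM: truncated header")
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P5")) stop("malformed PGM: bad magic '", magic, "'")
  width <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (anyNA(c(width, height, maxval)) || width < 1L || height < 1L)
    stop("malformed PGM: bad dimensions")
  if (maxval > 255L) stop("not 8-bit gray: PGM maxval ", maxval, " > 255")
  n <- width * height
  if (magic == "P5") {
    pos <- pos + 1L  # single whitespace byte after maxval
    if (pos + n - 1L > nbytes) stop("malformed PGM: truncated pixel data")
    px <- as.integer(raw[pos:(pos + n - 1L)])
  } else {
    txt <- rawToChar(raw[pos:nbytes])
    px <- suppressWarnings(as.integer(scan(text = txt, quiet = TRUE)))
    if (length(px) != n || anyNA(px)) stop("malformed PGM: expected ", n, " pixels")
  }
  if (any(px < 0L | px > maxval)) stop("malformed PGM: pixel above maxval")
  matrix(px, nrow = height, ncol = width, byrow = TRUE)
}

#' Read a histogram from the plain-text format
#'
#' The text format is 256 whitespace- or newline-separated nonnegative
#' integer counts; anything else is rejected.
#'
#' @param path text file path.
#' @return a [gray_histogram()].
#' @export
read_histogram_txt <- function(path) {
  if (!file.exists(path)) stop("cannot read histogram: ", path)
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (length(v) != 256L)
    stop("histogram file must contain exactly 256 values, got ", length(v))
  gray_histogram(v)
}

#' Write a histogram in the plain-text format
#'
#' @param h a [gray_histogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_histogram_txt <- function(h, path) {
  stopifnot(inherits(h, "gray_histogram"))
  writeLines(paste(format(h$counts, scientific = FALSE, trim = TRUE),
                   collapse = " "), path)
  invisible(path)
}

#' Write a label map as an 8-bit grayscale PNG
#'
#' Class indices are stored directly as pixel values, so the image
#' round-trips: reading it back with [read_gray_image()] recovers the exact
#' label matrix.
#'
#' @param labels integer matrix of class indices 0..255.
#' @param path output PNG path.
#' @param rescale if `TRUE`, stretch class indices over 0..255 for a viewable
#'   preview instead of storing raw indices.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(labels, path, rescale = FALSE) {
  m <- labels
  if (rescale && max(m) > 0) m <- round(m * (255 / max(m)))
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Write thresholds (and run metadata) as JSON
#'
#' @param result a `segmentation`, `merge_result` or `otsu_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_thresholds_json <- function(result, path) {
  out <- if (inherits(result, "segmentation")) {
    list(thresholds = result$thresholds, method = result$method,
         iterations = result$result$iterations,
         energy_evals = result$result$energy_evals,
         candidates = result$result$candidates,
         uniformity = if (is.na(result$uniformity)) NULL else result$uniformity)
  } else if (inherits(result, "merge_result")) {
    list(thresholds = result$thresholds, method = "merge",
         iterations = result$iterations, energy_evals = result$energy_evals)
  } else if (inherits(result, "otsu_result")) {
    list(thresholds = result$thresholds, method = "otsu",
         candidates = result$candidates,
         between_class_variance = result$between_class_variance)
  } else stop("unsupported result object")
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
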