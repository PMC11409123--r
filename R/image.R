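#' Min/max normalization of an image to [0, 1]
#'
#' `(x - min) / (max - min)` over all pixels (all channels jointly for 3-D
#' arrays). A constant image maps to all zeros.
#'
#' @param image Numeric matrix (grayscale) or 3-D array (per-channel planes).
#' @return The normalized image, same shape, values in `[0, 1]`.
#' @examples
#' minmax_normalize(matrix(c(0, 127.5, 255, 255), 2))
#' @export
minmax_normalize <- function(image) {
  stopifnot(is.numeric(image), length(image) > 0)
  lo <- min(image)
  hi <- max(image)
  if (hi == lo) return(image * 0)
  (image - lo) / (hi - lo)
}

#' Inject salt-and-pepper noise
#'
#' Each pixel is independently corrupted with probability `density`; a
#' corrupted pixel becomes 0 (pepper) or 1 (salt) with equal probability.
#' Density 0.04 is the corruption level the denoising stage is designed for.
#'
#' @param image Numeric matrix or array with intensities in `[0, 1]`.
#' @param density Corruption probability in `[0, 1]`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return The corrupted image.
#' @export
add_salt_pepper <- function(image, density, seed = NULL) {
  if (!is.numeric(density) || length(density) != 1L ||
      density < 0 || density > 1) {
    fh_stop("density must lie in [0, 1]", "firehawkdr_config_error")
  }
  with_seed(seed, {
    hit <- runif(length(image)) < density
    salt <- runif(length(image)) < 0.5
    out <- image
    out[hit & salt] <- 1
    out[hit & !salt] <- 0
    out
  })
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(1 / MSE)` for images on the `[0, 1]` scale. Identical images
#' report `Inf`.
#'
#' @param reference,test Numeric matrices/arrays of identical shape with
#'   intensities in `[0, 1]`.
#' @return PSNR in decibels.
#' @export
psnr <- function(reference, test) {
  if (!identical(dim(reference), dim(test)) ||
      length(reference) != length(test)) {
    fh_stop("images must have identical shape", "firehawkdr_dimension_error")
  }
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Block-average downsampling
#'
#' Averages non-overlapping `factor x factor` blocks; used to pool images to
#' a small feature vector for the desk-scale classifier.
#'
#' @param image Numeric matrix whose dimensions are divisible by `factor`.
#' @param factor Integer block edge length.
#' @return The pooled matrix.
#' @export
avg_pool <- function(image, factor) {
  stopifnot(is.matrix(image), is_count(factor),
            nrow(image) %% factor == 0, ncol(image) %% factor == 0)
  nr <- nrow(image) %/% factor
  nc <- ncol(image) %/% factor
  ri <- (seq_len(nrow(image)) - 1L) %/% factor
  ci <- (seq_len(ncol(image)) - 1L) %/% factor
  acc <- rowsum(image, ri)
  acc <- t(rowsum(t(acc), ci))
  acc / factor^2
}

#' Block-maximum downsampling
#'
#' Takes the maximum over non-overlapping `factor x factor` blocks. This is
#' the default feature reduction of the classification pipeline: a compact
#' bright-lesion detector, since any exudate inside a block drives that
#' block's feature to the lesion intensity.
#'
#' @inheritParams avg_pool
#' @return The pooled matrix.
#' @export
max_pool <- function(image, factor) {
  stopifnot(is.matrix(image), is_count(factor),
            nrow(image) %% factor == 0, ncol(image) %% factor == 0)
  nr <- nrow(image) %/% factor
  nc <- ncol(image) %/% factor
  out <- matrix(-Inf, nr, nc)
  for (di in seq_len(factor)) for (dj in seq_len(factor)) {
    out <- pmax(out, image[seq(di, nrow(image), by = factor),
                           seq(dj, ncol(image), by = factor), drop = FALSE])
  }
  out
}

#' Read a plain-text PGM (P2) image
#'
#' Minimal reader for the ASCII "portable graymap" format, the text-only
#' raster format the package uses on disk (no PNG codec is assumed to be
#' available). Pixels are returned on the `[0, 1]` scale.
#'
#' @param path File path.
#' @return A numeric matrix in `[0, 1]` (rows = image rows).
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) {
    fh_stop(paste("file not found:", path), "firehawkdr_io_error")
  }
  tokens <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (length(tokens) < 4L || tokens[1] != "P2") {
    fh_stop("not an ASCII PGM (P2) file", "firehawkdr_io_error")
  }
  w <- as.integer(tokens[2])
  h <- as.integer(tokens[3])
  maxval <- as.numeric(tokens[4])
  px <- as.numeric(tokens[-(1:4)])
  if (length(px) != w * h) {
    fh_stop("PGM pixel count does not match header", "firehawkdr_io_error")
  }
  matrix(px, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a plain-text PGM (P2) image
#'
#' @param image Numeric matrix with intensities in `[0, 1]`; quantized to
#'   8 bits on write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path) {
  stopifnot(is.matrix(image))
  q <- round(pmin(pmax(image, 0), 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
  apply(q, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
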