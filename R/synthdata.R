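#' Synthetic fundus image parameters
#'
#' Controls the labeled synthetic fundus-like generator: a radial-gradient
#' retinal disc on a dark background, crossed by dark vessel-like random-walk
#' curves; positive-class (DR) images additionally contain bright exudate
#' blobs and small dark hemorrhage dots inside the disc. Intensities are on
#' `[0, 1]`.
#'
#' @param size Square image side length, `>= 16`; default 64 (desk-scale
#'   stand-in for 224; 224 is accepted).
#' @param vessel_count Number of vessel curves; default 3.
#' @param lesion_count_range Integer interval for the per-lesion-type count
#'   in DR images; default `c(1, 4)` (at least one of each type).
#' @param exudate_intensity Bright-lesion intensity, above the disc
#'   background; default 0.95.
#' @param hemorrhage_intensity Dark-lesion intensity, below the background;
#'   default 0.05.
#' @param dr_fraction Fraction of DR images in a generated dataset, in
#'   (0, 1); default 0.25 (the positive class is the minority, which is what
#'   the SMOTE stage exists to correct).
#' @return An object of class `fundus_params`.
#' @export
fundus_params <- function(size = 64L, vessel_count = 3L,
                          lesion_count_range = c(1L, 4L),
                          exudate_intensity = 0.95,
                          hemorrhage_intensity = 0.05,
                          dr_fraction = 0.25) {
  if (!is_count(size, 16L)) {
    fh_stop("size must be an integer >= 16", "firehawkdr_config_error")
  }
  stopifnot(exudate_intensity <= 1, exudate_intensity > 0.6,
            hemorrhage_intensity >= 0, hemorrhage_intensity < 0.3,
            dr_fraction > 0, dr_fraction < 1,
            length(lesion_count_range) == 2L,
            lesion_count_range[1] >= 1L,
            lesion_count_range[1] <= lesion_count_range[2])
  structure(list(size = as.integer(size),
                 vessel_count = as.integer(vessel_count),
                 lesion_count_range = as.integer(lesion_count_range),
                 exudate_intensity = exudate_intensity,
                 hemorrhage_intensity = hemorrhage_intensity,
                 dr_fraction = dr_fraction),
            class = "fundus_params")
}

# paint a filled disc of given radius/intensity, blended over the image
.paint_disc <- function(img, ci, cj, radius, value) {
  n <- nrow(img)
  ii <- pmax(1L, floor(ci - radius)):pmin(n, ceiling(ci + radius))
  jj <- pmax(1L, floor(cj - radius)):pmin(n, ceiling(cj + radius))
  for (i in ii) for (j in jj) {
    if ((i - ci)^2 + (j - cj)^2 <= radius^2) img[i, j] <- value
  }
  img
}

#' Generate one labeled synthetic fundus-like image
#'
#' @param label 0 (No-DR) or 1 (DR).
#' @param params A [fundus_params()].
#' @param seed Optional integer seed; the image is bit-reproducible given
#'   the seed.
#' @return A `size x size` numeric matrix in `[0, 1]`.
#' @export
generate_fundus_image <- function(label, params = fundus_params(),
                                  seed = NULL) {
  stopifnot(label %in% c(0, 1))
  n <- params$size
  with_seed(seed, {
    center <- (n + 1) / 2
    disc_r <- 0.45 * n
    d <- sqrt(outer((seq_len(n) - center)^2, (seq_len(n) - center)^2, `+`))
    # radial gradient: brighter hub fading toward the rim, dark surround
    img <- ifelse(d <= disc_r, 0.55 - 0.2 * (d / disc_r)^2, 0.05)
    inside <- d <= disc_r * 0.85

    # vessel-like random walks from near the center outward, dark and thin
    for (v in seq_len(params$vessel_count)) {
      i <- center + runif(1, -0.1, 0.1) * n
      j <- center + runif(1, -0.1, 0.1) * n
      ang <- runif(1, 0, 2 * pi)
      for (step in seq_len(round(0.6 * n))) {
        ang <- ang + rnorm(1, 0, 0.3)
        i <- i + sin(ang)
        j <- j + cos(ang)
        ii <- round(i)
        jj <- round(j)
        if (ii < 1 || ii > n || jj < 1 || jj > n) break
        if (d[ii, jj] > disc_r) break
        img[ii, jj] <- 0.2
        if (jj < n) img[ii, jj + 1L] <- 0.2
      }
    }

    if (label == 1) {
      lcr <- params$lesion_count_range
      n_ex <- sample(lcr[1]:lcr[2], 1L)
      n_he <- sample(lcr[1]:lcr[2], 1L)
      spots <- which(inside, arr.ind = TRUE)
      for (e in seq_len(n_ex)) {  # bright exudate blobs
        at <- spots[sample.int(nrow(spots), 1L), ]
        img <- .paint_disc(img, at[1], at[2], runif(1, 1.8, 3.2),
                           params$exudate_intensity)
      }
      for (h in seq_len(n_he)) {  # dark hemorrhage dots
        at <- spots[sample.int(nrow(spots), 1L), ]
        img <- .paint_disc(img, at[1], at[2], runif(1, 1.0, 2.0),
                           params$hemorrhage_intensity)
      }
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Generate a labeled synthetic fundus dataset
#'
#' Produces `round(n * dr_fraction)` DR images and the remainder No-DR,
#' with a manifest mirroring the on-disk layout the CLI writes.
#'
#' @param n Number of images, `>= 10`.
#' @param params A [fundus_params()].
#' @param seed Integer seed; image `i` uses the child seed
#'   `derive_seed(seed, "image/<i>")`.
#' @param dir Optional directory; when given, images are written as ASCII
#'   PGM files and the manifest as `manifest.csv` there.
#' @return A list of class `fundus_dataset`: `images` (list of matrices),
#'   `labels`, `manifest` (data.frame with filename, label, synthetic,
#'   size).
#' @export
generate_dataset <- function(n, params = fundus_params(), seed = 1L,
                             dir = NULL) {
  if (!is_count(n, 10L)) {
    fh_stop("n must be an integer >= 10", "firehawkdr_config_error")
  }
  n_dr <- round(n * params$dr_fraction)
  if (n_dr < 1L || n_dr > n - 1L) {
    fh_stop("dr_fraction leaves a class empty", "firehawkdr_config_error")
  }
  labels <- c(rep(1L, n_dr), rep(0L, n - n_dr))
  images <- lapply(seq_len(n), function(i) {
    generate_fundus_image(labels[i], params,
                          seed = derive_seed(seed, paste0("image/", i)))
  })
  manifest <- data.frame(
    filename = sprintf("fundus_%04d.pgm", seq_len(n)),
    label = labels,
    synthetic = FALSE,
    size = params$size,
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      write_pgm(images[[i]], file.path(dir, manifest$filename[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(images = images, labels = labels, manifest = manifest),
            class = "fundus_dataset")
}

#' Flatten a fundus dataset into a labeled vector set
#'
#' Optionally block-average-pools each image first (the desk-scale feature
#' reduction used before classifier training).
#'
#' @param dataset A `fundus_dataset` (or a list with `images` and `labels`).
#' @param pool Integer pooling factor; 1 keeps full resolution.
#' @param method `"max"` (default; a bright-lesion detector, see
#'   [max_pool()]) or `"mean"`.
#' @return A [labeled_vector_set()].
#' @export
flatten_dataset <- function(dataset, pool = 1L, method = c("max", "mean")) {
  method <- match.arg(method)
  imgs <- dataset$images
  if (pool > 1L) {
    pf <- if (method == "max") max_pool else avg_pool
    imgs <- lapply(imgs, pf, factor = pool)
  }
  labeled_vector_set(do.call(rbind, lapply(imgs, as.vector)),
                     dataset$labels)
}
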