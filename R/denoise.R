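#' Parameters of the fuzzy impulse-noise denoiser
#'
#' The denoiser models three fuzzy intensity sets on `[0, 1]`: a pepper
#' (dark-extreme) set anchored at `t_low`, a salt (bright-extreme) set
#' anchored at `t_high`, and a signal set peaking at mid-gray. A pixel is
#' *noise-flagged* when its extreme-set membership dominates its signal
#' membership *and* it deviates from the median of its window neighbors by
#' more than `delta`; only flagged pixels are ever modified.
#'
#' @param window Odd window edge length `>= 3`; default 3.
#' @param t_low,t_high Extreme-intensity anchors in `[0, 1]` with
#'   `t_low < t_high`; defaults 0.02 and 0.98.
#' @param delta Median-deviation threshold; default 0.4.
#' @param max_iters Maximum detect/restore sweeps; default 3.
#' @return An object of class `wm_params`.
#' @export
wm_params <- function(window = 3L, t_low = 0.02, t_high = 0.98,
                      delta = 0.4, max_iters = 3L) {
  if (!is_count(window, 3L) || window %% 2L == 0L) {
    fh_stop("window must be an odd integer >= 3", "firehawkdr_config_error")
  }
  if (!(t_low >= 0 && t_high <= 1 && t_low < t_high)) {
    fh_stop("need 0 <= t_low < t_high <= 1", "firehawkdr_config_error")
  }
  stopifnot(delta > 0, is_count(max_iters, 1L))
  structure(list(window = as.integer(window), t_low = t_low, t_high = t_high,
                 delta = delta, max_iters = as.integer(max_iters)),
            class = "wm_params")
}

# Triangular memberships of the three fuzzy intensity sets.
.mu_pepper <- function(x, t_low) pmax(0, 1 - x / (2 * t_low))
.mu_salt <- function(x, t_high) pmax(0, 1 - (1 - x) / (2 * (1 - t_high)))
.mu_signal <- function(x) pmax(0, 1 - 2 * abs(x - 0.5))

# Row/col index pairs of the in-image window neighbors of (i, j), center
# excluded.
.window_neighbors <- function(i, j, h, w, half) {
  ri <- max(1L, i - half):min(h, i + half)
  ci <- max(1L, j - half):min(w, j + half)
  idx <- cbind(rep(ri, times = length(ci)), rep(ci, each = length(ri)))
  idx[!(idx[, 1] == i & idx[, 2] == j), , drop = FALSE]
}

#' Fuzzy rule-based salt-and-pepper denoising
#'
#' Iterative detect/restore sweep over a normalized grayscale image:
#' \enumerate{
#'   \item \emph{Fuzzify}: every pixel receives memberships to the pepper,
#'     signal and salt sets (see [wm_params()]).
#'   \item \emph{Detect}: a pixel is flagged as noise when its dominant
#'     extreme membership exceeds its signal membership and it deviates from
#'     the median of its window neighbors by more than `delta`.
#'   \item \emph{Restore}: each flagged pixel is replaced by the
#'     signal-membership-weighted mean of its non-flagged window neighbors;
#'     fallbacks, in order: median of non-flagged neighbors, a 5x5 window
#'     expansion, the global median of non-flagged pixels.
#'   \item \emph{Iterate} until no pixel is flagged or `max_iters` sweeps.
#' }
#' Non-flagged pixels are bit-unchanged, so a clean image passes through
#' identically.
#'
#' @param image Numeric matrix with intensities in `[0, 1]` (a 3-D array is
#'   denoised per channel).
#' @param params A [wm_params()].
#' @return The denoised image with attribute `flag_history`: the integer
#'   vector of flagged-pixel counts per sweep.
#' @examples
#' img <- matrix(0.5, 5, 5)
#' img[3, 3] <- 1                   # lone salt pixel
#' wm_denoise(img)[3, 3]            # restored to 0.5
#' @export
wm_denoise <- function(image, params = wm_params()) {
  if (is.array(image) && length(dim(image)) == 3L) {
    out <- image
    hist <- integer(0)
    for (ch in seq_len(dim(image)[3])) {
      r <- wm_denoise(image[, , ch], params)
      out[, , ch] <- r
      hist <- c(hist, attr(r, "flag_history"))
    }
    attr(out, "flag_history") <- hist
    return(out)
  }
  stopifnot(is.matrix(image))
  h <- nrow(image)
  w <- ncol(image)
  if (h < params$window || w < params$window) {
    fh_stop("image smaller than the denoising window",
            "firehawkdr_dimension_error")
  }
  if (min(image) < 0 || max(image) > 1) {
    fh_stop("denoiser expects a normalized image in [0, 1]",
            "firehawkdr_config_error")
  }
  x <- image
  half <- params$window %/% 2L
  flag_history <- integer(0)

  for (sweep in seq_len(params$max_iters)) {
    mu_ext <- pmax(.mu_pepper(x, params$t_low), .mu_salt(x, params$t_high))
    cand <- which(mu_ext > .mu_signal(x))
    if (length(cand) == 0L) break

    ij <- arrayInd(cand, dim(x))
    flagged <- logical(length(cand))
    for (k in seq_along(cand)) {
      nb <- .window_neighbors(ij[k, 1], ij[k, 2], h, w, half)
      flagged[k] <- abs(x[cand[k]] - stats::median(x[nb])) > params$delta
    }
    flag_history <- c(flag_history, sum(flagged))
    if (!any(flagged)) break

    is_flagged <- matrix(FALSE, h, w)
    is_flagged[cand[flagged]] <- TRUE
    global_med <- if (all(is_flagged)) stats::median(x) else {
      stats::median(x[!is_flagged])
    }

    new_x <- x
    for (k in which(flagged)) {
      i <- ij[k, 1]
      j <- ij[k, 2]
      val <- NA_real_
      for (hh in c(half, max(half, 2L))) {  # window, then 5x5 expansion
        nb <- .window_neighbors(i, j, h, w, hh)
        ok <- !is_flagged[nb]
        if (!any(ok)) next
        good <- x[nb[ok, , drop = FALSE]]
        wgt <- .mu_signal(good)
        val <- if (sum(wgt) > 0) {
          sum(wgt * good) / sum(wgt)
        } else {
          stats::median(good)
        }
        break
      }
      if (is.na(val)) val <- global_med
      new_x[i, j] <- val
    }
    x <- new_x
  }
  attr(x, "flag_history") <- flag_history
  x
}
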