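#' Box-bounded search space
#'
#' Defines the rectangular search space for the optimizer: a lower and upper
#' boundary per decision variable. Every candidate position the optimizer
#' proposes is clamped back into this box.
#'
#' @param lower,upper Numeric vectors of equal length `d` with
#'   `lower[j] <= upper[j]` for every dimension `j`. Scalars are recycled when
#'   the other argument has length > 1.
#' @return An object of class `search_space` with fields `lower`, `upper`, `d`.
#' @examples
#' search_space(c(0, 0), c(1, 1))
#' search_space(-100, 100)  # 1-D
#' @export
search_space <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper)) {
    fh_stop("lower and upper must be numeric", "firehawkdr_invalid_space")
  }
  d <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (d < 1L || anyNA(lower) || anyNA(upper)) {
    fh_stop("search space bounds must be finite and non-empty",
            "firehawkdr_invalid_space")
  }
  if (any(lower > upper)) {
    fh_stop("every lower bound must be <= its upper bound",
            "firehawkdr_invalid_space")
  }
  structure(list(lower = lower, upper = upper, d = d), class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space> d =", x$d, "\n")
  cat("  lower:", paste(signif(x$lower, 4), collapse = " "), "\n")
  cat("  upper:", paste(signif(x$upper, 4), collapse = " "), "\n")
  invisible(x)
}

#' Clamp a position into a search space
#'
#' Componentwise clipping of a candidate position into `[lower, upper]`; this
#' is the boundary-violation management applied after every position update.
#'
#' @param position Numeric vector of length `space$d`.
#' @param space A [search_space()].
#' @return The clipped position.
#' @examples
#' clamp_to_bounds(c(-5, 2), search_space(c(0, 0), c(1, 1)))
#' @export
clamp_to_bounds <- function(position, space) {
  stopifnot(inherits(space, "search_space"))
  if (length(position) != space$d) {
    fh_stop("position length does not match space dimension",
            "firehawkdr_dimension_error")
  }
  pmin(pmax(position, space$lower), space$upper)
}
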