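
# Classical test functions with their conventional box bounds. All four have
# a known optimum value of 0; rosenbrock's base optimum sits at the ones
# vector, the others at the origin.
.benchmark_defs <- list(
  sphere = list(
    bounds = c(-100, 100), base_opt = 0,
    fn = function(x) sum(x^2)
  ),
  rastrigin = list(
    bounds = c(-5.12, 5.12), base_opt = 0,
    fn = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
  ),
  rosenbrock = list(
    bounds = c(-5, 10), base_opt = 1,
    fn = function(x) {
      n <- length(x)
      if (n == 1L) return((1 - x)^2)
      sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
    }
  ),
  ackley = list(
    bounds = c(-32.768, 32.768), base_opt = 0,
    fn = function(x) {
      -20 * exp(-0.2 * sqrt(mean(x^2))) - exp(mean(cos(2 * pi * x))) +
        20 + exp(1)
    }
  )
)

#' Construct a benchmark objective
#'
#' Builds one of four classical continuous test functions (sphere, rastrigin,
#' rosenbrock, ackley) with its conventional box bounds, optionally shifted
#' so the global optimum sits away from its symmetric base location. These
#' stand in for an external shifted/rotated benchmark suite so that the
#' optimizer can be validated without downloaded data files. The constructed
#' spec self-verifies: the evaluator at `known_optimum_position` must return
#' `known_optimum_value` (0) to machine precision.
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"rosenbrock"`, `"ackley"`.
#' @param dim Problem dimension, `>= 1`.
#' @param shift `NULL` for no shift, a numeric vector of length `dim` added
#'   to the base optimum, or `"random"` to place the optimum uniformly inside
#'   the central 80% of the box.
#' @param seed Seed used when `shift = "random"`.
#' @return A list of class `objective_spec`: `name`, `dim`, `bounds`
#'   (a [search_space()]), `fn` (the evaluator), `known_optimum_position`,
#'   `known_optimum_value`, `shift`.
#' @examples
#' b <- make_benchmark("ackley", 5)
#' b$fn(b$known_optimum_position)  # 0
#' @export
make_benchmark <- function(name, dim, shift = NULL, seed = NULL) {
  def <- .benchmark_defs[[name]]
  if (is.null(def)) {
    fh_stop(paste0("unknown benchmark '", name, "'"), "firehawkdr_lookup_error")
  }
  if (!is_count(dim, 1L)) {
    fh_stop("dim must be a positive integer", "firehawkdr_config_error")
  }
  lo <- rep(def$bounds[1], dim)
  hi <- rep(def$bounds[2], dim)
  base_opt <- rep(def$base_opt, dim)
  if (identical(shift, "random")) {
    span <- hi - lo
    opt <- with_seed(seed, runif(dim, lo + 0.1 * span, hi - 0.1 * span))
    shift <- opt - base_opt
  } else if (is.null(shift)) {
    shift <- rep(0, dim)
  } else {
    stopifnot(is.numeric(shift), length(shift) == dim)
  }
  opt <- base_opt + shift
  if (any(opt < lo | opt > hi)) {
    fh_stop("shift places the optimum outside the bounds",
            "firehawkdr_config_error")
  }
  base_fn <- def$fn
  fn <- function(x) base_fn(x - shift)
  stopifnot(abs(fn(opt)) < 1e-9)  # self-verification of the optimum
  structure(list(name = name, dim = as.integer(dim),
                 bounds = search_space(lo, hi), fn = fn,
                 known_optimum_position = opt, known_optimum_value = 0,
                 shift = shift),
            class = "objective_spec")
}

#' The four-function benchmark suite
#'
#' Sphere, rastrigin, rosenbrock and ackley at a common dimension, each with
#' a seed-reproducible random shift placing its optimum at a random in-bounds
#' point.
#'
#' @param dim Common dimension, `>= 2`.
#' @param seed Integer seed; each function's shift uses a child seed derived
#'   from it, so the suite is reproducible as a whole.
#' @return A named list of `objective_spec` objects.
#' @export
benchmark_suite <- function(dim, seed = 1L) {
  stopifnot(dim >= 2)
  names <- names(.benchmark_defs)
  specs <- lapply(names, function(nm) {
    make_benchmark(nm, dim, shift = "random",
                   seed = derive_seed(seed, paste0("bench/", nm)))
  })
  names(specs) <- names
  specs
}
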