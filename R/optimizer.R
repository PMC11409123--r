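#' Adaptive exploration-exploitation schedule
#'
#' The improved fire hawk variant (IFHO) multiplies the hawk position update
#' by an adaptive factor
#' \deqn{f(\alpha) = \alpha + (1 - \alpha) e^{-\gamma t}}
#' which starts at exactly 1 (pure exploration, identical to plain FHO) and
#' decays toward \eqn{\alpha} as the iteration counter `t` grows, shifting the
#' search toward exploitation around the global best. Two modes for
#' \eqn{\alpha(t)} are supported: `fixed_alpha` keeps \eqn{\alpha = \alpha_0};
#' `linear_alpha` ramps it from `alpha0` to `alpha_end` across the run.
#'
#' @param alpha0 Initial control value in (0, 1); default 0.1.
#' @param alpha_end Final control value in (0, 1] used by `linear_alpha`;
#'   default 0.9. Must satisfy `alpha0 <= alpha_end`.
#' @param gamma Nonnegative per-iteration decay rate; default 0.01.
#' @param mode `"fixed_alpha"` or `"linear_alpha"`.
#' @return An object of class `adaptive_schedule`.
#' @seealso [adaptive_factor()]
#' @export
adaptive_schedule <- function(alpha0 = 0.1, alpha_end = 0.9, gamma = 0.01,
                              mode = c("fixed_alpha", "linear_alpha")) {
  mode <- match.arg(mode)
  if (!(alpha0 > 0 && alpha0 < 1)) {
    fh_stop("alpha0 must lie in (0, 1)", "firehawkdr_config_error")
  }
  if (!(alpha_end > 0 && alpha_end <= 1) || alpha0 > alpha_end) {
    fh_stop("alpha_end must lie in (0, 1] with alpha0 <= alpha_end",
            "firehawkdr_config_error")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0) {
    fh_stop("gamma must be a nonnegative scalar", "firehawkdr_config_error")
  }
  structure(list(alpha0 = alpha0, alpha_end = alpha_end, gamma = gamma,
                 mode = mode),
            class = "adaptive_schedule")
}

#' Evaluate the adaptive factor f(alpha) at iteration t
#'
#' @param schedule An [adaptive_schedule()].
#' @param t Iteration index, `t >= 0`; the first iteration of a run has
#'   `t = 0`, where `f` is exactly 1 for any schedule.
#' @param max_iters Total iteration budget; only needed by the
#'   `linear_alpha` mode to place `t` on the \eqn{[0, 1]} ramp.
#' @return `alpha + (1 - alpha) * exp(-gamma * t)`, a value in
#'   `[min(alpha, 1), 1]`, monotone non-increasing in `t`.
#' @examples
#' s <- adaptive_schedule(alpha0 = 0.2, gamma = 0.5)
#' adaptive_factor(s, 0)  # exactly 1
#' adaptive_factor(s, 2)  # 0.2 + 0.8 * exp(-1)
#' @export
adaptive_factor <- function(schedule, t, max_iters = Inf) {
  stopifnot(inherits(schedule, "adaptive_schedule"), t >= 0)
  alpha <- switch(schedule$mode,
    fixed_alpha = schedule$alpha0,
    linear_alpha = {
      if (!is.finite(max_iters)) {
        fh_stop("linear_alpha mode needs a finite max_iters",
                "firehawkdr_config_error")
      }
      frac <- min(t / max_iters, 1)
      schedule$alpha0 + (schedule$alpha_end - schedule$alpha0) * frac
    })
  alpha + (1 - alpha) * exp(-schedule$gamma * t)
}

#' Optimizer run configuration
#'
#' @param pop_size Number of candidate solutions (hawks + prey), `>= 2`;
#'   default 25.
#' @param max_iters Iteration budget, `>= 1`; default 1000.
#' @param max_evals Optional objective-evaluation budget; `Inf` (default)
#'   disables it.
#' @param variant `"ifho"` (adaptive hawk step, the default) or `"fho"`.
#' @param direction `"minimize"` (default) or `"maximize"`. Maximization is
#'   handled by internal negation; all reported values are on the caller's
#'   scale.
#' @param hawk_fraction_cap Upper bound on the hawk share of the population,
#'   in (0, 0.5]; default 0.2.
#' @param schedule An [adaptive_schedule()]; only consulted by `ifho`.
#' @param seed Integer seed making the whole run reproducible.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(pop_size = 25, max_iters = 1000, max_evals = Inf,
                             variant = c("ifho", "fho"),
                             direction = c("minimize", "maximize"),
                             hawk_fraction_cap = 0.2,
                             schedule = adaptive_schedule(), seed = 1L) {
  variant <- match.arg(variant)
  direction <- match.arg(direction)
  if (!is_count(pop_size, 2L)) {
    fh_stop("pop_size must be an integer >= 2", "firehawkdr_config_error")
  }
  if (!is_count(max_iters, 1L)) {
    fh_stop("max_iters must be an integer >= 1", "firehawkdr_config_error")
  }
  if (!(hawk_fraction_cap > 0 && hawk_fraction_cap <= 0.5)) {
    fh_stop("hawk_fraction_cap must lie in (0, 0.5]", "firehawkdr_config_error")
  }
  stopifnot(inherits(schedule, "adaptive_schedule"))
  structure(list(pop_size = as.integer(pop_size),
                 max_iters = as.integer(max_iters),
                 max_evals = max_evals, variant = variant,
                 direction = direction,
                 hawk_fraction_cap = hawk_fraction_cap,
                 schedule = schedule, seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Randomly initialize a population inside a search space
#'
#' Each component is drawn as
#' `z = lower + rand * (upper - lower)` with `rand` uniform on \eqn{[0, 1]}.
#'
#' @param space A [search_space()].
#' @param size Number of candidates, `>= 2`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `fho_population` with `positions` (`size x d`
#'   matrix), `values` (all `NA` until evaluated) and `evaluations_used`.
#' @export
initialize_population <- function(space, size, seed = NULL) {
  stopifnot(inherits(space, "search_space"))
  if (!is_count(size, 2L)) {
    fh_stop("population size must be an integer >= 2",
            "firehawkdr_config_error")
  }
  positions <- with_seed(seed, {
    r <- matrix(runif(size * space$d), nrow = size)
    sweep(sweep(r, 2L, space$upper - space$lower, `*`), 2L, space$lower, `+`)
  })
  structure(list(positions = positions, values = rep(NA_real_, size),
                 evaluations_used = 0L),
            class = "fho_population")
}

#' Draw the number of fire hawks for one search cycle
#'
#' The hawk count is redrawn every iteration from a clamped half-normal:
#' `clamp(round(|Normal(0,1)| * pop_size / 5), 1, floor(cap * pop_size))`,
#' additionally capped at `pop_size - 1` so at least one prey remains.
#'
#' @param pop_size Total number of candidates, `>= 2`.
#' @param cap Hawk fraction cap (default 0.2).
#' @param seed Optional seed; `NULL` uses the current stream.
#' @return An integer hawk count `n`, `1 <= n <= pop_size - 1`.
#' @export
draw_hawk_count <- function(pop_size, cap = 0.2, seed = NULL) {
  stopifnot(pop_size >= 2)
  hi <- max(1L, min(floor(cap * pop_size), pop_size - 1L))
  raw <- with_seed(seed, round_half_away(abs(rnorm(1)) * pop_size / 5))
  as.integer(min(max(raw, 1L), hi))
}

#' Euclidean distance between two positions
#'
#' @param a,b Numeric vectors of equal length.
#' @return The Euclidean norm of `a - b` (d-dimensional generalization of the
#'   planar hawk-prey distance).
#' @export
pairwise_distance <- function(a, b) {
  if (length(a) != length(b)) {
    fh_stop("positions must have equal length", "firehawkdr_dimension_error")
  }
  sqrt(sum((a - b)^2))
}

#' Partition prey among hawk territories
#'
#' Each prey is assigned to its nearest hawk by Euclidean distance; distance
#' ties go to the better-ranked hawk. `hawk_indices` must already be sorted
#' best-fitness-first, which is how [run_optimizer()] produces them.
#'
#' @param population An `fho_population` (only `positions` is used).
#' @param hawk_indices Integer row indices of the hawks, best first.
#' @param prey_indices Integer row indices of the prey; must be disjoint from
#'   the hawks and jointly exhaustive.
#' @return A list of class `territory_state` with `hawk_indices`,
#'   `prey_indices` and `assignment`: a list, one element per hawk (same
#'   order), each a (possibly empty) integer vector of prey indices.
#' @export
assign_territories <- function(population, hawk_indices, prey_indices) {
  if (length(hawk_indices) == 0L) {
    fh_stop("territory assignment needs at least one hawk",
            "firehawkdr_internal_error")
  }
  if (length(intersect(hawk_indices, prey_indices)) > 0L) {
    fh_stop("hawk and prey index sets must be disjoint",
            "firehawkdr_internal_error")
  }
  pos <- population$positions
  assignment <- rep(list(integer(0)), length(hawk_indices))
  if (length(prey_indices) > 0L) {
    hp <- pos[hawk_indices, , drop = FALSE]
    # m x n distance matrix; max.col(ties = "first") on the negated matrix
    # picks the smallest distance, ties resolved to the better-ranked hawk.
    d2 <- outer(rowSums(pos[prey_indices, , drop = FALSE]^2), rowSums(hp^2), `+`) -
      2 * pos[prey_indices, , drop = FALSE] %*% t(hp)
    nearest <- max.col(-d2, ties.method = "first")
    for (l in seq_along(hawk_indices)) {
      assignment[[l]] <- prey_indices[nearest == l]
    }
  }
  structure(list(hawk_indices = hawk_indices, prey_indices = prey_indices,
                 assignment = assignment),
            class = "territory_state")
}

#' Plain fire hawk position update
#'
#' `hawk + (r1 * global_best - r2 * near_hawk)`: the hawk moves using the
#' global best ("central fire") and another hawk's position, with fresh
#' scalar uniforms `r1`, `r2` per call. The result is *not* clamped; callers
#' apply [clamp_to_bounds()].
#'
#' @param hawk,global_best,near_hawk Positions of equal length.
#' @param r1,r2 Optional uniforms in `[0, 1]`; drawn if `NULL` (one scalar
#'   each, not per component).
#' @return The proposed position.
#' @export
hawk_step <- function(hawk, global_best, near_hawk, r1 = NULL, r2 = NULL) {
  stopifnot(length(hawk) == length(global_best),
            length(hawk) == length(near_hawk))
  if (is.null(r1)) r1 <- runif(1)
  if (is.null(r2)) r2 <- runif(1)
  hawk + (r1 * global_best - r2 * near_hawk)
}

#' Adaptive (IFHO) fire hawk position update
#'
#' As [hawk_step()], but the step is scaled by the adaptive factor
#' `f = adaptive_factor(schedule, t, max_iters)`:
#' `hawk + (r1 * global_best - r2 * near_hawk) * f`. At `t = 0` this is
#' bit-identical to the plain update given the same uniforms.
#'
#' @inheritParams hawk_step
#' @inheritParams adaptive_factor
#' @return The proposed position (unclamped).
#' @export
hawk_step_adaptive <- function(hawk, global_best, near_hawk, schedule, t,
                               max_iters = Inf, r1 = NULL, r2 = NULL) {
  stopifnot(length(hawk) == length(global_best),
            length(hawk) == length(near_hawk))
  if (is.null(r1)) r1 <- runif(1)
  if (is.null(r2)) r2 <- runif(1)
  f <- adaptive_factor(schedule, t, max_iters)
  hawk + (r1 * global_best - r2 * near_hawk) * f
}

#' Safe place of a hawk's territory
#'
#' The componentwise mean of the prey positions inside one territory, the
#' place where fleeing animals congregate locally.
#'
#' @param prey_positions Matrix (rows = prey) or single position vector; must
#'   contain at least one prey.
#' @return The mean position.
#' @export
local_safe_place <- function(prey_positions) {
  if (is.null(dim(prey_positions))) {
    prey_positions <- matrix(prey_positions, nrow = 1L)
  }
  if (nrow(prey_positions) == 0L) {
    fh_stop("safe place of an empty territory is undefined",
            "firehawkdr_internal_error")
  }
  colMeans(prey_positions)
}

#' Safe place outside all territories
#'
#' The componentwise mean over *all* prey in the solution space.
#'
#' @inheritParams local_safe_place
#' @return The mean position.
#' @export
global_safe_place <- function(prey_positions) local_safe_place(prey_positions)

#' Prey update inside its own territory
#'
#' `prey + (r3 * hawk - r4 * local_safe)`: the prey reacts to its own hawk
#' and its territory's safe place. Unclamped.
#'
#' @param prey,hawk,local_safe Positions of equal length.
#' @param r3,r4 Optional scalar uniforms; drawn if `NULL`.
#' @return The proposed position.
#' @export
prey_step_within <- function(prey, hawk, local_safe, r3 = NULL, r4 = NULL) {
  stopifnot(length(prey) == length(hawk), length(prey) == length(local_safe))
  if (is.null(r3)) r3 <- runif(1)
  if (is.null(r4)) r4 <- runif(1)
  prey + (r3 * hawk - r4 * local_safe)
}

#' Prey update escaping toward another territory
#'
#' `prey + (r5 * alter_hawk - r6 * global_safe)`: the prey moves relative to
#' a different hawk and the global safe place. Unclamped.
#'
#' @param prey,alter_hawk,global_safe Positions of equal length.
#' @param r5,r6 Optional scalar uniforms; drawn if `NULL`.
#' @return The proposed position.
#' @export
prey_step_outside <- function(prey, alter_hawk, global_safe,
                              r5 = NULL, r6 = NULL) {
  stopifnot(length(prey) == length(alter_hawk),
            length(prey) == length(global_safe))
  if (is.null(r5)) r5 <- runif(1)
  if (is.null(r6)) r6 <- runif(1)
  prey + (r5 * alter_hawk - r6 * global_safe)
}

#' Run the fire hawk optimizer
#'
#' Main loop shared by FHO and IFHO. Per iteration the population is ranked
#' best-first, a hawk count is drawn ([draw_hawk_count()]), territories are
#' assigned ([assign_territories()]), one proposal is generated per hawk
#' ([hawk_step()] or [hawk_step_adaptive()] depending on `config$variant`,
#' with the near hawk drawn uniformly among the other hawks, falling back to
#' a uniform non-self population member when only one hawk exists) and two
#' candidates per prey (territory update with the local safe-place mean;
#' escape update with a uniformly drawn other hawk and the global safe-place
#' mean). All proposals are clamped and evaluated, each prey keeps the better
#' of its two candidates, and an elitist merge of the old population with all
#' proposals is truncated back to `pop_size`, which guarantees the best-so-far
#' value never worsens. Non-finite objective values are ranked worst and
#' counted, and the run continues.
#'
#' @param objective Function mapping an in-bounds position vector to a scalar.
#' @param space A [search_space()].
#' @param config An [optimizer_config()].
#' @return An object of class `fho_result`: `best_position`, `best_value`,
#'   `history` (per-iteration best on the caller's scale, monotone under the
#'   configured direction), `evaluations`, `seed`, `n_nonfinite`, `config`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- run_optimizer(sphere, search_space(-5, 5),
#'                      optimizer_config(pop_size = 10, max_iters = 50,
#'                                       seed = 1))
#' res$best_value
#' @export
run_optimizer <- function(objective, space, config = optimizer_config()) {
  stopifnot(is.function(objective), inherits(space, "search_space"),
            inherits(config, "optimizer_config"))
  N <- config$pop_size
  if (is.finite(config$max_evals) && config$max_evals < N + 1) {
    fh_stop("evaluation budget does not cover one iteration",
            "firehawkdr_config_error")
  }
  sgn <- if (config$direction == "maximize") -1 else 1
  n_nonfinite <- 0L
  eval1 <- function(x) {
    v <- sgn * objective(x)
    if (!is.finite(v)) {
      n_nonfinite <<- n_nonfinite + 1L
      v <- Inf
    }
    v
  }

  with_seed(config$seed, {
    pop <- initialize_population(space, N)
    pos <- pop$positions
    val <- vapply(seq_len(N), function(i) eval1(pos[i, ]), numeric(1))
    evals <- N
    history <- numeric(0)

    for (iter in seq_len(config$max_iters)) {
      ord <- order(val)
      pos <- pos[ord, , drop = FALSE]
      val <- val[ord]
      n <- draw_hawk_count(N, config$hawk_fraction_cap)
      m <- N - n
      terr <- assign_territories(list(positions = pos), seq_len(n),
                                 seq.int(n + 1L, N))
      gb <- pos[1L, ]
      t0 <- iter - 1L  # first iteration has t = 0, so f = 1 exactly

      prop <- matrix(NA_real_, nrow = n + m, ncol = space$d)
      pval <- numeric(n + m)
      for (l in seq_len(n)) {
        near <- if (n > 1L) {
          pos[sample(seq_len(n)[-l], 1L), ]
        } else {
          pos[sample(seq_len(N)[-l], 1L), ]
        }
        cand <- if (config$variant == "ifho") {
          hawk_step_adaptive(pos[l, ], gb, near, config$schedule, t0,
                             config$max_iters)
        } else {
          hawk_step(pos[l, ], gb, near)
        }
        cand <- clamp_to_bounds(cand, space)
        prop[l, ] <- cand
        pval[l] <- eval1(cand)
      }

      prey_rows <- seq.int(n + 1L, N)
      sg <- global_safe_place(pos[prey_rows, , drop = FALSE])
      sl <- lapply(terr$assignment, function(idx) {
        if (length(idx)) local_safe_place(pos[idx, , drop = FALSE]) else NULL
      })
      owner <- integer(N)
      for (l in seq_len(n)) owner[terr$assignment[[l]]] <- l
      for (j in seq_len(m)) {
        q <- n + j
        l <- owner[q]
        c1 <- prey_step_within(pos[q, ], pos[l, ], sl[[l]])
        alter <- if (n > 1L) sample(seq_len(n)[-l], 1L) else l
        c2 <- prey_step_outside(pos[q, ], pos[alter, ], sg)
        c1 <- clamp_to_bounds(c1, space)
        c2 <- clamp_to_bounds(c2, space)
        v1 <- eval1(c1)
        v2 <- eval1(c2)
        if (v1 <= v2) {
          prop[n + j, ] <- c1
          pval[n + j] <- v1
        } else {
          prop[n + j, ] <- c2
          pval[n + j] <- v2
        }
        evals <- evals + 2L
      }
      evals <- evals + n

      # elitist merge: parents first, so order() keeps parents on ties
      allpos <- rbind(pos, prop)
      allval <- c(val, pval)
      keep <- order(allval)[seq_len(N)]
      pos <- allpos[keep, , drop = FALSE]
      val <- allval[keep]
      history <- c(history, val[1L])

      if (is.finite(config$max_evals) && evals >= config$max_evals) break
    }

    structure(list(best_position = pos[1L, ], best_value = sgn * val[1L],
                   history = sgn * history, evaluations = evals,
                   seed = config$seed, n_nonfinite = n_nonfinite,
                   config = config),
              class = "fho_result")
  })
}

#' @export
print.fho_result <- function(x, ...) {
  cat("<fho_result>", x$config$variant, "|", x$config$direction, "\n")
  cat("  best value:", format(x$best_value), "after", x$evaluations,
      "evaluations,", length(x$history), "iterations\n")
  cat("  best position:", paste(signif(x$best_position, 6), collapse = " "),
      "\n")
  if (x$n_nonfinite > 0L) {
    cat("  note:", x$n_nonfinite, "non-finite objective values ranked worst\n")
  }
  invisible(x)
}
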