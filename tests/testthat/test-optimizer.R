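test_that("initialize_population respects bounds, degenerate boxes and seeds", {
  s <- search_space(c(0, 0), c(1, 1))
  pop <- initialize_population(s, 5, seed = 1)
  expect_equal(dim(pop$positions), c(5L, 2L))
  expect_true(all(pop$positions >= 0 & pop$positions <= 1))
  expect_true(all(is.na(pop$values)))

  degen <- initialize_population(search_space(c(3, 3), c(3, 3)), 4, seed = 2)
  expect_true(all(degen$positions == 3))

  expect_identical(initialize_population(s, 6, seed = 9)$positions,
                   initialize_population(s, 6, seed = 9)$positions)
  expect_error(initialize_population(s, 1), class = "firehawkdr_config_error")
})

test_that("draw_hawk_count obeys its clamp and its half-normal law", {
  expect_true(all(vapply(1:50, function(i) draw_hawk_count(2, seed = i),
                         numeric(1)) == 1))
  draws25 <- vapply(1:500, function(i) draw_hawk_count(25, 0.2, seed = i),
                    numeric(1))
  expect_true(all(draws25 >= 1 & draws25 <= 5))

  # Monte-Carlo law check against the closed-form clamped half-normal pmf
  set.seed(123)
  draws <- replicate(10000, draw_hawk_count(100, 0.2))
  pmf <- oracle_hawk_pmf(100, 20)
  obs <- tabulate(draws, nbins = 20)
  keep <- pmf * 10000 >= 5  # standard chi-square cell-count rule
  chi <- sum((obs[keep] - 10000 * pmf[keep])^2 / (10000 * pmf[keep]))
  expect_lt(chi, qchisq(0.99, df = sum(keep) - 1))
})

test_that("pairwise_distance is the d-dimensional Euclidean norm", {
  expect_equal(pairwise_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pairwise_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pairwise_distance(c(1, 2, 3), c(4, 6, 3)), 5)
  expect_error(pairwise_distance(c(1, 2), c(1, 2, 3)),
               class = "firehawkdr_dimension_error")
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(pairwise_distance(a, b), pairwise_distance(b, a))
  }
})

test_that("assign_territories matches the brute-force nearest-hawk oracle", {
  # single hawk takes everything
  pos <- matrix(runif(10), 5, 2)
  t1 <- assign_territories(list(positions = pos), 1L, 2:5)
  expect_equal(t1$assignment[[1]], 2:5)

  # exact tie goes to the better-ranked hawk (integer coordinates: exact)
  pos <- rbind(c(0, 0), c(2, 0), c(1, 0))
  t2 <- assign_territories(list(positions = pos), c(1L, 2L), 3L)
  expect_equal(t2$assignment[[1]], 3L)
  expect_equal(t2$assignment[[2]], integer(0))

  # 3 hawks, 7 prey at fixed printed coordinates vs exhaustive enumeration
  set.seed(11)
  pos <- matrix(round(runif(20, 0, 10), 1), 10, 2)
  ts <- assign_territories(list(positions = pos), 1:3, 4:10)
  expect_equal(ts$assignment, oracle_assign(pos, 1:3, 4:10))

  # partition property over random configurations
  for (s in 1:10) {
    set.seed(s)
    pos <- matrix(rnorm(24), 12, 2)
    n <- sample(1:4, 1)
    ts <- assign_territories(list(positions = pos), seq_len(n), (n + 1):12)
    got <- sort(unlist(ts$assignment))
    expect_equal(got, (n + 1):12)  # exhaustive and disjoint
  }
  expect_error(assign_territories(list(positions = pos), integer(0), 1:3),
               class = "firehawkdr_internal_error")
})

test_that("hawk and prey steps follow their update equations", {
  x <- c(1, 1)
  expect_equal(hawk_step(x, c(0, 0), c(2, 2), r1 = 0, r2 = 0), x)
  expect_equal(hawk_step(x, x, x, r1 = 0.3, r2 = 0.3), x)  # cancellation
  expect_equal(hawk_step(c(1, 1), c(0, 0), c(2, 2), r1 = 0.5, r2 = 0.25),
               c(0.5, 0.5))

  expect_equal(prey_step_within(c(0, 0), c(1, 0), c(0, 1), r3 = 0, r4 = 0),
               c(0, 0))
  expect_equal(prey_step_within(c(0.2, 0.4), c(1, 1), c(1, 1),
                                r3 = 0.7, r4 = 0.7), c(0.2, 0.4))
  expect_equal(prey_step_within(c(0, 0), c(1, 0), c(0, 1),
                                r3 = 0.5, r4 = 0.5), c(0.5, -0.5))
  expect_equal(prey_step_outside(c(0, 0), c(1, 0), c(0, 1),
                                 r5 = 0.5, r6 = 0.5), c(0.5, -0.5))
})

test_that("safe places are componentwise prey means", {
  expect_equal(local_safe_place(c(0.3, 0.9)), c(0.3, 0.9))
  expect_equal(local_safe_place(rbind(c(0, 0), c(2, 2))), c(1, 1))
  set.seed(5)
  m <- matrix(round(rnorm(10), 2), 5, 2)
  manual <- c(sum(m[, 1]) / 5, sum(m[, 2]) / 5)
  expect_equal(local_safe_place(m), manual)
  expect_equal(global_safe_place(m), manual)
  expect_error(local_safe_place(matrix(0, 0, 2)),
               class = "firehawkdr_internal_error")
})

test_that("adaptive_factor matches its closed form and bounds", {
  s <- adaptive_schedule(alpha0 = 0.2, gamma = 0.5)
  expect_identical(adaptive_factor(s, 0), 1)
  expect_equal(adaptive_factor(s, 2), 0.2 + 0.8 * exp(-1))
  s0 <- adaptive_schedule(alpha0 = 0.3, gamma = 0)
  expect_identical(adaptive_factor(s0, 57), 1)
  # bounded in [alpha, 1], monotone non-increasing in t
  vals <- vapply(0:100, function(t) adaptive_factor(s, t), numeric(1))
  expect_true(all(vals >= 0.2 & vals <= 1))
  expect_true(all(diff(vals) <= 0))
  # linear mode ramps alpha across the run
  sl <- adaptive_schedule(alpha0 = 0.1, alpha_end = 0.9, gamma = 1,
                          mode = "linear_alpha")
  expect_gt(adaptive_factor(sl, 100, max_iters = 100), 0.899)
  expect_error(adaptive_factor(sl, 5), class = "firehawkdr_config_error")
})

test_that("hawk_step_adaptive reduces to hawk_step at t = 0 and scales by f", {
  s <- adaptive_schedule(alpha0 = 0.4, gamma = 0.3)
  expect_equal(hawk_step_adaptive(c(1, 1), c(0, 0), c(2, 2), s, 0,
                                  r1 = 0.5, r2 = 0.25),
               hawk_step(c(1, 1), c(0, 0), c(2, 2), r1 = 0.5, r2 = 0.25))
  # huge gamma: step scaled by exactly alpha for t >= 1
  sg <- adaptive_schedule(alpha0 = 0.4, gamma = 1e9)
  expect_equal(hawk_step_adaptive(c(1, 1), c(0, 0), c(2, 2), sg, 1,
                                  r1 = 0.5, r2 = 0.25),
               c(1, 1) + 0.4 * (0.5 * c(0, 0) - 0.25 * c(2, 2)))
  # f = 0.5 arithmetic example
  sh <- adaptive_schedule(alpha0 = 0.5, gamma = 1e9)
  expect_equal(hawk_step_adaptive(c(1, 1), c(0, 0), c(2, 2), sh, 3,
                                  r1 = 0.5, r2 = 0.25), c(0.75, 0.75))
})

test_that("run_optimizer: constant objective, monotone history, determinism", {
  s <- search_space(c(-1, -1), c(1, 1))
  cfg <- optimizer_config(pop_size = 8, max_iters = 15, seed = 3)
  rc <- run_optimizer(function(x) 7, s, cfg)
  expect_true(all(rc$history == 7))

  for (seed in 1:3) {
    r <- run_optimizer(function(x) sum(x^2), s,
                       optimizer_config(pop_size = 10, max_iters = 40,
                                        seed = seed))
    expect_true(all(diff(r$history) <= 0))
    expect_true(all(r$best_position >= s$lower & r$best_position <= s$upper))
  }
  a <- run_optimizer(function(x) sum(x^2), s,
                     optimizer_config(pop_size = 10, max_iters = 30, seed = 5))
  b <- run_optimizer(function(x) sum(x^2), s,
                     optimizer_config(pop_size = 10, max_iters = 30, seed = 5))
  expect_identical(a$best_position, b$best_position)
  expect_identical(a$history, b$history)
})

test_that("ifho and fho are bit-identical on the first iteration", {
  s <- search_space(c(-5, -5), c(5, 5))
  obj <- function(x) sum(x^2)
  r_ifho <- run_optimizer(obj, s, optimizer_config(pop_size = 12,
                                                   max_iters = 1,
                                                   variant = "ifho", seed = 2))
  r_fho <- run_optimizer(obj, s, optimizer_config(pop_size = 12,
                                                  max_iters = 1,
                                                  variant = "fho", seed = 2))
  expect_identical(r_ifho$best_position, r_fho$best_position)
  expect_identical(r_ifho$history, r_fho$history)
})

test_that("run_optimizer converges on the unshifted 2-D sphere and beats
           random search", {
  b <- make_benchmark("sphere", 2)
  bests <- vapply(1:20, function(seed) {
    run_optimizer(b$fn, b$bounds,
                  optimizer_config(pop_size = 30, max_iters = 200,
                                   seed = seed))$best_value
  }, numeric(1))
  expect_lte(median(bests), 1e-6)

  # brute-force random search at an equal evaluation budget is strictly worse
  rs <- vapply(1:20, function(seed) {
    set.seed(seed)
    n_evals <- 30 + 200 * 60
    pts <- matrix(runif(n_evals * 2, -100, 100), ncol = 2)
    min(rowSums(pts^2))
  }, numeric(1))
  expect_lt(median(bests), median(rs))
})

test_that("run_optimizer handles maximize, max_evals and non-finite values", {
  s <- search_space(c(0, 0), c(1, 1))
  rmax <- run_optimizer(function(x) -sum((x - 0.5)^2), s,
                        optimizer_config(pop_size = 10, max_iters = 60,
                                         direction = "maximize", seed = 1))
  expect_gt(rmax$best_value, -1e-3)
  expect_true(all(diff(rmax$history) >= 0))

  rbudget <- run_optimizer(function(x) sum(x), s,
                           optimizer_config(pop_size = 10, max_iters = 500,
                                            max_evals = 100, seed = 1))
  expect_lt(length(rbudget$history), 10)
  expect_error(run_optimizer(function(x) 0, s,
                             optimizer_config(pop_size = 10, max_iters = 5,
                                              max_evals = 5, seed = 1)),
               class = "firehawkdr_config_error")

  rnf <- run_optimizer(function(x) if (x[1] > 0.5) NaN else sum(x), s,
                       optimizer_config(pop_size = 10, max_iters = 20,
                                        seed = 2))
  expect_gt(rnf$n_nonfinite, 0)
  expect_true(is.finite(rnf$best_value))
})

test_that("population size is conserved and hawk counts stay legal", {
  # exercised indirectly: a run whose objective records every evaluated
  # position; all of them must be inside the box (feasibility invariant)
  s <- search_space(c(-3, 2), c(4, 9))
  seen <- list()
  obj <- function(x) {
    seen[[length(seen) + 1L]] <<- x
    sum((x - 3)^2)
  }
  r <- run_optimizer(obj, s, optimizer_config(pop_size = 9, max_iters = 25,
                                              seed = 8))
  mat <- do.call(rbind, seen)
  expect_equal(nrow(mat), r$evaluations)
  expect_true(all(mat[, 1] >= -3 & mat[, 1] <= 4))
  expect_true(all(mat[, 2] >= 2 & mat[, 2] <= 9))
})
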