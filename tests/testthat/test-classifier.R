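test_that("decode_hyperparameters rounds half-away and clamps into the box", {
  h <- decode_hyperparameters(c(100.4, 0.005, 63.7))
  expect_equal(c(h$n_hidden, h$learning_rate, h$batch_size), c(100, 0.005, 64))
  h2 <- decode_hyperparameters(c(50.0, 0.001, 32.0))
  expect_equal(c(h2$n_hidden, h2$learning_rate, h2$batch_size),
               c(50, 0.001, 32))
  h3 <- decode_hyperparameters(c(200.49, 0.01, 127.5))
  expect_equal(c(h3$n_hidden, h3$learning_rate, h3$batch_size),
               c(200, 0.01, 128))
  expect_error(decode_hyperparameters(c(100, 0.005)),
               class = "firehawkdr_dimension_error")

  # property: any in-box position decodes to in-box hyperparameters
  sp <- hyperparameter_space()
  set.seed(12)
  for (i in 1:200) {
    p <- runif(3, sp$lower, sp$upper)
    h <- decode_hyperparameters(p)
    expect_true(h$n_hidden >= 50 && h$n_hidden <= 200)
    expect_true(h$batch_size >= 32 && h$batch_size <= 128)
    expect_true(h$learning_rate >= 0.001 && h$learning_rate <= 0.01)
  }
})

test_that("hidden_layer classifier separates blobs and is deterministic", {
  blobs <- make_blobs(n_per = 80, seed = 3)
  spec <- classifier_spec(epochs = 60, seed = 4)
  m <- train_classifier(spec, blobs$x, blobs$y, hyperparameters())
  expect_gte(fitness_accuracy(m, blobs$x, blobs$y), 0.99)

  m2 <- train_classifier(spec, blobs$x, blobs$y, hyperparameters())
  expect_identical(predict(m, blobs$x)$scores, predict(m2, blobs$x)$scores)

  # fitness is the Iverson-bracket mean
  p <- predict(m, blobs$x)$labels
  expect_equal(fitness_accuracy(m, blobs$x, blobs$y), mean(p == blobs$y))
  expect_error(train_classifier(spec, blobs$x, rep(1, nrow(blobs$x))),
               class = "firehawkdr_training_error")
  expect_error(fitness_accuracy(m, blobs$x[0, , drop = FALSE], integer(0)),
               class = "firehawkdr_config_error")
})

test_that("label-permuted balanced data scores at chance level", {
  blobs <- make_blobs(n_per = 100, seed = 6)
  set.seed(7)
  y_perm <- sample(blobs$y)
  split <- train_validation_split(y_perm, seed = 8)
  m <- train_classifier(classifier_spec(epochs = 20, seed = 9),
                        blobs$x[split$train, ], y_perm[split$train],
                        hyperparameters())
  acc <- fitness_accuracy(m, blobs$x[split$validation, ],
                          y_perm[split$validation])
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
})

test_that("reduced_bottleneck mode runs end to end deterministically", {
  ds <- make_small_fundus(n = 24, seed = 5)
  small <- lapply(ds$images, avg_pool, factor = 4)  # 16x16 inputs
  x <- do.call(rbind, lapply(small, as.vector))
  spec <- classifier_spec("reduced_bottleneck", epochs = 30, input_size = 16,
                          channels = 6L, n_blocks = 2L, seed = 11)
  m <- train_classifier(spec, x, ds$labels, hyperparameters())
  p1 <- predict(m, x)
  m2 <- train_classifier(spec, x, ds$labels, hyperparameters())
  expect_identical(p1$scores, predict(m2, x)$scores)
  expect_length(p1$labels, 24)
  expect_true(all(p1$scores >= 0 & p1$scores <= 1))
})

test_that("tune_hyperparameters caches by decoded key and handles a constant
           surface", {
  calls <- 0L
  counting <- function(h) {
    calls <<- calls + 1L
    0.42
  }
  tr <- tune_hyperparameters(config = optimizer_config(pop_size = 6,
                                                       max_iters = 10,
                                                       seed = 1),
                             fitness_fn = counting)
  expect_equal(tr$best_fitness, 0.42)
  expect_true(tr$best$n_hidden >= 50 && tr$best$n_hidden <= 200)
  # every distinct decoded key trained exactly once
  expect_identical(calls, tr$n_trainings)
  expect_lte(tr$n_trainings, tr$optimizer_result$evaluations)

  # a corner-seeking surface collapses the population onto one decoded key
  # via boundary clamping, so the cache must absorb repeated evaluations
  calls <- 0L
  corner <- function(h) {
    calls <<- calls + 1L
    -(h$n_hidden + 1e4 * h$learning_rate + h$batch_size)
  }
  tr2 <- tune_hyperparameters(config = optimizer_config(pop_size = 8,
                                                        max_iters = 40,
                                                        seed = 2),
                              fitness_fn = corner)
  expect_identical(calls, tr2$n_trainings)
  expect_lt(tr2$n_trainings, tr2$optimizer_result$evaluations)
  expect_equal(c(tr2$best$n_hidden, tr2$best$batch_size), c(50, 32))
})

test_that("tune_hyperparameters improves fitness on real features", {
  ds <- make_small_fundus(n = 60, seed = 13)
  set <- flatten_dataset(ds, pool = 8)
  tr <- tune_hyperparameters(set,
                             optimizer_config(pop_size = 6, max_iters = 6,
                                              seed = 2),
                             classifier_spec(epochs = 5, seed = 3))
  expect_true(tr$best_fitness >= 0 && tr$best_fitness <= 1)
  # the audit trail is monotone non-decreasing under maximization
  expect_true(all(diff(tr$optimizer_result$history) >= 0))
  # reported best fitness is reproducible from the stored best config
  expect_equal(tr$best_fitness,
               max(tr$optimizer_result$history))
})
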