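#' Classifier hyperparameters
#'
#' The three tunable hyperparameters of the desk-scale classifier and their
#' search intervals: hidden-layer width `N` in \[50, 200\], learning rate
#' `LR` in \[0.001, 0.01\] (linear scale), batch size `B` in \[32, 128\].
#' The defaults are the demonstration configuration (100, 0.005, 64).
#'
#' @param n_hidden Integer hidden-layer width in \[50, 200\].
#' @param learning_rate SGD learning rate in \[0.001, 0.01\].
#' @param batch_size Integer mini-batch size in \[32, 128\].
#' @return An object of class `hyperparameters`.
#' @export
hyperparameters <- function(n_hidden = 100L, learning_rate = 0.005,
                            batch_size = 64L) {
  if (n_hidden < 50 || n_hidden > 200 || n_hidden != round(n_hidden) ||
      learning_rate < 0.001 || learning_rate > 0.01 ||
      batch_size < 32 || batch_size > 128 || batch_size != round(batch_size)) {
    fh_stop("hyperparameters outside their search intervals",
            "firehawkdr_config_error")
  }
  structure(list(n_hidden = as.integer(n_hidden),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size)),
            class = "hyperparameters")
}

#' The hyperparameter search box
#'
#' @return A [search_space()] over (N, LR, B) with bounds
#'   (50, 0.001, 32) to (200, 0.01, 128).
#' @export
hyperparameter_space <- function() {
  search_space(c(50, 0.001, 32), c(200, 0.01, 128))
}

#' Decode an optimizer position into hyperparameters
#'
#' The integer-valued variables (hidden width, batch size) are rounded
#' half-away-from-zero and clamped into the box; the learning rate passes
#' through unchanged (clamped only if a boundary proposal overshoots by
#' floating error).
#'
#' @param position Numeric vector of length 3: (N, LR, B).
#' @param space The search box; defaults to [hyperparameter_space()].
#' @return A [hyperparameters()] object.
#' @examples
#' decode_hyperparameters(c(100.4, 0.005, 63.7))
#' @export
decode_hyperparameters <- function(position, space = hyperparameter_space()) {
  if (length(position) != 3L) {
    fh_stop("position must have length 3", "firehawkdr_dimension_error")
  }
  cl <- function(x, j) min(max(x, space$lower[j]), space$upper[j])
  hyperparameters(n_hidden = cl(round_half_away(position[1]), 1),
                  learning_rate = cl(position[2], 2),
                  batch_size = cl(round_half_away(position[3]), 3))
}

#' Classifier architecture specification
#'
#' `hidden_layer` (default) is a fully trained one-hidden-layer network on
#' flattened features, matching the literal hidden-width decision variable.
#' `reduced_bottleneck` prepends a small frozen convolutional stack in the
#' inverted-bottleneck style (stem 3x3 conv, expand 1x1 / depthwise 3x3 /
#' project 1x1 blocks with stride-1 channel-matched shortcuts, global
#' average pooling) whose seeded random weights act as a fixed feature
#' extractor; only the classification head is trained.
#'
#' @param architecture `"hidden_layer"` or `"reduced_bottleneck"`.
#' @param epochs Training epochs, `>= 1` (default 20; fixed, not a decision
#'   variable).
#' @param input_size For `reduced_bottleneck`, the square image side length
#'   each input row is reshaped to; ignored by `hidden_layer`.
#' @param channels,n_blocks Width and depth of the frozen bottleneck stack.
#' @param standardize Z-score the training features (mean/sd estimated on
#'   the training split only, reapplied at prediction); default `TRUE`. This
#'   is standard conditioning for SGD on raw pixel features and matters at
#'   small epoch budgets.
#' @param seed Integer seed controlling weight initialization (and the
#'   frozen extractor).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(architecture = c("hidden_layer",
                                             "reduced_bottleneck"),
                            epochs = 20L, input_size = NULL, channels = 8L,
                            n_blocks = 2L, standardize = TRUE, seed = 1L) {
  architecture <- match.arg(architecture)
  if (!is_count(epochs, 1L)) {
    fh_stop("epochs must be an integer >= 1", "firehawkdr_config_error")
  }
  if (architecture == "reduced_bottleneck" && is.null(input_size)) {
    fh_stop("reduced_bottleneck needs input_size", "firehawkdr_config_error")
  }
  structure(list(architecture = architecture, epochs = as.integer(epochs),
                 input_size = input_size, channels = as.integer(channels),
                 n_blocks = as.integer(n_blocks),
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "classifier_spec")
}

# ---- internal: one-hidden-layer softmax network trained by mini-batch SGD
# (with classical momentum, a standard SGD variation) under cross-entropy.

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.train_mlp <- function(x, y, n_hidden, lr, batch_size, epochs, seed) {
  n <- nrow(x)
  p <- ncol(x)
  y1 <- cbind(1 - y, y)  # one-hot over {0, 1}
  with_seed(seed, {
    w1 <- matrix(rnorm(p * n_hidden, sd = sqrt(2 / p)), p, n_hidden)
    b1 <- rep(0, n_hidden)
    w2 <- matrix(rnorm(n_hidden * 2, sd = sqrt(2 / n_hidden)), n_hidden, 2)
    b2 <- rep(0, 2)
    v1 <- w1 * 0; vb1 <- b1; v2 <- w2 * 0; vb2 <- b2
    mom <- 0.9
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        z1 <- sweep(xb %*% w1, 2L, b1, `+`)
        a1 <- pmax(z1, 0)
        probs <- .softmax(sweep(a1 %*% w2, 2L, b2, `+`))
        d2 <- (probs - y1[idx, , drop = FALSE]) / length(idx)
        g2 <- t(a1) %*% d2
        gb2 <- colSums(d2)
        d1 <- (d2 %*% t(w2)) * (z1 > 0)
        g1 <- t(xb) %*% d1
        gb1 <- colSums(d1)
        v1 <- mom * v1 - lr * g1;  w1 <- w1 + v1
        vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
        v2 <- mom * v2 - lr * g2;  w2 <- w2 + v2
        vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
      }
    }
    list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
  })
}

.mlp_scores <- function(net, x) {
  a1 <- pmax(sweep(x %*% net$w1, 2L, net$b1, `+`), 0)
  .softmax(sweep(a1 %*% net$w2, 2L, net$b2, `+`))[, 2L]
}

# ---- internal: frozen inverted-bottleneck feature extractor --------------

.conv3 <- function(planes, weights, stride = 1L) {
  # planes: list of HxW matrices (input channels); weights: array
  # [3, 3, in, out]. Same-padding via zero borders, then optional stride.
  h <- nrow(planes[[1]])
  w <- ncol(planes[[1]])
  n_out <- dim(weights)[4]
  out <- vector("list", n_out)
  for (o in seq_len(n_out)) {
    acc <- matrix(0, h, w)
    for (ci in seq_along(planes)) {
      p <- planes[[ci]]
      for (di in -1:1) for (dj in -1:1) {
        wgt <- weights[di + 2L, dj + 2L, ci, o]
        if (wgt == 0) next
        shifted <- matrix(0, h, w)
        ri <- max(1, 1 + di):min(h, h + di)
        ci2 <- max(1, 1 + dj):min(w, w + dj)
        shifted[ri, ci2] <- p[ri - di, ci2 - dj]
        acc <- acc + wgt * shifted
      }
    }
    if (stride > 1L) {
      acc <- acc[seq(1L, h, by = stride), seq(1L, w, by = stride)]
    }
    out[[o]] <- acc
  }
  out
}

.inorm_relu <- function(planes) {
  lapply(planes, function(p) {
    s <- sqrt(mean(p^2) + 1e-8)
    pmax(p / s, 0)
  })
}

.bottleneck_weights <- function(channels, n_blocks, seed) {
  with_seed(seed, {
    expand <- 2L
    list(
      stem = array(rnorm(9 * channels, sd = 0.5), c(3, 3, 1, channels)),
      blocks = lapply(seq_len(n_blocks), function(b) {
        list(expand = matrix(rnorm(channels * channels * expand,
                                   sd = sqrt(1 / channels)),
                             channels, channels * expand),
             depth = array(rnorm(9 * channels * expand, sd = 0.5),
                           c(3, 3, channels * expand)),
             project = matrix(rnorm(channels * expand * channels,
                                    sd = sqrt(1 / (channels * expand))),
                              channels * expand, channels))
      })
    )
  })
}

.bottleneck_features <- function(xrow, side, wts) {
  img <- matrix(xrow, side, side)
  h <- .inorm_relu(.conv3(list(img), wts$stem, stride = 2L))
  for (blk in wts$blocks) {
    # expand 1x1: channel mixing
    stack <- simplify2array(h)                     # H x W x C
    hw <- dim(stack)[1] * dim(stack)[2]
    flat <- matrix(stack, hw, length(h))
    exp_flat <- flat %*% blk$expand
    expd <- lapply(seq_len(ncol(exp_flat)), function(c) {
      matrix(exp_flat[, c], dim(stack)[1], dim(stack)[2])
    })
    expd <- .inorm_relu(expd)
    # depthwise 3x3
    dw <- lapply(seq_along(expd), function(c) {
      .conv3(expd[c], array(blk$depth[, , c], c(3, 3, 1, 1)))[[1]]
    })
    dw <- .inorm_relu(dw)
    # project 1x1 + shortcut (stride 1, channels match)
    dflat <- matrix(simplify2array(dw), hw, length(dw))
    pflat <- dflat %*% blk$project
    h <- lapply(seq_len(ncol(pflat)), function(c) {
      h[[c]] + matrix(pflat[, c], dim(stack)[1], dim(stack)[2])
    })
  }
  vapply(h, mean, numeric(1))  # global average pooling
}

#' Train the desk-scale classifier
#'
#' `hidden_layer` mode trains a one-hidden-layer ReLU network with a softmax
#' head by seeded mini-batch SGD (momentum 0.9) under cross-entropy loss at
#' the given hyperparameters. `reduced_bottleneck` mode first maps each row
#' through the frozen seeded convolutional stack described in
#' [classifier_spec()] and trains the same head (width `n_hidden`) on the
#' pooled features. Training is deterministic given the seed.
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric feature matrix (rows = samples).
#' @param y Binary 0/1 labels; both classes must be present.
#' @param hyper A [hyperparameters()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A model handle of class `fh_classifier` with a [predict][
#'   predict.fh_classifier] method.
#' @export
train_classifier <- function(spec, x, y, hyper = hyperparameters(),
                             seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(hyper, "hyperparameters"))
  x <- as.matrix(x)
  if (nrow(x) == 0L || length(unique(y)) < 2L) {
    fh_stop("training set must be non-empty with two classes",
            "firehawkdr_training_error")
  }
  if (is.null(seed)) seed <- spec$seed
  extractor <- NULL
  feats <- x
  if (spec$architecture == "reduced_bottleneck") {
    side <- spec$input_size
    stopifnot(ncol(x) == side * side)
    extractor <- .bottleneck_weights(spec$channels, spec$n_blocks,
                                     derive_seed(seed, "conv"))
    feats <- t(apply(x, 1L, .bottleneck_features, side = side,
                     wts = extractor))
  }
  scaler <- NULL
  if (spec$standardize) {
    mu <- colMeans(feats)
    sg <- apply(feats, 2L, stats::sd)
    sg[!is.finite(sg) | sg < 1e-8] <- 1
    scaler <- list(mu = mu, sg = sg)
    feats <- scale(feats, mu, sg)
  }
  net <- .train_mlp(feats, y, hyper$n_hidden, hyper$learning_rate,
                    hyper$batch_size, spec$epochs,
                    derive_seed(seed, "mlp"))
  structure(list(spec = spec, hyper = hyper, net = net,
                 extractor = extractor, scaler = scaler, seed = seed),
            class = "fh_classifier")
}

#' Predict labels and scores
#'
#' @param object A trained `fh_classifier`.
#' @param newdata Feature matrix with the same column count as training.
#' @param ... Unused.
#' @return A list with `scores` (probability of class 1) and `labels`
#'   (0/1 at the 0.5 threshold).
#' @export
predict.fh_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$extractor)) {
    x <- t(apply(x, 1L, .bottleneck_features, side = object$spec$input_size,
                 wts = object$extractor))
  }
  if (!is.null(object$scaler)) {
    x <- scale(x, object$scaler$mu, object$scaler$sg)
  }
  scores <- .mlp_scores(object$net, x)
  list(scores = scores, labels = as.integer(scores >= 0.5))
}

#' Validation accuracy (the tuning fitness)
#'
#' The fraction of validation samples whose predicted label matches the true
#' label (Iverson-bracket mean) -- the quantity the optimizer maximizes when
#' tuning hyperparameters.
#'
#' @param model A trained `fh_classifier`.
#' @param x Validation feature matrix (non-empty).
#' @param y Validation labels.
#' @return Accuracy in `[0, 1]`.
#' @export
fitness_accuracy <- function(model, x, y) {
  if (NROW(x) == 0L) {
    fh_stop("validation set must be non-empty", "firehawkdr_config_error")
  }
  mean(predict(model, x)$labels == y)
}

#' Stratified 80:20 train/validation split
#'
#' @param labels Binary 0/1 labels.
#' @param frac Training fraction (default 0.8).
#' @param seed Optional integer seed.
#' @return A list with integer index vectors `train` and `validation`.
#' @export
train_validation_split <- function(labels, frac = 0.8, seed = NULL) {
  stopifnot(all(labels %in% c(0, 1)), frac > 0, frac < 1)
  with_seed(seed, {
    train <- integer(0)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      train <- c(train, sample(idx, round(frac * length(idx))))
    }
    train <- sort(train)
    list(train = train,
         validation = setdiff(seq_along(labels), train))
  })
}

#' Tune hyperparameters with the fire hawk optimizer
#'
#' Runs the optimizer (IFHO by default) over the (N, LR, B) search box,
#' maximizing validation accuracy: each candidate position is decoded with
#' [decode_hyperparameters()], a classifier is freshly trained on the 80%
#' training split at a fixed seed, and its accuracy on the 20% validation
#' split is the fitness. Fitness evaluations are cached by the decoded
#' hyperparameter key, so re-visiting an equivalent integer configuration
#' never retrains.
#'
#' @param set A [labeled_vector_set()]; split 80:20 stratified internally.
#' @param config An [optimizer_config()]; its `direction` is forced to
#'   `"maximize"`.
#' @param spec A [classifier_spec()].
#' @param fitness_fn Optional replacement fitness: a function
#'   `hyperparameters -> numeric` (used by tests to rig an analytic
#'   surface); when supplied, no training happens.
#' @return An object of class `tuning_result`: `best` (decoded
#'   hyperparameters), `best_fitness`, `optimizer_result`, `n_trainings`
#'   (distinct decoded keys evaluated).
#' @export
tune_hyperparameters <- function(set = NULL, config = optimizer_config(),
                                 spec = classifier_spec(),
                                 fitness_fn = NULL) {
  stopifnot(inherits(config, "optimizer_config"))
  config$direction <- "maximize"
  cache <- new.env(parent = emptyenv())
  n_trainings <- 0L

  if (is.null(fitness_fn)) {
    stopifnot(inherits(set, "labeled_vector_set"))
    split <- train_validation_split(set$labels,
                                    seed = derive_seed(config$seed, "split"))
    xtr <- set$vectors[split$train, , drop = FALSE]
    ytr <- set$labels[split$train]
    xva <- set$vectors[split$validation, , drop = FALSE]
    yva <- set$labels[split$validation]
    fit_seed <- derive_seed(config$seed, "fit")
    fitness_fn <- function(hyper) {
      model <- train_classifier(spec, xtr, ytr, hyper, seed = fit_seed)
      fitness_accuracy(model, xva, yva)
    }
  }

  objective <- function(position) {
    hyper <- decode_hyperparameters(position)
    key <- paste(hyper$n_hidden, signif(hyper$learning_rate, 9),
                 hyper$batch_size, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- fitness_fn(hyper)
    cache[[key]] <- v
    n_trainings <<- n_trainings + 1L
    v
  }

  res <- run_optimizer(objective, hyperparameter_space(), config)
  best <- decode_hyperparameters(res$best_position)
  structure(list(best = best, best_fitness = res$best_value,
                 optimizer_result = res, n_trainings = n_trainings),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result> fitness", format(x$best_fitness), "at N =",
      x$best$n_hidden, ", LR =", format(x$best$learning_rate), ", B =",
      x$best$batch_size, "(", x$n_trainings, "trainings )\n")
  invisible(x)
}
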