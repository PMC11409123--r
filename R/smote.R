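#' Labeled vector set
#'
#' The flat container SMOTE and the classifier harness operate on: a matrix
#' of flattened normalized images plus binary labels and per-row origin
#' flags distinguishing real from synthetic rows.
#'
#' @param vectors Numeric `M x p` matrix.
#' @param labels Integer/numeric vector of length `M` with values in
#'   \{0, 1\} (0 = negative / No-DR, 1 = positive / DR).
#' @param origin Character vector of per-row flags, `"real"` or
#'   `"synthetic"`; defaults to all `"real"`.
#' @return An object of class `labeled_vector_set`.
#' @export
labeled_vector_set <- function(vectors, labels, origin = NULL) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(labels)) {
    fh_stop("vectors and labels must be aligned", "firehawkdr_config_error")
  }
  if (!all(labels %in% c(0, 1))) {
    fh_stop("labels must be binary 0/1", "firehawkdr_config_error")
  }
  if (is.null(origin)) origin <- rep("real", nrow(vectors))
  stopifnot(length(origin) == nrow(vectors),
            all(origin %in% c("real", "synthetic")))
  structure(list(vectors = vectors, labels = as.integer(labels),
                 origin = origin),
            class = "labeled_vector_set")
}

#' @export
print.labeled_vector_set <- function(x, ...) {
  cat("<labeled_vector_set>", nrow(x$vectors), "rows x", ncol(x$vectors),
      "features;", sum(x$labels == 1), "positive /", sum(x$labels == 0),
      "negative;", sum(x$origin == "synthetic"), "synthetic\n")
  invisible(x)
}

#' k nearest same-class neighbors of one sample
#'
#' Euclidean nearest neighbors searched strictly within the query's own
#' class, excluding the query itself; distance ties are broken in favor of
#' the lower row index.
#'
#' @param set A [labeled_vector_set()].
#' @param index Row index of the query sample.
#' @param k Number of neighbors; must be smaller than the query's class size.
#' @return Integer vector of `k` row indices into `set$vectors`.
#' @export
nearest_neighbors <- function(set, index, k) {
  stopifnot(inherits(set, "labeled_vector_set"))
  same <- setdiff(which(set$labels == set$labels[index]), index)
  if (k >= length(same) + 1L) {
    fh_stop("k must be smaller than the class size", "firehawkdr_config_error")
  }
  q <- set$vectors[index, ]
  d2 <- colSums((t(set$vectors[same, , drop = FALSE]) - q)^2)
  same[order(d2, same)[seq_len(k)]]
}

#' Interpolate one synthetic sample
#'
#' `sample + lambda * (neighbor - sample)` with a single
#' `lambda ~ Uniform[0, 1]` shared by all components (classical SMOTE).
#' `per_component = TRUE` instead draws a fresh uniform per component.
#'
#' @param sample,neighbor Numeric vectors of equal length.
#' @param lambda Optional fixed multiplier(s); drawn if `NULL`.
#' @param per_component Draw one uniform per component instead of one per
#'   sample.
#' @return The synthetic vector, a convex combination lying on the segment
#'   (or, per component, in the box) between the two parents.
#' @export
synthesize_sample <- function(sample, neighbor, lambda = NULL,
                              per_component = FALSE) {
  if (length(sample) != length(neighbor)) {
    fh_stop("sample and neighbor must have equal length",
            "firehawkdr_dimension_error")
  }
  if (is.null(lambda)) {
    lambda <- if (per_component) runif(length(sample)) else runif(1)
  }
  sample + lambda * (neighbor - sample)
}

#' Balance a two-class set by SMOTE oversampling
#'
#' Appends synthetic minority rows until the class counts are equal. Each
#' synthetic row interpolates between a uniformly drawn minority sample and
#' one of its `k` nearest minority neighbors (also drawn uniformly), so every
#' synthetic vector stays inside the componentwise envelope of the minority
#' class. Real rows are never modified or removed.
#'
#' @param set A [labeled_vector_set()] containing exactly two classes.
#' @param k Neighborhood size (default 5); each class must have more than
#'   `k` members.
#' @param seed Optional integer seed.
#' @param per_component Passed to [synthesize_sample()].
#' @return A new `labeled_vector_set` with equal class counts; appended rows
#'   carry origin `"synthetic"`.
#' @export
smote_balance <- function(set, k = 5L, seed = NULL, per_component = FALSE) {
  stopifnot(inherits(set, "labeled_vector_set"))
  counts <- table(factor(set$labels, levels = c(0, 1)))
  if (any(counts == 0)) {
    fh_stop("both classes must be present", "firehawkdr_config_error")
  }
  if (any(counts <= k)) {
    fh_stop("each class needs more than k members", "firehawkdr_config_error")
  }
  deficit <- abs(counts[["1"]] - counts[["0"]])
  if (deficit == 0L) return(set)
  minority <- if (counts[["1"]] < counts[["0"]]) 1L else 0L
  min_idx <- which(set$labels == minority)

  with_seed(seed, {
    synth <- matrix(NA_real_, nrow = deficit, ncol = ncol(set$vectors))
    for (s in seq_len(deficit)) {
      i <- min_idx[sample.int(length(min_idx), 1L)]
      nn <- nearest_neighbors(set, i, k)
      j <- nn[sample.int(k, 1L)]
      synth[s, ] <- synthesize_sample(set$vectors[i, ], set$vectors[j, ],
                                      per_component = per_component)
    }
    labeled_vector_set(rbind(set$vectors, synth),
                       c(set$labels, rep(minority, deficit)),
                       c(set$origin, rep("synthetic", deficit)))
  })
}
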