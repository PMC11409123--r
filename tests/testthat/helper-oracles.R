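# Independent oracles used by the unit and acceptance suites. These are
# deliberately naive (loops, exhaustive enumeration) and must stay
# independent of the package's own code paths.

# nearest-hawk assignment by exhaustive distance enumeration
oracle_assign <- function(positions, hawk_idx, prey_idx) {
  lapply(seq_along(hawk_idx), function(l) {
    keep <- integer(0)
    for (q in prey_idx) {
      d <- vapply(hawk_idx, function(h) {
        sqrt(sum((positions[q, ] - positions[h, ])^2))
      }, numeric(1))
      if (which(d == min(d))[1] == l) keep <- c(keep, q)
    }
    keep
  })
}

# all positive-negative pairs AUC with half ties
oracle_auc <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# direct per-formula confusion metrics (percent scale), NA on zero
# denominators
oracle_metrics <- function(tp, tn, fp, fn) {
  sdiv <- function(a, b) if (b == 0) NA_real_ else 100 * a / b
  pr <- sdiv(tp, tp + fp)
  sp <- sdiv(tn, tn + fp)
  se <- sdiv(tp, tp + fn)
  ac <- sdiv(tp + tn, tp + tn + fp + fn)
  f1 <- if (is.na(pr) || is.na(se) || pr + se == 0) NA_real_ else {
    2 * pr * se / (pr + se)
  }
  c(precision = pr, specificity = sp, sensitivity = se, accuracy = ac,
    f1 = f1)
}

# brute-force k nearest neighbors within a class, ties by lower index
oracle_knn <- function(vectors, labels, index, k) {
  same <- setdiff(which(labels == labels[index]), index)
  d <- vapply(same, function(j) sqrt(sum((vectors[index, ] - vectors[j, ])^2)),
              numeric(1))
  same[order(d, same)][seq_len(k)]
}

# closed-form pmf of clamp(round(|N(0,1)| * pop / 5), 1, hi)
oracle_hawk_pmf <- function(pop, hi) {
  s <- pop / 5
  p <- numeric(hi)
  for (j in seq_len(hi)) {
    lo_b <- if (j == 1) -Inf else (j - 0.5) / s
    up_b <- if (j == hi) Inf else (j + 0.5) / s
    cdf <- function(x) if (is.infinite(x)) (if (x > 0) 1 else 0) else {
      2 * pnorm(x) - 1
    }
    p[j] <- cdf(up_b) - cdf(max(lo_b, 0))
  }
  p
}

# shared small fundus fixture (clean images)
make_small_fundus <- function(n = 40, seed = 7, dr_fraction = 0.25) {
  generate_dataset(n, fundus_params(dr_fraction = dr_fraction), seed = seed)
}

# well-separated 2-D blobs for classifier tests
make_blobs <- function(n_per = 60, seed = 1, sep = 0.6) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per, 0.2, 0.05), n_per, 2),
             matrix(rnorm(2 * n_per, 0.2 + sep, 0.05), n_per, 2))
  list(x = x, y = rep(c(0L, 1L), each = n_per))
}
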