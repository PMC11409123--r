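#' @keywords internal
"_PACKAGE"

# Internal error helper with a class so callers can test error categories.
fh_stop <- function(msg, class = "firehawkdr_error", call. = FALSE) {
  stop(structure(
    class = c(class, "firehawkdr_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

#' Derive a reproducible child seed from a parent seed and a label
#'
#' One global seed fans out to per-stage child streams by fixed labels so that
#' each pipeline stage (simulate, denoise, augment, tune, evaluate, ...) is
#' independently reproducible. The derivation is a small deterministic string
#' hash folded with the parent seed; the result always lies in
#' `[1, 2^31 - 2]` so it is a valid R integer seed.
#'
#' @param seed Integer parent seed.
#' @param label Character scalar naming the child stream.
#' @return An integer seed.
#' @examples
#' derive_seed(1, "simulate")
#' derive_seed(1, "denoise")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 1000000007
  as.integer(((abs(seed) %% 1048573) * 2039 + h) %% 2147483646 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
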