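# Internal numeric and seeding helpers shared across modules.

#' Derive a deterministic child seed from a global seed and a stream name
#'
#' All stochastic stages draw their randomness from named child streams of a
#' single global seed, so adding or reordering one generator never perturbs
#' the draws of another. The derived seed always fits in a 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param stream Character stream name, e.g. `"depth"` or `"network"`.
#' @return A single integer seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% 2147480009  # large prime < 2^31
  }
  as.integer((abs(seed) %% 2147480009 * 7919 + h) %% 2147480009)
}

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Elementwise log(exp(a)+exp(b)+exp(c)) over three equal-length vectors.
# Used by the batched forward-backward recursions.
lse3 <- function(a, b, c) {
  m <- pmax(a, b, c)
  out <- m + log(exp(a - m) + exp(b - m) + exp(c - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != round(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s", name,
                  paste(format(x), collapse = ",")))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must lie in [%s, %s]", name, lo, hi))
  }
  invisible(as.numeric(x))
}

# Parse "chrom:start-end" target identifiers into a tibble.
parse_target_ids <- function(ids) {
  m <- stringr::str_match(ids, "^([^:]+):(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) {
    abort(sprintf("malformed target identifier(s): %s",
                  paste(head(ids[is.na(m[, 1])], 3), collapse = ", ")))
  }
  tibble(
    target = ids,
    chrom = m[, 2],
    start = as.numeric(m[, 3]),
    end = as.numeric(m[, 4])
  )
}

format_target_ids <- function(targets) {
  sprintf("%s:%d-%d", targets$chrom, as.integer(targets$start),
          as.integer(targets$end))
}
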