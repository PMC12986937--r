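# Internal helpers: argument checking and reproducible seed streams.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a single finite number")
  if (x < lower || x > upper)
    abort_field(field, sprintf("must be in [%g, %g]", lower, upper))
  if (!allow_zero && x == 0) abort_field(field, "must be nonzero")
  invisible(x)
}

check_count <- function(x, field, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    abort_field(field, "must be a single integer")
  if (x < lower) abort_field(field, sprintf("must be >= %d", lower))
  invisible(as.integer(x))
}

#' Derive a child seed from a master seed and a stream tag
#'
#' Fans a single user-facing seed out to independent, stably named random
#' streams (per record, per module, per epoch) so that every component is
#' reproducible in isolation. Uses a 31-bit polynomial string hash; the result
#' is always a valid `set.seed()` input.
#'
#' @param seed Integer master seed.
#' @param tag Character stream name.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  check_number(seed, "seed")
  stopifnot(is.character(tag), length(tag) == 1L)
  h <- abs(as.double(seed)) %% 2147483647
  for (cc in utf8ToInt(tag)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 32-bit multiplicative string hash, as 8 hex digits. Used for pipeline
# manifests (config/input fingerprints), not cryptographic.
content_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (cc in utf8ToInt(x)) h <- ((h + cc) * 16777619) %% 4294967296
  lo <- h %% 65536
  hi <- (h - lo) / 65536
  sprintf("%04x%04x", hi, lo)
}
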