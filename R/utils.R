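# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Generators must be pure functions of their spec, so they never disturb the
# session RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_scalar_number <- function(x, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be a single non-missing number")
  }
  if (x < lo || x > hi) {
    stop_field(field, sprintf("must lie in [%s, %s]", format(lo), format(hi)))
  }
  invisible(x)
}

assert_rgb_triplet <- function(x, field) {
  if (!is.numeric(x) || length(x) != 3L || anyNA(x) || any(x < 0) || any(x > 255)) {
    stop_field(field, "must be an RGB triplet with values in [0, 255]")
  }
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary01 <- function(x) all(x %in% c(0, 1))
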