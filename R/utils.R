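# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.  All stochastic package
# operations funnel through this so identical seeds give identical
# output regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-item child seed from a master seed; kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + i * 9973) %% 2147483629) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)

# ITU-R BT.601 luma weights, used both for grayscale conversion and for
# reasoning about palette luminance.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)
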