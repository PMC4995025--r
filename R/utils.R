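# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Two-sided normal quantile for a confidence level, e.g. 1.959964 at 0.95.
ci_z <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  stats::qnorm((1 + level) / 2)
}

# Derive a reproducible sub-seed from a root seed and an operation tag, so
# that independent stages consume independent streams and adding draws to one
# stage does not perturb another. Kept within 32-bit signed range.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 69069 + h * 1013) %% 2147483587L)
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = leave the
# global stream alone).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(as.integer(seed))
  force(expr)
}

assert_numeric_col <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("column '%s' must be numeric", name), call. = FALSE)
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
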