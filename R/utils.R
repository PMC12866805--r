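#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop with the offending field named, so
# configuration errors point at what to fix.
.check <- function(ok, ..., call. = FALSE) {
  if (!isTRUE(ok)) stop(..., call. = call.)
  invisible(TRUE)
}

.is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

.is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Deterministic sub-stream seeds: one user-facing seed per run, stage seeds
# derived from it.  Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(.is_count(abs(seed)), .is_count(stream))
  as.integer((abs(as.double(seed)) * 48271 + stream * 1597) %% 2147483629)
}

# Evaluate `expr` under `seed` without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
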