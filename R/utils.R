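# internal helpers

# Run code with a temporarily seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed for a named stage from a root seed.
# Kept well below .Machine$integer.max for 32-bit safety.
sub_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000000L) * 1000L + (h + as.integer(index)) %% 1000L
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite value in ", what, call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
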