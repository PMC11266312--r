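#' @keywords internal
"_PACKAGE"

# Reproducibility: every stochastic entry point takes a `seed` argument and
# evaluates under a locally scoped Mersenne-Twister / Inversion RNG state, so
# callers' RNG streams are never disturbed and identical seeds give identical
# output on every platform.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

# derive a child seed from a base seed, staying inside 32-bit integer range
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1009 + offset) %% 2147483629
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    bad <- which(!is.finite(x) | x <= 0)
    stop_config("%s must be positive and finite (offending index: %s)",
                name, paste(utils::head(bad, 5L), collapse = ", "))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
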