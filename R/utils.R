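#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  All seed-taking functions in the package route
# through this so that identical seeds give identical output regardless of
# what ran before.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-replicate seed streams below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

msg <- function(..., verbose = getOption("clonintro.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
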