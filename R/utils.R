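#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded helpers never perturb a
#' surrounding simulation.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
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
  set.seed(as.integer(seed))
  code
}

# Derive a stream-specific child seed from a master seed, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) %% 1009L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() that never treats a length-1 vector as 1:x
resample <- function(x, size = length(x), ...) {
  x[sample.int(length(x), size, ...)]
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("`%s` must be a single number >= %s", name, format(min)))
  }
  invisible(x)
}
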