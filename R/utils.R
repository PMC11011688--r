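# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All seeded package functions go
# through this so that library calls never clobber user RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

# Derive `n` child seeds from a master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_beefhsi <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "beefhsi_error")))
}

assert_spectrum_pair <- function(x, u) {
  if (length(x) != length(u)) {
    stop_beefhsi("spectrum lengths differ: %d vs %d", length(x), length(u),
                 class = "beefhsi_length_error")
  }
}
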