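#' Derive a stage seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds through a fixed affine
#' counter scheme, so each stage is independently reproducible. Results stay
#' below 2^31 so they are always representable as R integers.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage counter (0, 1, 2, ...).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((abs(as.numeric(seed)) + 7919 * as.numeric(stage)) %% 2147483647)
}

# run code under a local RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# frequency grid of an n-point DFT at sampling interval d (cycles per unit)
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
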