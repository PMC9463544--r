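#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with a stream index into an integer seed in
#' `[0, 2^31)`. Used so that every stochastic stage (each wavelength, each
#' measurement repeat, each photon batch) draws from an independent,
#' counter-derived stream of one master seed.
#'
#' @param seed Master seed (non-negative integer-valued scalar).
#' @param index Stream index (non-negative integer-valued scalar).
#' @return A single integer-valued double in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(index), length(index) == 1L, index >= 0)
  derive_stream_seed_cpp(as.double(seed), as.double(index))
}

# Run code under a given RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Trapezoid-rule integral on an irregular grid.
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

stop_ewdrs <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ewdrs_error")))
}
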