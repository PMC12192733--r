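#' @importFrom rlang %||% .data :=
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats predict
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Deterministic RNG scope: evaluate `expr` under `seed` without touching the
# caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of sub-seeds from a master seed, kept within 32-bit range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
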