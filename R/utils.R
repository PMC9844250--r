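#' @keywords internal
#' @useDynLib dircon, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run an expression with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_dircon <- function(...) stop(..., call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_dircon(sprintf("non-finite values in %s", what))
  invisible(x)
}

# Nearest-integer rounding with halves away from zero (the usual reading of
# the bracket notation for per-class fold sizes).
round_half_up <- function(x) floor(x + 0.5)

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable row-wise softmax of a matrix.
row_softmax <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))
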