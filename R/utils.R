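# Internal helpers: classed errors, rounding, RNG hygiene.

gf_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "gf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Round half away from zero
#'
#' Report-level rounding used throughout the package (R's `round()` rounds
#' half to even, which does not match how clinical tables are printed).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties going away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # round(x * f, 9) guards against binary representation of exact halves
  sign(x) * floor(round(abs(x) * f, 9) + 0.5) / f
}

# Truncated normal via inverse-CDF (exact, no rejection).
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Run `expr` under a private RNG seed, restoring the caller's RNG state.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Session cache (attention-model calibrations are deterministic but costly).
.gf_cache <- new.env(parent = emptyenv())
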