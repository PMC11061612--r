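# Internal helpers shared across modules.

#' Two-parameter logistic inhibition curve
#'
#' Inhibition as a function of dose for a curve with asymptotes fixed at 0
#' (no effect) and 1 (complete growth inhibition): `1 / (1 + (ic50/d)^slope)`.
#' The midpoint of the curve sits at `d = ic50`.
#'
#' @param d Dose(s), strictly positive, same units as `ic50`.
#' @param ic50 Dose giving half-maximal inhibition; must be positive.
#' @param slope Dimensionless shape parameter; must be positive.
#' @return Numeric vector of inhibition values in `[0, 1]`.
#' @examples
#' logistic2p(c(0.1, 1, 10), ic50 = 1, slope = 2)
#' @export
logistic2p <- function(d, ic50, slope) {
  stopifnot(all(d > 0), ic50 > 0, slope > 0)
  1 / (1 + (ic50 / d)^slope)
}

# Clip to the probability scale used by Bliss/HSA.
clip01 <- function(x) pmin(1, pmax(0, x))

# Round half away from zero to `digits` decimals (printed responder
# percentages use this convention, e.g. 42.85 -> 42.9), unlike base round()
# which rounds half to even.
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Counter-based substream seed: hash a string key together with the global
# seed so each simulated entity (cell line, drug, plate, ...) owns its own
# reproducible stream and adding entities never perturbs existing ones.
substreamSeed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  as.integer((h + (as.numeric(seed) %% 2147483647) * 97003) %% 2147483646) + 1L
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# stop() with a consistent input-error prefix
inputError <- function(...) stop(..., call. = FALSE)
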