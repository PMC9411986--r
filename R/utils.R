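# Internal helpers shared across modules.

# fmol -> nmol
FMOL_TO_NMOL <- 1e-6

# mM change per hour per unit volumetric rate (nmol cm^-3 d^-1):
# 1 nmol cm^-3 = 1 uM = 1e-3 mM, spread over 24 h.
RATE_TO_MM_PER_H <- 1e-3 / 24

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run an expression under a fixed RNG seed without touching the global stream
#' @noRd
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Standard deviation of log for a multiplicative log-normal with given CV
#' @noRd
cv_to_sdlog <- function(cv) {
  stopifnot(cv >= 0, cv < 1)
  sqrt(log1p(cv^2))
}

#' Median-preserving multiplicative log-normal noise
#'
#' meanlog = log(truth), so log-scale statistics (geometric means, log-linear
#' fits) are unbiased. Zero truth values stay exactly zero.
#' @noRd
apply_lognormal_noise <- function(x, cv) {
  if (cv == 0) return(x)
  sdlog <- cv_to_sdlog(cv)
  out <- x * exp(stats::rnorm(length(x), 0, sdlog))
  out[x == 0] <- 0
  out
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    stop(sprintf("`%s` = %g is out of range", name, x), call. = FALSE)
  }
  invisible(x)
}
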