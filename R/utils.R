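## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_dmy <- function(..., class = "ampmyield_error") {
  rlang::abort(paste0(...), class = class)
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_dmy(...)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

## Truncated-normal sampler by inverse-CDF; bounds are in standard units
## of the parent normal. Vectorised over n.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

## Mean of a normal truncated to [lo, hi] (used by tests as an oracle and
## by the generator's calibration summary).
truncnorm_mean <- function(mean, sd, lo, hi) {
  if (sd == 0) return(mean)
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

## Deterministic sub-seed derivation; keeps results below 2^31 so they are
## valid R integer seeds.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1299721) %% 2147483647)
}

## Coefficients of an lm with aliased (rank-deficient) terms zeroed.
coef_zeroed <- function(fit) {
  co <- coef(fit)
  co[is.na(co)] <- 0
  co
}

## Standard-error accessor tolerant of aliased terms (returns NA for
## terms dropped from the summary table).
se_of <- function(fit) {
  sm <- summary(fit)$coefficients
  function(nm) {
    if (nm %in% rownames(sm)) unname(sm[nm, "Std. Error"]) else NA_real_
  }
}

## Stable short hash of an R object (used to stamp pipeline outputs).
config_hash <- function(x) {
  rlang::hash(x)
}
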