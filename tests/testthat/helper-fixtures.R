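# Fixture builders used across the suite. Everything is generated in
# code; no stored data.

# A minimal valid paired record; override any field.
toy_record <- function(cow_id = "C1", herd_id = "H1", breed = "Holstein",
                       parity = 1L, lactation_month = 5L, dim = 150L,
                       am_interval_h = 12.5, pm_interval_h = 11.5,
                       am_yield_kg = 16, pm_yield_kg = 15,
                       measured_session = "AM") {
  tibble::tibble(
    cow_id = cow_id, herd_id = herd_id, breed = breed, parity = parity,
    lactation_month = lactation_month, dim = dim,
    am_interval_h = am_interval_h, pm_interval_h = pm_interval_h,
    am_yield_kg = am_yield_kg, pm_yield_kg = pm_yield_kg,
    measured_session = measured_session
  )
}

toy_records <- function(n, ...) {
  args <- list(...)
  if (!"cow_id" %in% names(args)) args$cow_id <- sprintf("C%03d", seq_len(n))
  rec <- do.call(toy_record, lapply(args, function(a) rep(a, length.out = n)))
  rec
}

# Records whose AM and PM rows both satisfy the exponential-regression
# model exactly (no noise): for each pair of intervals the daily yield
# solves x(t_am) + x(t_pm) = y with x(t) = (y exp(-a - b_t t - g dd))^(1/b).
exact_m8_records <- function(t_am, t_pm, dim, alpha = 1.86, beta = -0.065,
                             gamma = 0, b = 0.86, d0 = 158) {
  n <- length(t_am)
  y <- numeric(n)
  x_am <- numeric(n)
  x_pm <- numeric(n)
  for (i in seq_len(n)) {
    dd <- dim[i] - d0
    part <- function(yy, tt) (yy * exp(-alpha - beta * tt - gamma * dd))^(1 / b)
    f <- function(yy) part(yy, t_am[i]) + part(yy, t_pm[i]) - yy
    y[i] <- uniroot(f, c(1, 200), tol = 1e-12)$root
    x_am[i] <- part(y[i], t_am[i])
    x_pm[i] <- part(y[i], t_pm[i])
  }
  toy_records(n, am_interval_h = t_am, pm_interval_h = t_pm,
              dim = as.integer(round(dim)),
              am_yield_kg = x_am, pm_yield_kg = x_pm,
              measured_session = rep(c("AM", "PM"), length.out = n))
}

# Stochastic exponential-model data with exogenous AM regressors: the AM
# rows follow the model with independent lognormal noise; the PM yield
# is the remainder of the daily total (so only the AM-separate fit is a
# clean recovery target).
noisy_m8_am_records <- function(n, alpha = 1.86, beta = -0.065,
                                gamma = -2e-4, b = 0.86, sigma = 0.06,
                                d0 = 158, seed = 1) {
  withr::with_seed(seed, {
    t_am <- runif(n, 9, 15)
    dim <- sample(30:300, n, replace = TRUE)
    x_am <- exp(rnorm(n, log(15), 0.2))
    eps <- rnorm(n, 0, sigma)
    y <- x_am^b * exp(alpha + beta * t_am + gamma * (dim - d0) + eps)
    pm <- pmax(y - x_am, 0.1)
    toy_records(n, am_interval_h = t_am, pm_interval_h = 24 - t_am,
                dim = as.integer(dim), am_yield_kg = x_am, pm_yield_kg = pm,
                measured_session = "AM")
  })
}

grid_default <- function() mic_grid(6, 20, 1)
grid_centered <- function() mic_grid(5.5, 19.5, 1)
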