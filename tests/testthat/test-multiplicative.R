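test_that("M5 smooths bulk proportions with a quadratic reciprocal", {
  g <- mic_grid(9, 15, 1)
  # equal split everywhere: constant quadratic at 0.5, F = 2
  withr::with_seed(3, {
    t <- runif(60, 9, 15)
    rec <- toy_records(60, am_interval_h = t, pm_interval_h = 24 - t,
                       am_yield_kg = 15, pm_yield_kg = 15)
  })
  fit <- fit_m5(rec, g)
  expect_equal(fit$table$F, rep(2, nrow(fit$table)), tolerance = 1e-8)

  # proportions on a known quadratic: exact coefficient recovery
  p_true <- function(t) 0.8 - 0.04 * t + 0.001 * t^2
  mids <- g$midpoints
  rec2 <- dplyr::bind_rows(lapply(seq_along(mids), function(k) {
    toy_records(2, am_interval_h = mids[k], pm_interval_h = 24 - mids[k],
                am_yield_kg = 30 * p_true(mids[k]),
                pm_yield_kg = 30 * (1 - p_true(mids[k])))
  }))
  fit2 <- fit_m5(rec2, g)
  expect_equal(unname(fit2$coefficients$AM),
               c(0.8, -0.04, 0.001), tolerance = 1e-8)

  # brute-force polynomial least squares oracle on a toy proportion table
  props <- c(0.54, 0.52, 0.50, 0.48, 0.46)
  mids5 <- 10:14
  g5 <- mic_grid(9.5, 14.5, 1)
  rec3 <- dplyr::bind_rows(lapply(1:5, function(k) {
    toy_records(2, am_interval_h = mids5[k], pm_interval_h = 24 - mids5[k],
                am_yield_kg = 20 * props[k] + c(-0.3, 0.3),
                pm_yield_kg = 20 * (1 - props[k]) - c(-0.3, 0.3))
  }))
  fit3 <- fit_m5(rec3, g5)
  X <- cbind(1, mids5, mids5^2)
  bulk_p <- props  # bulk sums cancel the +-0.3 perturbation within bins
  beta <- solve(crossprod(X), crossprod(X, bulk_p))
  expect_equal(fit3$table$F[fit3$table$session == "AM"],
               1 / as.numeric(X %*% beta), tolerance = 1e-8)

  expect_error(fit_m5(rec3[1:2, ], g5), "3 populated bins")
})

test_that("M6 per-bin slopes match the closed-form no-intercept oracle", {
  g <- mic_grid(9, 15, 1)
  # y = 2x exactly: flat reciprocal line, F = 2 everywhere
  withr::with_seed(4, {
    t <- runif(80, 9, 15)
    x <- runif(80, 10, 20)
    rec <- toy_records(80, am_interval_h = t, pm_interval_h = 24 - t,
                       am_yield_kg = x, pm_yield_kg = x)
  })
  fit <- fit_m6(rec, g)
  expect_equal(fit$table$F, rep(2, nrow(fit$table)), tolerance = 1e-8)

  # single-bin hand case {(10,21), (12,25)} without the DIM term
  rec2 <- toy_records(4, am_interval_h = c(12.2, 12.7, 10.5, 10.6),
                      pm_interval_h = c(11.8, 11.3, 13.5, 13.4),
                      am_yield_kg = c(10, 12, 11, 11),
                      pm_yield_kg = c(11, 13, 11, 11))
  fit2 <- fit_m6(rec2, g, use_dim = FALSE)
  b_hand <- (10 * 21 + 12 * 25) / (10^2 + 12^2)
  am <- fit2$table[fit2$table$session == "AM", ]
  expect_equal(am$b_raw[am$bin_lo == 12], b_hand)

  # prediction applies F x + per-bin gamma (dim - d0)
  rec3 <- generate_milking_data(breed_profile("holstein"), 400, 2, seed = 6)
  fit3 <- fit_m6(rec3, grid_default())
  tab <- fit3$table
  v <- toy_record(am_interval_h = 12.5, dim = 200L, am_yield_kg = 16)
  row <- tab[tab$session == "AM" & tab$bin_lo == 12, ]
  expect_equal(predict_multiplicative(v, fit3),
               row$F * 16 + row$gamma * (200 - 158))
})

test_that("M7 ratio regression matches its oracle and factor tables", {
  # constant ratio: intercepts 0.5, zero slopes
  withr::with_seed(5, {
    t <- runif(50, 9, 15)
    y <- runif(50, 25, 35)
    rec <- toy_records(50, am_interval_h = t, pm_interval_h = 24 - t,
                       dim = sample(50L:250L, 50, TRUE),
                       am_yield_kg = y / 2, pm_yield_kg = y / 2)
  })
  fit <- fit_m7(rec)
  expect_equal(fit$coefficients$alpha, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(fit$coefficients$beta[1], 0, tolerance = 1e-10)

  # 5 hand-written records vs normal equations on the stacked design
  rec2 <- toy_records(5, am_interval_h = c(10, 11, 12, 13, 14),
                      pm_interval_h = c(14, 13, 12, 11, 10),
                      dim = c(80L, 120L, 160L, 200L, 240L),
                      am_yield_kg = c(14, 15, 15.5, 16, 17),
                      pm_yield_kg = c(13, 14, 15, 14.5, 15))
  fit2 <- fit_m7(rec2)
  long <- ampmyield:::stack_sessions(rec2)
  X <- cbind(am = as.numeric(long$session == "AM"),
             pm = as.numeric(long$session == "PM"),
             t = long$t, dd = long$dim - 158)
  beta <- solve(crossprod(X), crossprod(X, long$x / long$y))
  expect_equal(fit2$coefficients$alpha, unname(beta[c("am", "pm"), 1]))
  expect_equal(fit2$coefficients$beta[1], unname(beta["t", 1]))

  # factor table is the element-wise reciprocal of the line at midpoints
  g <- mic_grid(9, 15, 1)
  tab <- mcf_from_ratio_fit(fit2, g)
  cf <- fit2$coefficients[fit2$coefficients$session == "AM", ]
  expect_equal(tab$F[tab$session == "AM"],
               1 / (cf$alpha + cf$beta * g$midpoints))

  # hand arithmetic: alpha 0.05, beta 0.0375 at t = 12 -> F = 2
  fit2$coefficients$alpha <- c(0.05, 0.05)
  fit2$coefficients$beta <- c(0.0375, 0.0375)
  fit2$coefficients$gamma <- c(0, 0)
  tab2 <- mcf_from_ratio_fit(fit2, mic_grid(11.5, 12.5, 1))
  expect_equal(tab2$F, c(2, 2))

  # non-positive denominators are an error naming the bin
  fit2$coefficients$alpha <- c(0.5, 0.5)
  fit2$coefficients$beta <- c(-0.05, -0.05)
  expect_error(mcf_from_ratio_fit(fit2, mic_grid(9, 15, 1)), "bin")
})

test_that("M7A and M7B agree at bin midpoints with d = d0", {
  rec <- generate_milking_data(breed_profile("holstein"), 600, 2, seed = 9)
  g <- grid_default()
  mA <- fit_dmy_model(rec, "M7A", grid = g)
  mB <- fit_dmy_model(rec, "M7B", grid = g)
  test <- toy_records(3, am_interval_h = c(10.5, 12.5, 13.5),
                      pm_interval_h = 11.5, dim = 158L,
                      am_yield_kg = c(12, 15, 18), pm_yield_kg = 14)
  expect_equal(predict(mB, test), predict(mA, test), tolerance = 1e-10)
})

test_that("M8 recovers exact exponential structure and matches its oracle", {
  # noise-free: both sessions constructed to satisfy the model exactly
  withr::with_seed(11, {
    t_am <- runif(40, 10, 14)
    rec <- exact_m8_records(t_am, 24 - t_am, dim = sample(50:250, 40, TRUE),
                            alpha = 1.86, beta = -0.065, b = 0.86)
  })
  fit <- fit_m8(rec)
  expect_equal(fit$coefficients$alpha, c(1.86, 1.86), tolerance = 1e-6)
  expect_equal(fit$coefficients$beta[1], -0.065, tolerance = 1e-6)
  expect_equal(fit$coefficients$b[1], 0.86, tolerance = 1e-6)
  # direct prediction reproduces the daily yields
  m <- fit_dmy_model(rec, "M8A")
  expect_equal(predict(m, rec), rec$am_yield_kg + rec$pm_yield_kg,
               tolerance = 1e-6)

  # b = 1, alpha = log 2: doubling as a special case (y = 2x for any y,
  # so daily yields are drawn freely and split evenly)
  withr::with_seed(12, {
    t_am <- runif(30, 10, 14)
    yy <- exp(rnorm(30, log(30), 0.2))
    rec2 <- toy_records(30, am_interval_h = t_am, pm_interval_h = 24 - t_am,
                        dim = 158L, am_yield_kg = yy / 2,
                        pm_yield_kg = yy / 2)
  })
  fit2 <- fit_m8(rec2)
  expect_equal(fit2$coefficients$alpha[1], log(2), tolerance = 1e-6)
  expect_equal(fit2$coefficients$b[1], 1, tolerance = 1e-6)

  # 6 hand-written records vs log-scale normal equations
  rec3 <- toy_records(6, am_interval_h = c(10, 11, 12, 13, 14, 12.5),
                      pm_interval_h = c(14, 13, 12, 11, 10, 11.5),
                      dim = c(60L, 100L, 140L, 180L, 220L, 260L),
                      am_yield_kg = c(13, 14, 15, 16, 17, 15.5),
                      pm_yield_kg = c(14, 13.5, 15, 14, 13, 15))
  fit3 <- fit_m8(rec3)
  long <- ampmyield:::stack_sessions(rec3)
  X <- cbind(am = as.numeric(long$session == "AM"),
             pm = as.numeric(long$session == "PM"),
             t = long$t, dd = long$dim - 158, lx = log(long$x))
  beta <- solve(crossprod(X), crossprod(X, log(long$y)))
  expect_equal(fit3$coefficients$alpha, unname(beta[c("am", "pm"), 1]))
  expect_equal(fit3$coefficients$beta[1], unname(beta["t", 1]))
  expect_equal(fit3$coefficients$b[1], unname(beta["lx", 1]))
})

test_that("M8 factor tables evaluate the lognormal-moment expression", {
  # degenerate variances give rho = 1 and the M8B = M8A coincidence
  rec <- toy_records(6, am_interval_h = 12.5, pm_interval_h = 11.5,
                     dim = 158L, am_yield_kg = 16, pm_yield_kg = 15)
  fit <- fit_dmy_model(rec, "M8A")$fit
  g <- mic_grid(11, 13, 1)
  tab <- mcf_m8(fit, g, rec)
  am <- tab[tab$session == "AM" & tab$bin_lo == 12, ]
  expect_equal(am$rho, 1)
  v <- toy_record(am_interval_h = 12.5, dim = 158L, am_yield_kg = 16)
  expect_equal(predict_multiplicative(v, tab),
               predict_multiplicative(v, fit), tolerance = 1e-10)

  # single-expression oracle for a hand-specified bin
  Ex <- 16; Vx <- 4; Ey <- 32; Vy <- 16
  bb <- 0.9; aa <- 1.8; be <- -0.06; tbar <- 12
  rho <- exp(0.5 * (Vy / Ey^2 - bb * Vx / Ex^2))
  f_oracle <- Ex^(bb - 1) * rho * exp(aa + be * tbar)
  fit$coefficients$alpha <- c(aa, aa)
  fit$coefficients$beta <- c(be, be)
  fit$coefficients$b <- c(bb, bb)
  withr::with_seed(13, {
    x <- rnorm(400, Ex, sqrt(Vx) * sqrt(399 / 400))
    y <- rnorm(400, Ey, sqrt(Vy) * sqrt(399 / 400))
    rec2 <- toy_records(400, am_interval_h = 12, pm_interval_h = 12,
                        am_yield_kg = x, pm_yield_kg = pmax(y - x, 0.1))
  })
  tab2 <- mcf_m8(fit, mic_grid(11.5, 12.5, 1), rec2)
  am2 <- tab2[tab2$session == "AM", ]
  f_direct <- am2$Ex^(bb - 1) *
    exp(0.5 * (am2$Vy / am2$Ey^2 - bb * am2$Vx / am2$Ex^2)) *
    exp(aa + be * 12)
  expect_equal(am2$F, f_direct, tolerance = 1e-12)

  # singleton bins are treated as unpopulated and flagged imputed
  rec3 <- dplyr::bind_rows(
    toy_records(5, am_interval_h = 11.5, pm_interval_h = 12.5,
                am_yield_kg = c(14, 15, 16, 15, 14), pm_yield_kg = 14),
    toy_record(am_interval_h = 12.6, pm_interval_h = 11.4)
  )
  tab3 <- mcf_m8(fit, mic_grid(11, 13, 1), rec3)
  am3 <- tab3[tab3$session == "AM", ]
  expect_true(am3$imputed[am3$bin_lo == 12])
  expect_false(am3$imputed[am3$bin_lo == 11])
})

test_that("M8 parameter estimates are unbiased on exogenous simulated data", {
  truth <- c(beta = -0.065, gamma = -2e-4, b = 0.86)
  reps <- 20
  est <- matrix(NA_real_, reps, 3, dimnames = list(NULL, names(truth)))
  for (r in seq_len(reps)) {
    rec <- noisy_m8_am_records(10000, beta = truth["beta"],
                               gamma = truth["gamma"], b = truth["b"],
                               seed = 100 + r)
    fit <- fit_m8(rec, model_spec("M8", "direct", "separate"))
    cf <- fit$coefficients[fit$coefficients$session == "AM", ]
    est[r, ] <- c(cf$beta, cf$gamma, cf$b)
  }
  for (p in names(truth)) {
    bias <- mean(est[, p]) - truth[p]
    se <- sd(est[, p]) / sqrt(reps)
    expect_lt(abs(bias), 3 * se)
  }
})

test_that("factors are positive and near 2 at matched 12-h intervals", {
  rec <- generate_milking_data(breed_profile("symmetric"), 4000, 2, seed = 17)
  g <- grid_centered()
  at12 <- function(tab) tab$F[abs(tab$midpoint - 12) < 1e-8]
  m5 <- fit_m5(rec, g)
  m6 <- fit_m6(rec, g)
  m7 <- mcf_from_ratio_fit(fit_m7(rec), g)
  m8 <- mcf_m8(fit_m8(rec), g, rec)
  for (tab in list(m5$table, m6$table, m7, m8)) {
    expect_true(all(tab$F > 0))
    expect_equal(at12(tab), c(2, 2), tolerance = 0.1)
  }

  # monotone factor structure on asymmetric data: AM factors decrease
  # with AM interval, above 2 below 12 h and below 2 above it
  reca <- generate_milking_data(breed_profile("holstein"), 4000, 2, seed = 18)
  tab <- mcf_from_ratio_fit(fit_m7(reca), g)
  am <- tab[tab$session == "AM" & tab$midpoint >= 9 & tab$midpoint <= 15, ]
  expect_true(all(diff(am$F) < 0))
  expect_gt(am$F[am$midpoint == 10], 2)
  expect_lt(am$F[am$midpoint == 14], 2)
  pm <- tab[tab$session == "PM" & tab$midpoint >= 9 & tab$midpoint <= 15, ]
  expect_gt(pm$F[pm$midpoint == 10], 2)
})
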