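test_that("doubling estimator is exact arithmetic", {
  expect_equal(predict_m0(c(16.4, 0, 15.3)), c(32.8, 0, 30.6))
  expect_error(predict_m0(-1), ">= 0")
})

test_that("model specs police admissible strategies", {
  expect_error(model_spec("M1", strategy = "direct"), "factor")
  expect_error(model_spec("M4", strategy = "factor"), "direct")
  expect_equal(model_label(as_model_spec("M3B")), "M3B")
  expect_equal(as_model_spec("M7A")$strategy, "direct")
  expect_error(as_model_spec("M9"), "unrecognized")
})

test_that("categorical ACF cells equal brute-force per-cell means", {
  # 3 MIC x 2 LM toy layout with hand-filled differences
  g <- mic_grid(10, 13, 1)
  rec <- toy_records(
    12,
    am_interval_h = rep(c(10.5, 11.5, 12.5), each = 4),
    pm_interval_h = rep(c(10.5, 11.5, 12.5), each = 4),
    lactation_month = rep(c(2L, 2L, 7L, 7L), times = 3),
    am_yield_kg = 15,
    pm_yield_kg = 15 + c(1, 3, -2, 0, 0.5, 1.5, 2, 4, -1, 1, 0, 2)
  )
  fit <- fit_m1(rec, g)
  long <- ampmyield:::stack_sessions(rec)
  long$mic <- as.integer(assign_mic(long$t, g))
  oracle <- tapply(long$z, list(long$session, long$mic, long$lactation_month),
                   mean)
  cells <- fit$cells[!fit$cells$imputed, ]
  for (i in seq_len(nrow(cells))) {
    expect_equal(
      cells$delta[i],
      oracle[cells$session[i], as.character(cells$mic[i]),
             as.character(cells$lactation_month[i])]
    )
  }
  # single cell {1, 3} -> mean 2 with the AM/PM sign convention
  am_cells <- cells[cells$session == "AM" & cells$mic == 1, ]
  expect_equal(am_cells$delta[am_cells$lactation_month == 2], 2)

  # zero differences give a zero table
  rec0 <- toy_records(6, am_yield_kg = 15, pm_yield_kg = 15)
  fit0 <- fit_m1(rec0, g)
  expect_true(all(fit0$cells$delta == 0))
  expect_error(fit_m1(rec[0, ], g), "no training")
})

test_that("empty M1 cells are imputed from marginals, never silently zero", {
  g <- mic_grid(10, 13, 1)
  rec <- toy_records(4, am_interval_h = 10.5, pm_interval_h = 10.5,
                     lactation_month = 2L,
                     am_yield_kg = 15, pm_yield_kg = c(16, 18, 17, 17))
  fit <- fit_m1(rec, g, lm_levels = c(2L, 7L))
  empty <- fit$cells[fit$cells$mic == 3, ]
  expect_true(all(empty$imputed))
  # falls back to the session mean (no data in that MIC at all)
  expect_equal(empty$delta[empty$session == "AM"],
               rep(mean(c(16, 18, 17, 17) - 15), 2))
})

test_that("additive regressions recover known coefficients", {
  # noise-free linear structure: exact interpolation
  withr::with_seed(10, {
    n <- 60
    t_am <- runif(n, 10, 14)
    t_pm <- 24 - t_am
    d <- sample(50:250, n, replace = TRUE)
    x_am <- runif(n, 12, 20)
    y <- 26.7 - 1.9 * t_am - 0.005 * (d - 158) + 1.75 * x_am
    rec <- toy_records(n, am_interval_h = t_am, pm_interval_h = t_pm,
                       dim = as.integer(d), am_yield_kg = x_am,
                       pm_yield_kg = y - x_am)
  })
  fit <- fit_additive_regression(rec, model_spec("M3", "direct",
                                                 session_scope = "separate"))
  cf <- fit$coefficients[fit$coefficients$session == "AM", ]
  expect_equal(cf$alpha, 26.7, tolerance = 1e-8)
  expect_equal(cf$beta, -1.9, tolerance = 1e-8)
  expect_equal(cf$gamma, -0.005, tolerance = 1e-8)
  expect_equal(cf$b, 1.75, tolerance = 1e-8)
  # direct prediction reproduces y exactly
  m <- fit_dmy_model(rec, model_spec("M3", "direct",
                                     session_scope = "separate"))
  expect_equal(predict(m, rec), y, tolerance = 1e-8)
})

test_that("M3 coefficients equal the closed-form normal-equations oracle", {
  rec <- toy_records(4,
    am_interval_h = c(11, 12, 13, 14), pm_interval_h = c(13, 12, 11, 10),
    dim = c(100L, 150L, 200L, 250L),
    am_yield_kg = c(14, 16, 18, 15), pm_yield_kg = c(13, 15, 14, 12)
  )
  fit <- fit_additive_regression(rec, model_spec("M3", "direct"))
  long <- ampmyield:::stack_sessions(rec)
  X <- cbind(am = as.numeric(long$session == "AM"),
             pm = as.numeric(long$session == "PM"),
             t = long$t, dd = long$dim - 158, x = long$x)
  beta_oracle <- solve(crossprod(X), crossprod(X, long$y))
  cf <- fit$coefficients
  expect_equal(cf$alpha[cf$session == "AM"], unname(beta_oracle["am", 1]))
  expect_equal(cf$alpha[cf$session == "PM"], unname(beta_oracle["pm", 1]))
  expect_equal(cf$beta[1], unname(beta_oracle["t", 1]))
  expect_equal(cf$gamma[1], unname(beta_oracle["dd", 1]))
  expect_equal(cf$b[1], unname(beta_oracle["x", 1]))
})

test_that("M2 equals the offset formulation and degenerate designs obey the singularity rule", {
  rec <- generate_milking_data(breed_profile("holstein"), 300, 2, seed = 21)
  fit <- fit_additive_regression(rec, model_spec("M2"))
  long <- ampmyield:::stack_sessions(rec)
  long$dd <- long$dim - 158
  off <- lm(y ~ 0 + session + t + dd + offset(2 * x), data = long)
  cf <- fit$coefficients
  expect_equal(cf$alpha[cf$session == "AM"], unname(coef(off)["sessionAM"]))
  expect_equal(cf$alpha[cf$session == "PM"], unname(coef(off)["sessionPM"]))
  expect_equal(cf$beta[1], unname(coef(off)["t"]))
  expect_equal(cf$gamma[1], unname(coef(off)["dd"]))
  expect_true(all(cf$b == 2))

  # constant z with constant t, d: intercept picks up z, slopes zeroed
  recc <- toy_records(8, am_interval_h = 12, pm_interval_h = 12,
                      dim = 158L, am_yield_kg = 15, pm_yield_kg = 16.5)
  fitc <- fit_additive_regression(recc, model_spec("M2"))
  cfc <- fitc$coefficients
  expect_equal(cfc$alpha[cfc$session == "AM"], 1.5)
  expect_equal(cfc$beta[1], 0)
  expect_equal(cfc$gamma[1], 0)
})

test_that("ACF tables evaluate the fitted line at midpoints, both conventions", {
  rec <- generate_milking_data(breed_profile("holstein"), 400, 2, seed = 31)
  g <- grid_default()
  fit <- fit_additive_regression(rec, model_spec("M2", "factor"))
  tab <- acf_from_fit(fit, g, rec)
  cf <- fit$coefficients[fit$coefficients$session == "AM", ]
  am <- tab[tab$session == "AM", ]
  expect_equal(am$delta_kg, cf$alpha + cf$beta * g$midpoints)

  # with_dim convention reduces to the text convention when bin mean DIM = d0
  rec158 <- dplyr::mutate(rec, dim = 158L)
  tab2 <- acf_from_fit(fit, g, rec158, convention = "with_dim")
  expect_equal(tab2$delta_kg, tab$delta_kg)

  # beta = 0 gives a constant table; hand arithmetic for a single midpoint
  fit$coefficients$beta <- 0
  tabc <- acf_from_fit(fit, g, rec)
  expect_equal(unique(tabc$delta_kg[tabc$session == "AM"]), cf$alpha)
  fit$coefficients$alpha <- c(27, 27)
  fit$coefficients$beta <- c(-2, -2)
  tabh <- acf_from_fit(fit, mic_grid(12, 13, 1), rec)
  expect_equal(tabh$delta_kg, c(2, 2))
})

test_that("factor predictions apply delta + dim adjustment + b x", {
  # M2B hand case: delta = -1, gamma = 0, x = 16 -> 31
  rec <- toy_record(am_yield_kg = 16, dim = 158L)
  g <- mic_grid(12, 13, 1)
  tab <- structure(
    tibble::tibble(session = c("AM", "PM"), mic = 1L, bin_lo = 12,
                   bin_hi = 13, midpoint = 12.5, delta_kg = -1,
                   n_train = 5L, imputed = FALSE),
    class = c("acf_table", "tbl_df", "tbl", "data.frame"),
    gamma = c(AM = 0, PM = 0), b = c(AM = 2, PM = 2), d0 = 158,
    convention = "interval_only", model_id = "M2"
  )
  expect_equal(predict_additive(rec, tab), 31)

  # a zeroed M2 fit degenerates to doubling
  null_fit <- structure(
    list(spec = model_spec("M2", "direct"),
         coefficients = tibble::tibble(
           session = c("AM", "PM"), alpha = 0, alpha_se = 0, beta = 0,
           beta_se = 0, beta2 = 0, beta2_se = 0, gamma = 0, gamma_se = 0,
           gamma2 = 0, gamma2_se = 0, b = 2, b_se = 0)),
    class = c("additive_fit", "dmy_fit")
  )
  recs <- toy_records(5, am_yield_kg = c(10, 12, 14, 16, 18))
  expect_equal(predict_additive(recs, null_fit), predict_m0(recs$am_yield_kg))
})

test_that("direct and factor strategies coincide at bin midpoints with d = d0", {
  train <- generate_milking_data(breed_profile("holstein"), 500, 2, seed = 41)
  g <- grid_default()
  for (lab in c("M2", "M3")) {
    mA <- fit_dmy_model(train, model_spec(lab, "direct"), grid = g)
    mB <- fit_dmy_model(train, model_spec(lab, "factor"), grid = g)
    test <- toy_records(3, am_interval_h = c(10.5, 12.5, 14.5),
                        pm_interval_h = 11.5, dim = 158L,
                        am_yield_kg = c(12, 15, 18), pm_yield_kg = 14)
    expect_equal(predict(mB, test), predict(mA, test), tolerance = 1e-10)
  }
})

test_that("AM and PM ACF sum to zero on fully paired cells", {
  # identical AM/PM intervals put both rows of a record in the same cell,
  # where z_AM = -z_PM record-wise makes the sum vanish exactly
  withr::with_seed(7, {
    t <- runif(40, 10, 14)
    rec <- toy_records(40, am_interval_h = t, pm_interval_h = t,
                       lactation_month = 5L,
                       am_yield_kg = runif(40, 12, 18),
                       pm_yield_kg = runif(40, 12, 18))
  })
  g <- grid_default()
  fit <- fit_m1(rec, g)
  cells <- fit$cells[!fit$cells$imputed, ]
  sums <- tapply(cells$delta, cells$mic, sum)
  expect_equal(as.numeric(sums), rep(0, length(sums)), tolerance = 1e-8)

  # sampling-level version on generator data: the AM and PM corrections
  # cancel at the matched 12-h class (t_AM = t_PM = 12 sums to the 24-h
  # day, where z_AM = -z_PM record-wise)
  gen <- generate_milking_data(breed_profile("holstein"), 2000, 2, seed = 8)
  fit2 <- fit_additive_regression(gen, model_spec("M2", "factor"))
  tab <- acf_from_fit(fit2, grid_centered())
  mid <- tab[tab$midpoint == 12, ]
  expect_lt(abs(sum(mid$delta_kg)), 0.5)
})

test_that("joint fits are at least as precise as separate fits", {
  rec <- generate_milking_data(breed_profile("holstein"), 1500, 2, seed = 51)
  joint <- fit_additive_regression(rec, model_spec("M3", "direct", "joint"))
  sep <- fit_additive_regression(rec, model_spec("M3", "direct", "separate"))
  expect_lte(joint$coefficients$beta_se[1],
             min(sep$coefficients$beta_se))
  expect_lte(joint$coefficients$b_se[1], min(sep$coefficients$b_se))
})

test_that("the free-coefficient vs fixed-2.0 ACF gap follows its formula", {
  expect_equal(acf_regression_gap(16.4, 15.3, 1.72, 1.78),
               ((2 - 1.72) * 16.4 + (2 - 1.78) * 15.3) / 2)
})
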