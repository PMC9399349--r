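## Cubic smoothing splines: characterization of daily yield and of
## per-animal accuracy as smooth functions of milking interval, and
## model-implied mean-yield curves with average-absolute-deviation
## summaries.

#' Fit a cubic smoothing spline
#'
#' Minimizes `sum((y - f(x))^2) + lambda * integral(f''(x)^2 dx)` over
#' twice-differentiable functions. The smoothing parameter is chosen by
#' generalized cross-validation (default), by REML (via a cubic
#' penalized-regression-spline fit), or fixed. As `lambda -> 0` the fit
#' approaches the interpolating spline; as `lambda -> Inf` it approaches
#' the straight-line least-squares fit.
#'
#' @param x,y Observations; at least 4 distinct `x` values.
#' @param method `"GCV"` (default), `"REML"` or `"fixed"`.
#' @param lambda Smoothing parameter for `method = "fixed"` (on
#'   [stats::smooth.spline()]'s normalized scale).
#' @return Object of class `"css_fit"`; evaluate with `predict(fit, x)`.
#' @export
fit_css <- function(x, y, method = c("GCV", "REML", "fixed"),
                    lambda = NULL) {
  method <- match.arg(method)
  assert_that(length(x) == length(y), "x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  assert_that(length(unique(x)) >= 4, "need at least 4 distinct x values")
  if (method == "REML") {
    k <- min(30L, length(unique(x)) - 1L)
    fit <- mgcv::gam(y ~ s(x, bs = "cr", k = k), method = "REML",
                     data = data.frame(x = x, y = y))
    lambda_out <- unname(fit$sp[1])
  } else if (method == "fixed") {
    assert_that(is.numeric(lambda) && lambda >= 0,
                "fixed method needs lambda >= 0")
    fit <- smooth.spline(x, y, lambda = max(lambda, 1e-12),
                         all.knots = TRUE, keep.data = FALSE)
    lambda_out <- fit$lambda
  } else {
    fit <- smooth.spline(x, y, cv = FALSE, keep.data = FALSE)
    lambda_out <- fit$lambda
  }
  structure(
    list(fit = fit, method = method, lambda = lambda_out,
         range = range(x)),
    class = "css_fit"
  )
}

#' @export
predict.css_fit <- function(object, x, ...) {
  if (inherits(object$fit, "gam")) {
    as.numeric(predict(object$fit, newdata = data.frame(x = x)))
  } else {
    predict(object$fit, x)$y
  }
}

#' @export
print.css_fit <- function(x, ...) {
  cat("Cubic smoothing spline (", x$method, "), lambda = ",
      signif(x$lambda, 4), ", x range [", signif(x$range[1], 4), ", ",
      signif(x$range[2], 4), "]\n", sep = "")
  invisible(x)
}

#' Smoothing-spline mean curve over milking interval
#'
#' Fits a cubic smoothing spline of a per-record response against the
#' chosen session's milking interval and evaluates it on a grid of
#' interval values. Evaluation points outside the observed interval
#' range are dropped (no extrapolation); the number dropped is recorded
#' in the `"n_truncated"` attribute.
#'
#' @param records Paired records.
#' @param response `"daily_yield"` (AM + PM yield) or
#'   `"individual_r2"`, in which case `values` must supply the
#'   per-record accuracies (e.g. `R2_i` from [run_crossval()]).
#' @param session `"AM"` or `"PM"`: which session's interval is the
#'   abscissa.
#' @param eval_points Interval grid in hours (default 9-15 h by 0.1 h).
#' @param values Per-record response for `response = "individual_r2"`.
#' @param method Passed to [fit_css()].
#' @return Tibble `interval_h`, `value`, with the fitted `"css_fit"` as
#'   attribute `"fit"`.
#' @export
css_mean_curve <- function(records,
                           response = c("daily_yield", "individual_r2"),
                           session = "AM",
                           eval_points = seq(9, 15, by = 0.1),
                           values = NULL,
                           method = "GCV") {
  response <- match.arg(response)
  session <- match.arg(session, SESSIONS)
  t <- if (session == "AM") records$am_interval_h else records$pm_interval_h
  y <- if (response == "daily_yield") {
    records$am_yield_kg + records$pm_yield_kg
  } else {
    assert_that(!is.null(values) && length(values) == nrow(records),
                "individual_r2 needs per-record values")
    values
  }
  fit <- fit_css(t, y, method = method)
  keep <- eval_points >= fit$range[1] & eval_points <= fit$range[2]
  out <- tibble::tibble(
    interval_h = eval_points[keep],
    value = predict(fit, eval_points[keep])
  )
  attr(out, "fit") <- fit
  attr(out, "n_truncated") <- sum(!keep)
  out
}

#' Model-implied mean daily yield by milking interval
#'
#' At each evaluation interval `t`, predictions of a fitted estimator
#' are averaged over the empirical distribution of measured yield and
#' DIM among the session's records whose interval falls in the MIC bin
#' containing `t` (predictions are made at interval `t` itself). For
#' the doubling model this reduces to twice the local mean measured
#' yield, which makes the comparison with the smoothing-spline mean of
#' actual yields well-defined. `average = "global"` instead plugs in
#' the session-wide mean yield and DIM everywhere.
#'
#' @param model A [fit_dmy_model()] result (direct strategy).
#' @param records Records supplying the local covariate distribution.
#' @param session `"AM"` or `"PM"`.
#' @param grid A [mic_grid()] defining the local windows.
#' @param eval_points Interval grid, hours.
#' @param average `"local"` (default) or `"global"`.
#' @return Tibble `interval_h`, `value`; points whose window holds no
#'   records are omitted.
#' @export
model_mean_curve <- function(model, records, session, grid,
                             eval_points = seq(9, 15, by = 0.1),
                             average = c("local", "global")) {
  average <- match.arg(average)
  session <- match.arg(session, SESSIONS)
  long <- stack_sessions(records)
  dat <- long[long$session == session, ]
  dat$mic <- as.integer(assign_mic(dat$t, grid))

  rows <- lapply(eval_points, function(tv) {
    if (average == "local") {
      k <- as.integer(assign_mic(tv, grid))
      oog <- attr(assign_mic(tv, grid), "out_of_grid")
      sub <- dat[dat$mic == k, ]
      if (isTRUE(oog[1]) || nrow(sub) == 0) return(NULL)
      x_use <- sub$x
      d_use <- sub$dim
    } else {
      x_use <- mean(dat$x)
      d_use <- mean(dat$dim)
    }
    pseudo <- tibble::tibble(
      cow_id = "curve", herd_id = "curve", breed = "curve",
      parity = 1L, lactation_month = 1L,
      dim = d_use,
      am_interval_h = tv, pm_interval_h = 24 - tv,
      am_yield_kg = if (session == "AM") x_use else 0,
      pm_yield_kg = if (session == "PM") x_use else 0,
      measured_session = session
    )
    tibble::tibble(interval_h = tv,
                   value = mean(predict(model, pseudo)))
  })
  dplyr::bind_rows(rows)
}

#' Mean absolute deviation between two interval curves
#'
#' @param curve_a,curve_b Tibbles with columns `interval_h`, `value`
#'   (e.g. from [model_mean_curve()] and [css_mean_curve()]); compared
#'   on their common grid points (matched to 1e-8 h).
#' @return Mean of `|a - b|` over the common grid, in the response's
#'   units.
#' @export
curve_deviation <- function(curve_a, curve_b) {
  key_a <- round(curve_a$interval_h, 8)
  key_b <- round(curve_b$interval_h, 8)
  common <- intersect(key_a, key_b)
  assert_that(length(common) > 0, "curves share no grid points")
  a <- curve_a$value[match(common, key_a)]
  b <- curve_b$value[match(common, key_b)]
  mean(abs(a - b))
}
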