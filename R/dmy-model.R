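## One entry point over the whole estimator suite: fit any of the 13
## model/strategy variants on paired training records and predict daily
## yield for test records from their single measured milking.

#' Fit any daily-milk-yield estimator
#'
#' Dispatches on the [model_spec()] (or label): `M0` doubling, `M1`
#' categorical ACF, `M2`/`M3`/`M4` additive regressions, `M5`-`M8`
#' multiplicative families. For factor ("B") strategies the per-MIC
#' factor table is built at fit time from the training records, so a
#' cross-validation split never leaks test information into the table.
#'
#' @param records Paired training records.
#' @param spec A [model_spec()] or a label accepted by
#'   [as_model_spec()].
#' @param grid A [mic_grid()]; required for factor strategies.
#' @param acf_convention Passed to [acf_from_fit()] for M2B/M3B.
#' @param m7_dim_adjust Apply the ratio-scale DIM slope as an additive
#'   kg adjustment in M7B predictions (default TRUE, the literal
#'   published construction).
#' @param m5_weighted Weight M5's quadratic smoothing by bin counts.
#' @return Object of class `"dmy_model"` holding the spec, the
#'   underlying fit and (for factor strategies) the factor table.
#' @export
fit_dmy_model <- function(records, spec, grid = NULL,
                          acf_convention = "interval_only",
                          m7_dim_adjust = TRUE,
                          m5_weighted = FALSE) {
  spec <- as_model_spec(spec)
  needs_grid <- spec$strategy == "factor" && spec$model_id != "M0"
  assert_that(!needs_grid || inherits(grid, "mic_grid"),
              model_label(spec), " with factor strategy needs a MIC grid")

  fit <- NULL
  table <- NULL
  switch(spec$model_id,
    M0 = NULL,
    M1 = {
      fit <- fit_m1(records, grid, d0 = spec$d0)
    },
    M2 = ,
    M3 = {
      fit <- fit_additive_regression(records, spec)
      if (spec$strategy == "factor") {
        table <- acf_from_fit(fit, grid, records,
                              convention = acf_convention)
      }
    },
    M4 = {
      fit <- fit_additive_regression(records, spec)
    },
    M5 = {
      fit <- fit_m5(records, grid, weighted = m5_weighted)
      table <- fit$table
    },
    M6 = {
      fit <- fit_m6(records, grid, d0 = spec$d0)
      table <- fit$table
    },
    M7 = {
      fit <- fit_m7(records, spec, dim_adjust = m7_dim_adjust)
      if (spec$strategy == "factor") {
        table <- mcf_from_ratio_fit(fit, grid)
        if (!m7_dim_adjust) {
          attr(table, "gamma")[] <- 0
        }
      }
    },
    M8 = {
      fit <- fit_m8(records, spec)
      if (spec$strategy == "factor") {
        table <- mcf_m8(fit, grid, records)
      }
    }
  )
  structure(
    list(spec = spec, fit = fit, table = table, grid = grid),
    class = "dmy_model"
  )
}

#' Predict daily milk yield
#'
#' @param object A [fit_dmy_model()] result.
#' @param newdata Records to predict for; only the measured session's
#'   yield, interval and DIM are used.
#' @param ... Unused.
#' @return Numeric vector of estimated daily yields, kg.
#' @export
predict.dmy_model <- function(object, newdata, ...) {
  view <- measured_view(newdata)
  spec <- object$spec
  if (spec$model_id == "M0") {
    return(predict_m0(view$x))
  }
  if (spec$model_id == "M1") {
    return(predict_additive_view(view, object$fit))
  }
  if (spec$model_id %in% c("M2", "M3", "M4")) {
    target <- if (spec$strategy == "factor") object$table else object$fit
    return(predict_additive_view(view, target))
  }
  target <- if (spec$strategy == "factor" &&
                  spec$model_id %in% c("M7", "M8")) {
    object$table
  } else {
    object$fit
  }
  predict_multiplicative_view(view, target)
}

#' @export
print.dmy_model <- function(x, ...) {
  cat("DMY estimator ", model_label(x$spec), "\n", sep = "")
  if (!is.null(x$fit) && !is.null(x$fit$coefficients) &&
        is.data.frame(x$fit$coefficients)) {
    print(x$fit$coefficients)
  }
  invisible(x)
}
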