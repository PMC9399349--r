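## Additive-correction estimators. The common idea: daily yield is
## b * x + Delta, where x is the single measured yield, b is 2 (doubling
## and classical ACF models) or estimated (linear regression), and Delta
## is an additive correction depending on milking interval and DIM.
## The ACF response is z = y - 2x, i.e. the complementary-session yield
## minus the measured one, which makes yhat = Delta + 2x unbiased in
## expectation by construction.

#' Doubling estimator (M0)
#'
#' The original AM-PM plan estimate: twice the single measured yield,
#' exact only under equal 12-12 h milking intervals.
#'
#' @param x Single-session yield, kg (>= 0).
#' @return `2 * x`.
#' @export
predict_m0 <- function(x) {
  assert_that(all(x >= 0), "yields must be >= 0")
  2 * x
}

#' Categorical ACF model (M1)
#'
#' Additive correction factors as expected AM/PM yield differences
#' computed per cell of measured session x milking-interval class x
#' lactation month. With a saturated two-way layout the sum of estimated
#' main and interaction effects equals the cell mean, so cells are
#' estimated directly by their training means. Cells with no training
#' records are imputed from the session-by-MIC marginal mean (and, if
#' that is empty too, the session mean), and marked imputed -- never
#' silently zero.
#'
#' @param records Paired training records (both sessions known).
#' @param grid A [mic_grid()].
#' @param lm_levels Lactation-month levels to tabulate; defaults to the
#'   levels present in the training data.
#' @param d0 Reference DIM carried for interface symmetry (unused by the
#'   cell means).
#' @return Object of class `c("m1_fit", "dmy_fit")` with the cell table
#'   (`cells`: session, mic, lactation_month, delta, n, imputed) and the
#'   marginal fallback tables.
#' @export
fit_m1 <- function(records, grid, lm_levels = NULL, d0 = 158) {
  assert_that(nrow(records) > 0, "no training records")
  long <- stack_sessions(records)
  long$mic <- as.integer(assign_mic(long$t, grid))
  lm_levels <- sort(lm_levels %||% unique(long$lactation_month))

  observed <- dplyr::summarise(
    dplyr::group_by(long, .data$session, .data$mic, .data$lactation_month),
    delta = mean(.data$z), n = dplyr::n(), .groups = "drop"
  )
  marginal_mic <- dplyr::summarise(
    dplyr::group_by(long, .data$session, .data$mic),
    delta_mic = mean(.data$z), .groups = "drop"
  )
  marginal_session <- dplyr::summarise(
    dplyr::group_by(long, .data$session),
    delta_session = mean(.data$z), .groups = "drop"
  )

  full <- tidyr_expand_grid(
    session = SESSIONS, mic = seq_len(n_bins(grid)),
    lactation_month = lm_levels
  )
  cells <- dplyr::left_join(full, observed,
                            by = c("session", "mic", "lactation_month"))
  cells <- dplyr::left_join(cells, marginal_mic, by = c("session", "mic"))
  cells <- dplyr::left_join(cells, marginal_session, by = "session")
  cells$imputed <- is.na(cells$delta)
  cells$delta <- dplyr::coalesce(cells$delta, cells$delta_mic,
                                 cells$delta_session)
  cells$n[is.na(cells$n)] <- 0L
  cells <- cells[c("session", "mic", "lactation_month", "delta", "n",
                   "imputed")]

  structure(
    list(spec = model_spec("M1", d0 = d0), grid = grid, cells = cells,
         marginal_mic = marginal_mic, marginal_session = marginal_session),
    class = c("m1_fit", "dmy_fit")
  )
}

## expand.grid with tibble output and first-factor-slowest ordering kept
## deterministic; avoids importing tidyr for one call.
tidyr_expand_grid <- function(...) {
  g <- expand.grid(..., KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(g[do.call(order, g), , drop = FALSE])
}

#' Regression-based additive fits (M2, M3, M4)
#'
#' * **M2** regresses the ACF response `z = y - 2x` on a session
#'   intercept, milking interval `t` and centred DIM; equivalently an
#'   offset-`2x` regression of daily yield, and the two formulations give
#'   identical coefficients.
#' * **M3** regresses daily yield `y` on session intercepts, `t`,
#'   centred DIM and the measured yield `x` with a free coefficient `b`.
#' * **M4** adds quadratic interval and DIM terms to M3.
#'
#' Joint scope stacks AM-measured and PM-measured rows with
#' session-specific intercepts and common slopes; separate scope fits
#' one model per session. Aliased interval/DIM columns (e.g. a constant
#' interval) are reported with coefficient 0 under the singularity rule;
#' an aliased intercept or yield column is an error.
#'
#' @param records Paired training records.
#' @param spec A [model_spec()] with `model_id` `"M2"`, `"M3"` or
#'   `"M4"`.
#' @return Object of class `c("additive_fit", "dmy_fit")` with
#'   `coefficients` (tibble: session, alpha, beta, gamma, b, quadratic
#'   terms, standard errors) and the underlying `lm` fits.
#' @export
fit_additive_regression <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  assert_that(spec$model_id %in% c("M2", "M3", "M4"),
              "spec must be M2, M3 or M4")
  assert_that(nrow(records) > 0, "no training records")
  long <- stack_sessions(records)
  long$dd <- long$dim - spec$d0

  fit_one <- function(dat, joint) {
    if (spec$model_id == "M2") {
      fm <- if (joint) z ~ 0 + session + t + dd else z ~ t + dd
      fixed_b <- 2
    } else if (spec$model_id == "M3") {
      fm <- if (joint) y ~ 0 + session + t + dd + x else y ~ t + dd + x
      fixed_b <- NULL
    } else {
      fm <- if (joint) {
        y ~ 0 + session + t + I(t^2) + dd + I(dd^2) + x
      } else {
        y ~ t + I(t^2) + dd + I(dd^2) + x
      }
      fixed_b <- NULL
    }
    fit <- lm(fm, data = dat)
    co <- coef(fit)
    aliased <- names(co)[is.na(co)]
    key_terms <- c("(Intercept)", "sessionAM", "sessionPM", "x")
    assert_that(!any(aliased %in% key_terms),
                "singular design: aliased ", paste(aliased, collapse = ", "),
                class = "ampmyield_singular")
    co[is.na(co)] <- 0
    se <- rep(NA_real_, length(co))
    names(se) <- names(co)
    sm <- summary(fit)$coefficients
    se[rownames(sm)] <- sm[, "Std. Error"]
    list(fit = fit, coef = co, se = se, fixed_b = fixed_b,
         aliased = aliased)
  }

  get0n <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0
  getNA <- function(v, nm) if (nm %in% names(v)) v[[nm]] else NA_real_

  if (spec$session_scope == "joint") {
    f <- fit_one(long, joint = TRUE)
    coefs <- dplyr::bind_rows(lapply(SESSIONS, function(s) {
      a_nm <- paste0("session", s)
      tibble::tibble(
        session = s,
        alpha = f$coef[[a_nm]], alpha_se = f$se[[a_nm]],
        beta = get0n(f$coef, "t"), beta_se = getNA(f$se, "t"),
        beta2 = get0n(f$coef, "I(t^2)"), beta2_se = getNA(f$se, "I(t^2)"),
        gamma = get0n(f$coef, "dd"), gamma_se = getNA(f$se, "dd"),
        gamma2 = get0n(f$coef, "I(dd^2)"), gamma2_se = getNA(f$se, "I(dd^2)"),
        b = f$fixed_b %||% f$coef[["x"]],
        b_se = if (is.null(f$fixed_b)) f$se[["x"]] else 0
      )
    }))
    fits <- list(joint = f$fit)
  } else {
    per <- lapply(SESSIONS, function(s) {
      fit_one(long[long$session == s, ], joint = FALSE)
    })
    names(per) <- SESSIONS
    coefs <- dplyr::bind_rows(lapply(SESSIONS, function(s) {
      f <- per[[s]]
      tibble::tibble(
        session = s,
        alpha = f$coef[["(Intercept)"]], alpha_se = f$se[["(Intercept)"]],
        beta = get0n(f$coef, "t"), beta_se = getNA(f$se, "t"),
        beta2 = get0n(f$coef, "I(t^2)"), beta2_se = getNA(f$se, "I(t^2)"),
        gamma = get0n(f$coef, "dd"), gamma_se = getNA(f$se, "dd"),
        gamma2 = get0n(f$coef, "I(dd^2)"), gamma2_se = getNA(f$se, "I(dd^2)"),
        b = f$fixed_b %||% f$coef[["x"]],
        b_se = if (is.null(f$fixed_b)) f$se[["x"]] else 0
      )
    }))
    fits <- lapply(per, `[[`, "fit")
  }

  structure(
    list(spec = spec, coefficients = coefs, fits = fits),
    class = c("additive_fit", "dmy_fit")
  )
}

#' @export
print.additive_fit <- function(x, ...) {
  cat("Additive DMY fit ", model_label(x$spec), " (", x$spec$session_scope,
      ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

session_coefs <- function(fit, session) {
  fit$coefficients[fit$coefficients$session == session, ]
}

#' Additive correction-factor table from a regression fit
#'
#' Evaluates `Delta_j(k) = alpha_j + beta * tbar_j(k)` at the MIC
#' midpoints (the `"interval_only"` convention); the alternative
#' `"with_dim"` convention additionally adds
#' `gamma * (mean training DIM in bin - d0)` and requires `records`.
#' Bins with no training records still receive the smoothed Delta but
#' are marked imputed. The DIM slope `gamma` and `d0` are carried for
#' the residual DIM adjustment at prediction time.
#'
#' @param fit An [fit_additive_regression()] result (M2 or M3).
#' @param grid A [mic_grid()].
#' @param records Optional training records, needed for per-bin counts
#'   and for the `"with_dim"` convention.
#' @param convention `"interval_only"` (default) or `"with_dim"`.
#' @return Tibble of class `"acf_table"`: session, bin_lo, bin_hi,
#'   midpoint, delta_kg, n_train, imputed, with attributes `gamma`, `b`,
#'   `d0`, `convention`.
#' @export
acf_from_fit <- function(fit, grid, records = NULL,
                         convention = c("interval_only", "with_dim")) {
  stopifnot(inherits(fit, "additive_fit"))
  assert_that(fit$spec$model_id %in% c("M2", "M3"),
              "ACF tables are built from M2 or M3 fits")
  convention <- match.arg(convention)
  assert_that(n_bins(grid) > 0, "empty grid")
  assert_that(convention == "interval_only" || !is.null(records),
              "the with_dim convention needs training records")

  bin_stats <- NULL
  if (!is.null(records)) {
    long <- stack_sessions(records)
    long$mic <- as.integer(assign_mic(long$t, grid))
    bin_stats <- dplyr::summarise(
      dplyr::group_by(long, .data$session, .data$mic),
      n_train = dplyr::n(), mean_dim = mean(.data$dim), .groups = "drop"
    )
  }

  rows <- lapply(SESSIONS, function(s) {
    cf <- session_coefs(fit, s)
    tb <- tibble::tibble(
      session = s,
      mic = seq_len(n_bins(grid)),
      bin_lo = grid$edges[-length(grid$edges)],
      bin_hi = grid$edges[-1],
      midpoint = grid$midpoints,
      delta_kg = cf$alpha + cf$beta * grid$midpoints,
      n_train = 0L,
      mean_dim = NA_real_
    )
    if (!is.null(bin_stats)) {
      bs <- bin_stats[bin_stats$session == s, ]
      idx <- match(tb$mic, bs$mic)
      tb$n_train <- ifelse(is.na(idx), 0L, bs$n_train[idx])
      tb$mean_dim <- bs$mean_dim[idx]
    }
    if (convention == "with_dim") {
      adj <- ifelse(is.na(tb$mean_dim), 0, cf$gamma * (tb$mean_dim - fit$spec$d0))
      tb$delta_kg <- tb$delta_kg + adj
    }
    tb$imputed <- tb$n_train == 0L
    tb$mean_dim <- NULL
    tb
  })
  out <- dplyr::bind_rows(rows)
  g <- setNames(fit$coefficients$gamma, fit$coefficients$session)
  b <- setNames(fit$coefficients$b, fit$coefficients$session)
  structure(out, class = c("acf_table", class(out)),
            gamma = g, b = b, d0 = fit$spec$d0, convention = convention,
            model_id = fit$spec$model_id)
}

## Internal: predict DMY with an additive fit or ACF table. `view` is
## the measured_view() of the records.
predict_additive_view <- function(view, object, grid = NULL) {
  if (inherits(object, "m1_fit")) {
    mic <- as.integer(assign_mic(view$t, object$grid))
    key <- paste(view$session, mic, view$lactation_month)
    cells_key <- paste(object$cells$session, object$cells$mic,
                       object$cells$lactation_month)
    idx <- match(key, cells_key)
    delta <- object$cells$delta[idx]
    miss <- is.na(delta)
    if (any(miss)) {
      mk <- paste(view$session, mic)[miss]
      m_idx <- match(mk, paste(object$marginal_mic$session,
                               object$marginal_mic$mic))
      delta[miss] <- object$marginal_mic$delta_mic[m_idx]
      still <- is.na(delta)
      if (any(still)) {
        s_idx <- match(view$session[still], object$marginal_session$session)
        delta[still] <- object$marginal_session$delta_session[s_idx]
      }
    }
    return(delta + 2 * view$x)
  }
  if (inherits(object, "acf_table")) {
    gamma <- attr(object, "gamma")
    b <- attr(object, "b")
    d0 <- attr(object, "d0")
    edges <- sort(unique(c(object$bin_lo, object$bin_hi)))
    grid_obj <- mic_grid(edges[1], edges[length(edges)],
                         edges[2] - edges[1])
    mic_raw <- assign_mic(view$t, grid_obj)
    mic <- as.integer(mic_raw)
    idx <- match(paste(view$session, mic), paste(object$session, object$mic))
    delta <- object$delta_kg[idx]
    est <- as.numeric(delta + unname(gamma[view$session]) * (view$dim - d0) +
                        unname(b[view$session]) * view$x)
    oog <- attr(mic_raw, "out_of_grid")
    if (any(oog)) attr(est, "out_of_grid") <- oog
    return(est)
  }
  stopifnot(inherits(object, "additive_fit"))
  cf <- object$coefficients[match(view$session, object$coefficients$session), ]
  dd <- view$dim - object$spec$d0
  cf$alpha + cf$beta * view$t + cf$beta2 * view$t^2 +
    cf$gamma * dd + cf$gamma2 * dd^2 + cf$b * view$x
}

#' Predict daily milk yield with an additive estimator
#'
#' Direct fits (`additive_fit`) use the record's exact interval and DIM;
#' factor tables (`acf_table`) use the Delta of the record's MIC bin
#' plus the residual DIM adjustment `gamma * (dim - d0)` and `b * x`
#' (`b = 2` for M1/M2 tables, estimated for M3). M1 cell tables fall
#' back to marginal means for unseen cells. Records outside the grid use
#' the clamped terminal bin and are flagged via the `"out_of_grid"`
#' attribute.
#'
#' @param records Records to predict for (only the measured session's
#'   yield and interval are used).
#' @param object An `additive_fit`, `acf_table` or `m1_fit`.
#' @return Numeric vector of estimated daily yields, kg.
#' @export
predict_additive <- function(records, object) {
  predict_additive_view(measured_view(records), object)
}

#' Average ACF gap between free-coefficient and fixed-2.0 models
#'
#' The additive correction of a linear-regression estimator exceeds that
#' of a fixed-coefficient ACF model by `(2 - b_j) * x_j` on average for
#' session `j`. Given the two session mean yields and the two estimated
#' yield coefficients from separate AM/PM fits, returns the average gap
#' over the two sessions,
#' `((2 - b_am) * mean_am + (2 - b_pm) * mean_pm) / 2`.
#'
#' @param mean_am_yield,mean_pm_yield Session mean yields, kg.
#' @param b_am,b_pm Estimated single-yield coefficients per session.
#' @return Average ACF gap in kg.
#' @export
acf_regression_gap <- function(mean_am_yield, mean_pm_yield, b_am, b_pm) {
  ((2 - b_am) * mean_am_yield + (2 - b_pm) * mean_pm_yield) / 2
}
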