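## Multiplicative (ratio) correction-factor estimators. The common idea:
## daily yield is F * x where F is the daily-to-single yield ratio for
## the record's milking-interval class, possibly with a residual DIM
## adjustment. Four traditions are implemented: quadratic smoothing of
## bulk session proportions (M5), per-bin no-intercept regression with
## reciprocal linear smoothing (M6), ratio regression (M7), and
## exponential regression with a lognormal-moment correction (M8).

new_mcf_table <- function(df, model_id, gamma = NULL, d0 = NA_real_) {
  structure(df, class = c("mcf_table", class(df)),
            model_id = model_id, gamma = gamma, d0 = d0)
}

bin_frame <- function(grid, session) {
  tibble::tibble(
    session = session,
    mic = seq_len(n_bins(grid)),
    bin_lo = grid$edges[-length(grid$edges)],
    bin_hi = grid$edges[-1],
    midpoint = grid$midpoints
  )
}

#' Bulk-proportion MCF model with quadratic smoothing (M5)
#'
#' Per session and interval class, the bulk session proportion of daily
#' yield `P_j(k) = sum(x) / sum(y)` over the bin's training records; a
#' quadratic least-squares fit of `P_j(k)` on the bin midpoints then
#' yields smoothed factors `F_j(k) = 1 / (a + b1 * t + b2 * t^2)`. AM
#' and PM factors are computed directly and separately from the session's
#' own data. Unweighted smoothing by default; `weighted = TRUE` weights
#' bins by their record counts.
#'
#' @param records Paired training records.
#' @param grid A [mic_grid()].
#' @param weighted Weight the quadratic fit by per-bin record counts.
#' @return Object of class `c("m5_fit", "dmy_fit")` with per-session
#'   smoothing coefficients and an [`mcf_table`][fit_m5] (`table`).
#' @export
fit_m5 <- function(records, grid, weighted = FALSE) {
  assert_that(nrow(records) > 0, "no training records")
  long <- stack_sessions(records)
  long$mic <- as.integer(assign_mic(long$t, grid))

  per_session <- lapply(SESSIONS, function(s) {
    dat <- long[long$session == s, ]
    props <- dplyr::summarise(
      dplyr::group_by(dat, .data$mic),
      p = sum(.data$x) / sum(.data$y), n = dplyr::n(), .groups = "drop"
    )
    assert_that(nrow(props) >= 3,
                "M5 needs at least 3 populated bins for session ", s)
    props$tbar <- grid$midpoints[props$mic]
    w <- if (weighted) props$n else NULL
    qfit <- lm(p ~ tbar + I(tbar^2), data = props, weights = w)
    co <- coef(qfit)
    co[is.na(co)] <- 0
    den_pop <- co[[1]] + co[[2]] * props$tbar + co[[3]] * props$tbar^2
    assert_that(all(den_pop > 0),
                "M5 smoothed proportion non-positive on a populated bin (",
                s, ")")
    tb <- bin_frame(grid, s)
    den <- co[[1]] + co[[2]] * tb$midpoint + co[[3]] * tb$midpoint^2
    tb$F <- 1 / den
    tb$n_train <- 0L
    tb$n_train[props$mic] <- props$n
    tb$p_raw <- NA_real_
    tb$p_raw[props$mic] <- props$p
    tb$imputed <- tb$n_train == 0L
    list(coef = setNames(as.numeric(co), c("alpha", "beta1", "beta2")),
         table = tb)
  })
  names(per_session) <- SESSIONS
  tab <- dplyr::bind_rows(lapply(per_session, `[[`, "table"))
  assert_that(all(tab$F[!tab$imputed] > 0),
              "non-positive M5 factor on a populated bin")
  structure(
    list(spec = model_spec("M5"), grid = grid,
         coefficients = lapply(per_session, `[[`, "coef"),
         table = new_mcf_table(tab, "M5")),
    class = c("m5_fit", "dmy_fit")
  )
}

#' Per-bin no-intercept regression MCF model (M6)
#'
#' Within each session and interval class, daily yield is regressed on
#' the single yield (and centred DIM) without intercept, giving a
#' per-bin factor `b_jk` and DIM slope `gamma_jk`; the reciprocals
#' `1 / b_jk` are then smoothed linearly on the bin midpoints and the
#' smoothed factors are `F_j(k) = 1 / (a_j + c_j * t)`. Prediction adds
#' the per-bin DIM adjustment `gamma_jk * (dim - d0)`.
#'
#' @param records Paired training records.
#' @param grid A [mic_grid()].
#' @param use_dim Include the per-bin centred-DIM term (default TRUE).
#' @param d0 Reference DIM.
#' @return Object of class `c("m6_fit", "dmy_fit")`; `table` holds the
#'   per-bin raw `b_jk`, `gamma_jk`, smoothed `F`, counts and imputation
#'   flags, `smooth` the per-session reciprocal lines.
#' @export
fit_m6 <- function(records, grid, use_dim = TRUE, d0 = 158) {
  assert_that(nrow(records) > 0, "no training records")
  long <- stack_sessions(records)
  long$mic <- as.integer(assign_mic(long$t, grid))
  long$dd <- long$dim - d0

  per_session <- lapply(SESSIONS, function(s) {
    dat <- long[long$session == s, ]
    bins <- split(dat, dat$mic)
    est <- lapply(bins, function(bd) {
      if (nrow(bd) < 2 || sum(bd$x^2) == 0) return(NULL)
      X <- if (use_dim) cbind(x = bd$x, dd = bd$dd) else cbind(x = bd$x)
      XtX <- crossprod(X)
      if (rcond_safe(XtX) < 1e-12) {
        X <- cbind(x = bd$x)
        XtX <- crossprod(X)
      }
      co <- solve(XtX, crossprod(X, bd$y))
      list(mic = bd$mic[1], b = co["x", 1],
           gamma = if ("dd" %in% rownames(co)) co["dd", 1] else 0,
           n = nrow(bd))
    })
    est <- est[!vapply(est, is.null, logical(1))]
    assert_that(length(est) >= 2,
                "M6 reciprocal smoothing needs >= 2 populated bins (", s, ")")
    raw <- tibble::tibble(
      mic = vapply(est, `[[`, integer(1), "mic"),
      b = vapply(est, `[[`, numeric(1), "b"),
      gamma = vapply(est, `[[`, numeric(1), "gamma"),
      n = vapply(est, `[[`, numeric(1), "n")
    )
    assert_that(all(raw$b > 0), "non-positive per-bin factor in M6 (", s, ")")
    raw$tbar <- grid$midpoints[raw$mic]
    sfit <- lm(I(1 / b) ~ tbar, data = raw)
    co <- coef(sfit)
    co[is.na(co)] <- 0
    tb <- bin_frame(grid, s)
    den <- co[[1]] + co[[2]] * tb$midpoint
    assert_that(all((co[[1]] + co[[2]] * raw$tbar) > 0),
                "M6 smoothed reciprocal non-positive on a populated bin (",
                s, ")")
    tb$F <- 1 / den
    tb$b_raw <- NA_real_
    tb$b_raw[raw$mic] <- raw$b
    tb$gamma <- NA_real_
    tb$gamma[raw$mic] <- raw$gamma
    tb$n_train <- 0L
    tb$n_train[raw$mic] <- raw$n
    tb$imputed <- tb$n_train < 2L
    ## unpopulated bins borrow the nearest populated bin's DIM slope
    pop <- which(!tb$imputed)
    if (length(pop) > 0) {
      nearest <- pop[apply(abs(outer(tb$mic, tb$mic[pop], "-")), 1,
                           which.min)]
      tb$gamma[tb$imputed] <- tb$gamma[nearest[tb$imputed]]
    }
    list(smooth = setNames(as.numeric(co), c("alpha", "beta")), table = tb)
  })
  names(per_session) <- SESSIONS
  tab <- dplyr::bind_rows(lapply(per_session, `[[`, "table"))
  structure(
    list(spec = model_spec("M6", d0 = d0), grid = grid, d0 = d0,
         use_dim = use_dim,
         smooth = lapply(per_session, `[[`, "smooth"),
         table = new_mcf_table(tab, "M6", d0 = d0)),
    class = c("m6_fit", "dmy_fit")
  )
}

rcond_safe <- function(m) {
  tryCatch(rcond(m), error = function(e) 0)
}

#' Ratio-regression model (M7)
#'
#' Ordinary least squares of the single-to-daily yield ratio `x / y` on
#' session intercepts, milking interval and centred DIM. Records with
#' zero daily yield are excluded (counted in `n_excluded`). Prediction
#' is either direct, `yhat = x / (alpha_j + beta * t + gamma * dd)`
#' (M7A), or via per-MIC factors `F_j(k) = 1 / (alpha_j + beta * tbar)`
#' (M7B, see [mcf_from_ratio_fit()]).
#'
#' @param records Paired training records.
#' @param spec A [model_spec()] for `"M7"`.
#' @param dim_adjust For the factor strategy, apply the common
#'   ratio-scale `gamma` as an additive kg-scale DIM adjustment at
#'   prediction time (the literal published construction; dimensionally
#'   questionable, hence switchable).
#' @return Object of class `c("m7_fit", "dmy_fit")`.
#' @export
fit_m7 <- function(records, spec = model_spec("M7"), dim_adjust = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  assert_that(spec$model_id == "M7", "spec must be M7")
  long <- stack_sessions(records)
  excl <- long$y <= 0
  long <- long[!excl, ]
  assert_that(nrow(long) > 0, "no usable training records (all y <= 0)")
  long$r <- long$x / long$y
  long$dd <- long$dim - spec$d0

  if (spec$session_scope == "joint") {
    fit <- lm(r ~ 0 + session + t + dd, data = long)
    co <- coef_zeroed(fit)
    se <- se_of(fit)
    coefs <- dplyr::bind_rows(lapply(SESSIONS, function(s) {
      tibble::tibble(session = s,
                     alpha = co[paste0("session", s)],
                     alpha_se = se(paste0("session", s)),
                     beta = co["t"], beta_se = se("t"),
                     gamma = co["dd"], gamma_se = se("dd"))
    }))
    fits <- list(joint = fit)
  } else {
    per <- lapply(SESSIONS, function(s) {
      lm(r ~ t + dd, data = long[long$session == s, ])
    })
    names(per) <- SESSIONS
    coefs <- dplyr::bind_rows(lapply(SESSIONS, function(s) {
      co <- coef_zeroed(per[[s]])
      se <- se_of(per[[s]])
      tibble::tibble(session = s,
                     alpha = co["(Intercept)"], alpha_se = se("(Intercept)"),
                     beta = co["t"], beta_se = se("t"),
                     gamma = co["dd"], gamma_se = se("dd"))
    }))
    fits <- per
  }
  coefs$alpha <- unname(coefs$alpha)
  coefs$beta <- unname(coefs$beta)
  coefs$gamma <- unname(coefs$gamma)
  structure(
    list(spec = spec, coefficients = coefs, fits = fits,
         n_excluded = sum(excl), dim_adjust = dim_adjust),
    class = c("m7_fit", "dmy_fit")
  )
}

#' MCF table from a ratio-regression fit
#'
#' `F_j(k) = 1 / (alpha_j + beta * tbar_j(k))`, the reciprocal of the
#' fitted ratio line at the bin midpoints (the local-expectation /
#' first-order Taylor construction `E(x/y) ~ E(x)/E(y)`). A non-positive
#' denominator at any midpoint is an error naming the offending bin.
#'
#' @param fit An [fit_m7()] result.
#' @param grid A [mic_grid()].
#' @return An `mcf_table` tibble: session, bin, midpoint, `F`, with the
#'   ratio-scale `gamma` and `d0` carried as attributes.
#' @export
mcf_from_ratio_fit <- function(fit, grid) {
  stopifnot(inherits(fit, "m7_fit"))
  tabs <- lapply(SESSIONS, function(s) {
    cf <- session_coefs(fit, s)
    tb <- bin_frame(grid, s)
    den <- cf$alpha + cf$beta * tb$midpoint
    bad <- which(den <= 0)
    assert_that(length(bad) == 0,
                "non-positive ratio denominator at ", s, " bin ",
                paste(bad, collapse = ", "))
    tb$F <- 1 / den
    tb$imputed <- FALSE
    tb
  })
  g <- setNames(fit$coefficients$gamma, fit$coefficients$session)
  new_mcf_table(dplyr::bind_rows(tabs), "M7", gamma = g, d0 = fit$spec$d0)
}

#' Exponential regression model (M8)
#'
#' Daily yield as `x^b * exp(alpha_j + beta * t + gamma * dd)` with
#' multiplicative lognormal error; fitted by ordinary least squares on
#' the natural-log scale: `log y ~ session + t + dd + log x`. Records
#' with non-positive `x` or `y` are excluded (counted; a warning is
#' raised if more than 1% are dropped).
#'
#' @param records Paired training records.
#' @param spec A [model_spec()] for `"M8"`.
#' @return Object of class `c("m8_fit", "dmy_fit")` with coefficients
#'   `(alpha_j, beta, gamma, b)`, their standard errors and the residual
#'   variance of the log model.
#' @export
fit_m8 <- function(records, spec = model_spec("M8")) {
  stopifnot(inherits(spec, "model_spec"))
  assert_that(spec$model_id == "M8", "spec must be M8")
  long <- stack_sessions(records)
  excl <- long$x <= 0 | long$y <= 0
  if (sum(excl) > 0.01 * nrow(long)) {
    warning(sum(excl), " records with non-positive yields excluded (> 1%)")
  }
  long <- long[!excl, ]
  assert_that(nrow(long) > 0, "no usable training records (non-positive yields)")
  long$ly <- log(long$y)
  long$lx <- log(long$x)
  long$dd <- long$dim - spec$d0

  extract <- function(fit, joint, s = NULL) {
    co <- coef_zeroed(fit)
    se <- se_of(fit)
    a_nm <- if (joint) paste0("session", s) else "(Intercept)"
    tibble::tibble(
      session = s %||% NA_character_,
      alpha = unname(co[a_nm]), alpha_se = se(a_nm),
      beta = unname(co["t"]), beta_se = se("t"),
      gamma = unname(co["dd"]), gamma_se = se("dd"),
      b = unname(co["lx"]), b_se = se("lx")
    )
  }
  if (spec$session_scope == "joint") {
    fit <- lm(ly ~ 0 + session + t + dd + lx, data = long)
    coefs <- dplyr::bind_rows(lapply(SESSIONS, function(s) {
      extract(fit, TRUE, s)
    }))
    sigma2 <- summary(fit)$sigma^2
    fits <- list(joint = fit)
  } else {
    per <- lapply(SESSIONS, function(s) {
      lm(ly ~ t + dd + lx, data = long[long$session == s, ])
    })
    names(per) <- SESSIONS
    coefs <- dplyr::bind_rows(lapply(SESSIONS, function(s) {
      out <- extract(per[[s]], FALSE)
      out$session <- s
      out
    }))
    sigma2 <- mean(vapply(per, function(f) summary(f)$sigma^2, numeric(1)))
    fits <- per
  }
  structure(
    list(spec = spec, coefficients = coefs, fits = fits,
         sigma2_log = sigma2, n_excluded = sum(excl)),
    class = c("m8_fit", "dmy_fit")
  )
}

#' @export
print.m8_fit <- function(x, ...) {
  cat("Exponential DMY fit M8 (", x$spec$session_scope, ")\n", sep = "")
  print(x$coefficients)
  cat("log-scale residual variance:", signif(x$sigma2_log, 4), "\n")
  invisible(x)
}

#' MCF table from an exponential-regression fit
#'
#' Per populated interval class, the lognormal-moment correction
#' `rho_j(k) = exp((V(y)/E(y)^2 - b * V(x)/E(x)^2) / 2)` is computed
#' from the bin's training means and variances of single and daily
#' yields, and the factor is
#' `F_j(k) = E(x)^(b-1) * rho_j(k) * exp(alpha_j + beta * tbar_j(k))`.
#' Bins with fewer than two training records (variance undefined) are
#' treated as unpopulated; they borrow the nearest populated bin's
#' moments and are flagged imputed.
#'
#' @param fit An [fit_m8()] result.
#' @param grid A [mic_grid()].
#' @param records Training records supplying the per-bin moments.
#' @return An `mcf_table` tibble with columns session, bin, midpoint,
#'   `F`, `rho`, `Ex`, `Vx`, `Ey`, `Vy`, `n_train`, `imputed`.
#' @export
mcf_m8 <- function(fit, grid, records) {
  stopifnot(inherits(fit, "m8_fit"))
  long <- stack_sessions(records)
  long <- long[long$x > 0 & long$y > 0, ]
  long$mic <- as.integer(assign_mic(long$t, grid))

  tabs <- lapply(SESSIONS, function(s) {
    cf <- session_coefs(fit, s)
    dat <- long[long$session == s, ]
    stats <- dplyr::summarise(
      dplyr::group_by(dat, .data$mic),
      Ex = mean(.data$x), Vx = var(.data$x),
      Ey = mean(.data$y), Vy = var(.data$y),
      n = dplyr::n(), .groups = "drop"
    )
    stats <- stats[stats$n >= 2, ]
    assert_that(nrow(stats) > 0, "no bin with >= 2 records for session ", s)
    tb <- bin_frame(grid, s)
    idx <- match(tb$mic, stats$mic)
    tb$imputed <- is.na(idx)
    ## nearest populated bin donates moments for empty/singleton bins
    pop_mics <- stats$mic
    nearest <- vapply(tb$mic, function(k) {
      pop_mics[which.min(abs(pop_mics - k))]
    }, numeric(1))
    use <- ifelse(is.na(idx), match(nearest, stats$mic), idx)
    tb$Ex <- stats$Ex[use]
    tb$Vx <- stats$Vx[use]
    tb$Ey <- stats$Ey[use]
    tb$Vy <- stats$Vy[use]
    tb$n_train <- ifelse(tb$imputed, 0L, as.integer(stats$n[use]))
    tb$rho <- exp(0.5 * (tb$Vy / tb$Ey^2 - cf$b * tb$Vx / tb$Ex^2))
    tb$F <- tb$Ex^(cf$b - 1) * tb$rho * exp(cf$alpha + cf$beta * tb$midpoint)
    tb
  })
  g <- setNames(fit$coefficients$gamma, fit$coefficients$session)
  new_mcf_table(dplyr::bind_rows(tabs), "M8", gamma = g, d0 = fit$spec$d0)
}

## Internal: predict DMY with a multiplicative fit or table for a
## measured_view().
predict_multiplicative_view <- function(view, object) {
  if (inherits(object, "m5_fit")) {
    return(predict_mcf_table_view(view, object$table, dim_term = "none"))
  }
  if (inherits(object, "m6_fit")) {
    return(predict_mcf_table_view(view, object$table,
                                  dim_term = if (object$use_dim) {
                                    "per_bin_additive"
                                  } else "none",
                                  d0 = object$d0))
  }
  if (inherits(object, "m7_fit")) {
    cf <- object$coefficients[match(view$session,
                                    object$coefficients$session), ]
    den <- cf$alpha + cf$beta * view$t + cf$gamma * (view$dim - object$spec$d0)
    bad <- which(den <= 0)
    assert_that(length(bad) == 0,
                "non-positive ratio denominator for record(s) ",
                paste(view$row_id[head(bad, 5)], collapse = ", "))
    return(view$x / den)
  }
  if (inherits(object, "m8_fit")) {
    cf <- object$coefficients[match(view$session,
                                    object$coefficients$session), ]
    dd <- view$dim - object$spec$d0
    return(view$x^cf$b * exp(cf$alpha + cf$beta * view$t + cf$gamma * dd))
  }
  if (inherits(object, "mcf_table")) {
    model_id <- attr(object, "model_id")
    dim_term <- switch(model_id,
      M5 = "none",
      M6 = "per_bin_additive",
      M7 = "common_additive",
      M8 = "exponential",
      "none")
    return(predict_mcf_table_view(view, object, dim_term = dim_term,
                                  d0 = attr(object, "d0")))
  }
  stop_dmy("unsupported multiplicative object of class ",
           paste(class(object), collapse = "/"))
}

predict_mcf_table_view <- function(view, table, dim_term, d0 = NA_real_) {
  edges <- sort(unique(c(table$bin_lo, table$bin_hi)))
  grid_obj <- mic_grid(edges[1], edges[length(edges)], edges[2] - edges[1])
  mic <- as.integer(assign_mic(view$t, grid_obj))
  idx <- match(paste(view$session, mic), paste(table$session, table$mic))
  f <- table$F[idx]
  est <- f * view$x
  gamma_attr <- attr(table, "gamma")
  if (dim_term == "per_bin_additive" && "gamma" %in% names(table)) {
    g <- table$gamma[idx]
    g[is.na(g)] <- 0
    est <- est + g * (view$dim - d0)
  } else if (dim_term == "common_additive" && !is.null(gamma_attr)) {
    est <- est + unname(gamma_attr[view$session]) * (view$dim - d0)
  } else if (dim_term == "exponential" && !is.null(gamma_attr)) {
    est <- est * exp(unname(gamma_attr[view$session]) * (view$dim - d0))
  }
  as.numeric(est)
}

#' Predict daily milk yield with a multiplicative estimator
#'
#' Dispatches on the object: `m5_fit`/`m6_fit` use their smoothed factor
#' tables (M6 adding the per-bin DIM adjustment), `m7_fit` predicts
#' directly as `x / (alpha_j + beta t + gamma dd)` (error if the
#' denominator is non-positive, naming the record), `m8_fit` predicts
#' `x^b exp(alpha_j + beta t + gamma dd)`, and an `mcf_table` applies
#' `F * x` with the table's own DIM convention (none for M5, per-bin
#' additive for M6, common additive for M7, exponential for M8).
#'
#' @param records Records to predict for.
#' @param object A multiplicative fit or `mcf_table`.
#' @return Numeric vector of estimated daily yields, kg.
#' @export
predict_multiplicative <- function(records, object) {
  predict_multiplicative_view(measured_view(records), object)
}
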