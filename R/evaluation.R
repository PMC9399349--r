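## Replicated k-fold cross-validation of the estimator suite, with the
## MSE decomposed across replicates into the variance of the estimates
## and the squared bias of the replicate-mean estimate, R-squared
## accuracy, correlations, and paired significance tests.

#' Cross-validation plan
#'
#' @param k Number of folds (>= 2), default 10.
#' @param replicates Number of independent replications of the whole
#'   k-fold rotation, each with a fresh random partition, default 30.
#' @param unit Partition unit: `"record"` (default) or `"cow"` (keeps
#'   all records of a cow in one fold, preventing same-cow leakage).
#' @param seed Integer seed driving all fold randomness.
#' @return A list of class `"cv_plan"`.
#' @export
cv_plan <- function(k = 10, replicates = 30, unit = c("record", "cow"),
                    seed = 1L) {
  assert_that(is_count(k) && k >= 2, "k must be an integer >= 2")
  assert_that(is_count(replicates), "replicates must be a positive integer")
  unit <- match.arg(unit)
  structure(list(k = k, replicates = replicates, unit = unit,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Random fold assignment
#'
#' Folds are as equal as possible (sizes differ by at most one) and each
#' unit appears in exactly one test fold. Deterministic for a given
#' seed; different replicates use seeds derived from the plan seed.
#'
#' @param n Number of units.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels 1..k, length `n`.
#' @export
make_folds <- function(n, k, seed) {
  assert_that(k <= n, "k must not exceed the number of units")
  withr::with_seed(as.integer(seed), {
    sample(rep(seq_len(k), length.out = n))
  })
}

#' Decompose replicated cross-validation errors
#'
#' For an `n x m` matrix of estimates (records by replicates) and the
#' true values, computes
#' `Var  = mean over i,r of (est[i,r] - rowmean[i])^2`,
#' `Bias2 = mean over i of (rowmean[i] - y[i])^2`, and the MSE both as
#' `Var + Bias2` and directly as `mean((est - y)^2)`; the identity is
#' asserted to 1e-8 relative tolerance.
#'
#' @param estimates Numeric matrix, one row per record, one column per
#'   replicate (no missing entries).
#' @param actual True daily yields, length `nrow(estimates)`.
#' @return Named list `Var`, `Bias2`, `MSE`.
#' @export
decompose_mse <- function(estimates, actual) {
  estimates <- as.matrix(estimates)
  assert_that(nrow(estimates) == length(actual),
              "estimates and actual lengths differ")
  assert_that(ncol(estimates) >= 1, "need at least one replicate")
  assert_that(!anyNA(estimates), "missing estimates for some record/replicate")
  row_mean <- rowMeans(estimates)
  v <- mean((estimates - row_mean)^2)
  b2 <- mean((row_mean - actual)^2)
  mse_direct <- mean((estimates - actual)^2)
  rel <- abs(v + b2 - mse_direct) / max(mse_direct, .Machine$double.eps)
  assert_that(rel < 1e-8, "MSE decomposition identity violated")
  list(Var = v, Bias2 = b2, MSE = mse_direct)
}

#' R-squared accuracy
#'
#' `R2 = sigma2 / (sigma2 + MSE)`: the share of the true phenotypic
#' variance in the error-inflated total. Unlike a squared correlation it
#' penalizes bias.
#'
#' @param mse Mean squared error(s), >= 0 (vectorised).
#' @param sigma2 Reference phenotypic variance of daily yield, > 0.
#' @return R-squared accuracy in (0, 1].
#' @export
r2_accuracy <- function(mse, sigma2) {
  assert_that(is.numeric(sigma2) && length(sigma2) == 1 && sigma2 > 0,
              "sigma2 must be a positive scalar")
  assert_that(all(mse >= 0), "mse must be >= 0")
  sigma2 / (sigma2 + mse)
}

#' Per-animal accuracy distribution
#'
#' Per-record R-squared accuracies from replicate-averaged MSEs, with
#' distribution summaries including the fraction at or above 0.90.
#'
#' @param mse_i Per-record MSEs averaged across replicates.
#' @param sigma2 Reference variance, > 0.
#' @return List with `r2` (per-record vector) and `summary` (tibble:
#'   mean, median, sd, fraction_ge_0.90).
#' @export
individual_accuracy <- function(mse_i, sigma2) {
  r2 <- r2_accuracy(mse_i, sigma2)
  list(
    r2 = r2,
    summary = tibble::tibble(
      mean = mean(r2), median = median(r2), sd = sd(r2),
      fraction_ge_0.90 = mean(r2 >= 0.90)
    )
  )
}

#' Replicated k-fold cross-validation of DMY estimators
#'
#' For each replicate, the records (or cows) are partitioned into `k`
#' folds; each fold in turn is held out, every requested model is fitted
#' on the remaining folds only -- including its MIC bin statistics and
#' factor tables, so nothing leaks from the test fold -- and the held-out
#' records' daily yields are estimated from their single measured
#' milking. Each record is therefore estimated exactly once per
#' replicate; per-replicate metrics pool the k test folds.
#'
#' @param records Validated paired records.
#' @param models Character labels or [model_spec()]s (e.g.
#'   `c("M0", "M2B", "M8A")`).
#' @param plan A [cv_plan()].
#' @param grid A [mic_grid()] for factor strategies.
#' @param sigma2 Reference variance for [r2_accuracy()]: `"full"`
#'   (default; sample variance of actual daily yield over the full
#'   dataset) or a positive number.
#' @param ... Passed to [fit_dmy_model()].
#' @return Object of class `"cv_report"`: `per_replicate` (model,
#'   replicate, MSE, R2, correlation), `decomposition` (model, Var,
#'   Bias2, MSE), `per_record` (model, record, replicate-mean estimate,
#'   MSE_i, R2_i), `estimates` (n x models x replicates array),
#'   `sigma2`, `plan`, `failures`.
#' @export
run_crossval <- function(records, models, plan = cv_plan(), grid = NULL,
                         sigma2 = "full", ...) {
  n <- nrow(records)
  assert_that(n >= plan$k, "fewer records than folds")
  labels <- vapply(models, function(m) model_label(as_model_spec(m)),
                   character(1))
  specs <- lapply(models, as_model_spec)
  names(specs) <- labels
  y <- records$am_yield_kg + records$pm_yield_kg

  sigma2_val <- if (identical(sigma2, "full")) var(y) else sigma2
  assert_that(is.numeric(sigma2_val) && sigma2_val > 0,
              "sigma2 must be positive")

  units <- if (plan$unit == "cow") {
    match(records$cow_id, unique(records$cow_id))
  } else {
    seq_len(n)
  }
  n_units <- max(units)
  assert_that(n_units >= plan$k, "fewer units than folds")

  est <- array(NA_real_,
               dim = c(n, length(labels), plan$replicates),
               dimnames = list(NULL, labels, NULL))
  failures <- list()

  for (r in seq_len(plan$replicates)) {
    unit_fold <- make_folds(n_units, plan$k, derive_seed(plan$seed, r))
    fold <- unit_fold[units]
    for (f in seq_len(plan$k)) {
      test_idx <- which(fold == f)
      if (length(test_idx) == 0) next
      train <- records[fold != f, ]
      test <- records[test_idx, ]
      for (lab in labels) {
        res <- tryCatch(
          {
            m <- fit_dmy_model(train, specs[[lab]], grid = grid, ...)
            predict(m, test)
          },
          error = function(e) e
        )
        if (inherits(res, "error")) {
          failures[[length(failures) + 1]] <- list(
            model = lab, replicate = r, fold = f,
            message = conditionMessage(res)
          )
        } else {
          est[test_idx, lab, r] <- res
        }
      }
    }
  }

  per_replicate <- dplyr::bind_rows(lapply(labels, function(lab) {
    dplyr::bind_rows(lapply(seq_len(plan$replicates), function(r) {
      e <- est[, lab, r]
      ok <- !is.na(e)
      if (!any(ok)) {
        return(tibble::tibble(model = lab, replicate = r, MSE = NA_real_,
                              R2 = NA_real_, correlation = NA_real_,
                              n = 0L, complete = FALSE))
      }
      mse <- mean((e[ok] - y[ok])^2)
      tibble::tibble(
        model = lab, replicate = r, MSE = mse,
        R2 = r2_accuracy(mse, sigma2_val),
        correlation = stats::cor(e[ok], y[ok]),
        n = sum(ok), complete = all(ok)
      )
    }))
  }))

  decomposition <- dplyr::bind_rows(lapply(labels, function(lab) {
    e <- est[, lab, , drop = FALSE]
    dim(e) <- c(n, plan$replicates)
    ok <- stats::complete.cases(e)
    if (!any(ok)) {
      return(tibble::tibble(model = lab, Var = NA_real_, Bias2 = NA_real_,
                            MSE = NA_real_, n = 0L))
    }
    d <- decompose_mse(e[ok, , drop = FALSE], y[ok])
    tibble::tibble(model = lab, Var = d$Var, Bias2 = d$Bias2, MSE = d$MSE,
                   n = sum(ok))
  }))

  per_record <- dplyr::bind_rows(lapply(labels, function(lab) {
    e <- est[, lab, , drop = FALSE]
    dim(e) <- c(n, plan$replicates)
    mse_i <- rowMeans((e - y)^2)
    tibble::tibble(
      model = lab, record = seq_len(n),
      estimate_mean = rowMeans(e),
      MSE_i = mse_i,
      R2_i = ifelse(is.na(mse_i), NA_real_,
                    sigma2_val / (sigma2_val + mse_i))
    )
  }))

  structure(
    list(per_replicate = per_replicate, decomposition = decomposition,
         per_record = per_record, estimates = est, actual = y,
         sigma2 = sigma2_val, plan = plan, models = labels,
         failures = failures),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report: ", x$plan$k, "-fold x ", x$plan$replicates,
      " replicates, ", length(x$actual), " records, sigma2 = ",
      signif(x$sigma2, 4), "\n", sep = "")
  print(format_cv_table(x))
  if (length(x$failures) > 0) {
    cat(length(x$failures), "model-fit failures recorded\n")
  }
  invisible(x)
}

#' Render a cross-validation report as a summary table
#'
#' One row per model: decomposed Var, squared bias and MSE, and the mean
#' (standard error in parentheses is the across-replicate standard
#' deviation) of the R-squared accuracy and correlation.
#'
#' @param report A [run_crossval()] result.
#' @return A tibble with columns model, Var, Bias2, MSE, Acc, Acc_se,
#'   Cor, Cor_se.
#' @export
format_cv_table <- function(report) {
  agg <- dplyr::summarise(
    dplyr::group_by(report$per_replicate, .data$model),
    Acc = mean(.data$R2, na.rm = TRUE),
    Acc_se = sd(.data$R2, na.rm = TRUE),
    Cor = mean(.data$correlation, na.rm = TRUE),
    Cor_se = sd(.data$correlation, na.rm = TRUE),
    .groups = "drop"
  )
  out <- dplyr::left_join(report$decomposition, agg, by = "model")
  out[match(report$models, out$model), ]
}

#' Paired comparison of two models in a cross-validation report
#'
#' Replicate level: paired t-test on the per-replicate R-squared
#' accuracies. Individual level: paired t-test on per-record R-squared
#' accuracies. Zero-variance differences are reported as degenerate
#' rather than raising an error.
#'
#' @param report A [run_crossval()] result.
#' @param model_a,model_b Model labels present in the report.
#' @param level `"replicate"` or `"individual"`.
#' @return Tibble with mean_diff, t, df, p, degenerate.
#' @export
compare_models <- function(report, model_a, model_b,
                           level = c("replicate", "individual")) {
  level <- match.arg(level)
  assert_that(all(c(model_a, model_b) %in% report$models),
              "both models must be present in the report")
  if (level == "replicate") {
    pr <- report$per_replicate
    a <- pr$R2[pr$model == model_a]
    b <- pr$R2[pr$model == model_b]
  } else {
    pr <- report$per_record
    a <- pr$R2_i[pr$model == model_a]
    b <- pr$R2_i[pr$model == model_b]
  }
  d <- a - b
  d <- d[!is.na(d)]
  assert_that(length(d) >= 2, "need at least two paired values")
  if (sd(d) == 0) {
    return(tibble::tibble(
      model_a = model_a, model_b = model_b, level = level,
      mean_diff = mean(d), t = NA_real_, df = length(d) - 1,
      p = NA_real_, degenerate = TRUE
    ))
  }
  tt <- t.test(d)
  tibble::tibble(
    model_a = model_a, model_b = model_b, level = level,
    mean_diff = mean(d), t = unname(tt$statistic),
    df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE
  )
}
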