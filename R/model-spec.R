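## Model specifications: which estimator, which prediction strategy
## ("direct" from fitted coefficients at the record's exact covariates
## vs "factor" via a per-MIC correction-factor table), and whether AM
## and PM milkings are fitted jointly (session-specific intercepts,
## common slopes) or separately.

MODEL_IDS <- paste0("M", 0:8)
FACTOR_ONLY <- c("M0", "M1", "M5", "M6")
DIRECT_ONLY <- "M4"

#' Specify a daily-milk-yield estimator
#'
#' @param model_id One of `"M0"` (doubling) ... `"M8"` (exponential
#'   regression). `M0`, `M1`, `M5`, `M6` admit only the factor strategy;
#'   `M4` only the direct strategy.
#' @param strategy `"direct"` (predict from fitted coefficients at the
#'   record's exact interval and DIM -- the "A" variants) or `"factor"`
#'   (via a per-MIC correction-factor table built at bin midpoints --
#'   the "B" variants). Defaults to the only admissible strategy where
#'   there is one, else `"direct"`.
#' @param session_scope `"joint"` (stacked AM/PM rows, session-specific
#'   intercepts, common slopes) or `"separate"` (one fit per session).
#' @param d0 Reference days-in-milk used to centre DIM (default 158).
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(model_id,
                       strategy = NULL,
                       session_scope = c("joint", "separate"),
                       d0 = 158) {
  assert_that(model_id %in% MODEL_IDS,
              "unknown model_id: ", model_id)
  if (is.null(strategy)) {
    strategy <- if (model_id %in% FACTOR_ONLY) "factor" else "direct"
  }
  strategy <- match.arg(strategy, c("direct", "factor"))
  session_scope <- match.arg(session_scope)
  assert_that(!(model_id %in% FACTOR_ONLY) || strategy == "factor",
              model_id, " admits only the factor strategy")
  assert_that(!(model_id %in% DIRECT_ONLY) || strategy == "direct",
              model_id, " admits only the direct strategy")
  assert_that(is.numeric(d0) && d0 > 0, "d0 must be positive")
  structure(list(model_id = model_id, strategy = strategy,
                 session_scope = session_scope, d0 = d0),
            class = "model_spec")
}

#' Model specification from a short label
#'
#' Accepts the conventional labels: `"M0"`, `"M1"`, `"M2A"`, `"M2B"`,
#' `"M3A"`, `"M3B"`, `"M4"`, `"M5"`, `"M6"`, `"M7A"`, `"M7B"`, `"M8A"`,
#' `"M8B"`, where the `A`/`B` suffix selects the direct/factor strategy.
#'
#' @param label Character label.
#' @inheritParams model_spec
#' @return A [model_spec()].
#' @export
as_model_spec <- function(label, session_scope = "joint", d0 = 158) {
  if (inherits(label, "model_spec")) return(label)
  m <- regmatches(label, regexec("^(M[0-8])([AB]?)$", label))[[1]]
  assert_that(length(m) == 3, "unrecognized model label: ", label)
  strategy <- switch(m[3], A = "direct", B = "factor", NULL)
  model_spec(m[2], strategy = strategy, session_scope = session_scope, d0 = d0)
}

#' Conventional label of a model specification
#' @param spec A [model_spec()].
#' @return Character label, e.g. `"M3B"`.
#' @export
model_label <- function(spec) {
  suffix <- if (spec$model_id %in% c(FACTOR_ONLY, DIRECT_ONLY)) {
    ""
  } else if (spec$strategy == "direct") "A" else "B"
  paste0(spec$model_id, suffix)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("DMY model spec ", model_label(x), ": ", x$strategy, " strategy, ",
      x$session_scope, " AM/PM fit, d0 = ", x$d0, " d\n", sep = "")
  invisible(x)
}
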