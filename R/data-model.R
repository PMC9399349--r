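## Domain types and plumbing for paired AM/PM test-day milking records:
## file exchange format, record validation, session stacking, and
## milking-interval-class (MIC) discretization.

#' Read a milking-record file
#'
#' Reads the package's delimited exchange format for paired test-day
#' milking records: comma-separated, header row, columns exactly
#' `cow_id, herd_id, breed, parity, lactation_month, dim, am_interval_h,
#' pm_interval_h, am_yield_kg, pm_yield_kg, measured_session`. Missing
#' values are empty fields. Units are hours for intervals, kg for yields,
#' days for days in milk (DIM); no unit inference is performed.
#'
#' @param path Path to a delimited text file.
#' @return A tibble with the eleven record columns. No validation is
#'   applied; see [validate_records()].
#' @seealso [write_milking_records()], [validate_records()]
#' @export
read_milking_records <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      cow_id = readr::col_character(),
      herd_id = readr::col_character(),
      breed = readr::col_character(),
      parity = readr::col_double(),
      lactation_month = readr::col_double(),
      dim = readr::col_double(),
      am_interval_h = readr::col_double(),
      pm_interval_h = readr::col_double(),
      am_yield_kg = readr::col_double(),
      pm_yield_kg = readr::col_double(),
      measured_session = readr::col_character()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(RECORD_COLUMNS, names(df))
  assert_that(length(missing_cols) == 0,
              "missing required columns: ", paste(missing_cols, collapse = ", "))
  df[RECORD_COLUMNS]
}

#' Write a milking-record file
#'
#' @param records A table of paired test-day records (the eleven exchange
#'   columns, see [read_milking_records()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_milking_records <- function(records, path) {
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  assert_that(length(missing_cols) == 0,
              "missing required columns: ", paste(missing_cols, collapse = ", "))
  readr::write_csv(records[RECORD_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Validate paired test-day milking records
#'
#' Applies the record invariants and returns the records that satisfy all
#' of them together with a per-rule drop report. Rules, applied in order
#' and reported exclusively (a record counts under the first rule it
#' violates): missing field; non-finite numeric field; interval out of
#' range (intervals must lie strictly inside 0-24 h); negative yield;
#' DIM below 1; parity below 1; lactation month outside 1-11; unknown
#' measured session (must be `"AM"` or `"PM"`). Records are never
#' silently coerced.
#'
#' @param records A raw record table as returned by
#'   [read_milking_records()].
#' @return An object of class `"milking_validation"`: a list with
#'   `records` (the kept tibble), `report` (tibble of rule, n_dropped),
#'   `n_in`, `n_kept`.
#' @export
validate_records <- function(records) {
  assert_that(is.data.frame(records), "records must be a data frame")
  assert_that(nrow(records) > 0, "empty input: no records to validate",
              class = "ampmyield_empty_data")
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  assert_that(length(missing_cols) == 0,
              "missing required columns: ", paste(missing_cols, collapse = ", "))
  records <- tibble::as_tibble(records)[RECORD_COLUMNS]

  num_cols <- c("parity", "lactation_month", "dim", "am_interval_h",
                "pm_interval_h", "am_yield_kg", "pm_yield_kg")
  chr_cols <- c("cow_id", "herd_id", "breed", "measured_session")

  reason <- rep(NA_character_, nrow(records))
  flag <- function(cond, label) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- label
  }

  any_missing <- Reduce(`|`, lapply(records[num_cols], is.na)) |
    Reduce(`|`, lapply(records[chr_cols], function(x) is.na(x) | x == ""))
  flag(any_missing, "missing field")
  flag(!Reduce(`&`, lapply(records[num_cols], is.finite)), "non-finite field")
  flag(records$am_interval_h <= 0 | records$am_interval_h >= 24 |
         records$pm_interval_h <= 0 | records$pm_interval_h >= 24,
       "interval out of range")
  flag(records$am_yield_kg < 0 | records$pm_yield_kg < 0, "negative yield")
  flag(records$dim < 1, "dim out of range")
  flag(records$parity < 1, "parity out of range")
  flag(records$lactation_month < 1 | records$lactation_month > 11,
       "lactation month out of range")
  flag(!(records$measured_session %in% SESSIONS), "unknown measured session")

  kept <- records[is.na(reason), ]
  dropped <- table(factor(reason[!is.na(reason)]))
  report <- tibble::tibble(
    rule = names(dropped),
    n_dropped = as.integer(dropped)
  )
  structure(
    list(records = kept, report = report,
         n_in = nrow(records), n_kept = nrow(kept)),
    class = "milking_validation"
  )
}

#' @export
print.milking_validation <- function(x, ...) {
  cat("Milking record validation: ", x$n_kept, "/", x$n_in, " records kept\n",
      sep = "")
  if (nrow(x$report) > 0) {
    for (i in seq_len(nrow(x$report))) {
      cat("  dropped ", x$report$n_dropped[i], ": ", x$report$rule[i], "\n",
          sep = "")
    }
  }
  invisible(x)
}

#' Build a milking-interval-class grid
#'
#' Contiguous half-open bins `[e_k, e_{k+1})` over the milking-interval
#' axis, with midpoints used as the evaluation points of smoothed factor
#' tables. The default convention elsewhere in the package is 1-h bins
#' spanning 6-20 h.
#'
#' @param min_h,max_h Grid span in hours; `max_h - min_h` must be an
#'   integer multiple of `width_h` (to tolerance 1e-8).
#' @param width_h Bin width in hours, positive.
#' @param session Optional session label (`"AM"`/`"PM"`) carried as
#'   metadata; the same grid geometry is typically used for both sessions.
#' @return An object of class `"mic_grid"` with elements `edges`,
#'   `midpoints`, `width_h`, `session`.
#' @export
mic_grid <- function(min_h, max_h, width_h = 1, session = NA_character_) {
  assert_that(is.numeric(width_h) && width_h > 0, "bin width must be positive")
  assert_that(min_h < max_h, "min_h must be below max_h")
  n_bins <- (max_h - min_h) / width_h
  assert_that(abs(n_bins - round(n_bins)) < 1e-8,
              "(max_h - min_h) must be a multiple of width_h")
  n_bins <- as.integer(round(n_bins))
  edges <- min_h + width_h * (0:n_bins)
  structure(
    list(
      edges = edges,
      midpoints = (edges[-1] + edges[-length(edges)]) / 2,
      width_h = width_h,
      session = session
    ),
    class = "mic_grid"
  )
}

#' @export
print.mic_grid <- function(x, ...) {
  cat("MIC grid: ", length(x$midpoints), " bins of ", x$width_h, " h over [",
      x$edges[1], ", ", x$edges[length(x$edges)], ") h\n", sep = "")
  invisible(x)
}

n_bins <- function(grid) length(grid$midpoints)

#' Assign milking intervals to interval classes
#'
#' Half-open membership: interval `t` belongs to bin `k` iff
#' `edges[k] <= t < edges[k + 1]`. Intervals below the grid minimum or at
#' or above the maximum are clamped to the nearest terminal bin and
#' flagged, never dropped.
#'
#' @param interval_h Numeric vector of intervals in hours.
#' @param grid A [mic_grid()].
#' @return Integer vector of 1-based bin indices with attribute
#'   `"out_of_grid"`, a logical vector marking clamped entries.
#' @export
assign_mic <- function(interval_h, grid) {
  stopifnot(inherits(grid, "mic_grid"))
  k <- findInterval(interval_h, grid$edges, left.open = FALSE)
  out <- k < 1L | k > n_bins(grid)
  k <- clamp(k, 1L, n_bins(grid))
  attr(k, "out_of_grid") <- out
  k
}

#' Summary statistics of paired AM/PM records
#'
#' Per-session means, medians and ranges of intervals and yields, and
#' paired AM-minus-PM comparisons of interval and yield: mean difference,
#' 95% t-interval and the paired t statistic. With zero variance of the
#' within-record differences the t statistic is reported as `NA` with a
#' degenerate flag rather than failing.
#'
#' @param records A validated record table.
#' @return A list of class `"paired_summary"` with elements `sessions`
#'   (tibble of per-session statistics) and `paired` (tibble with one row
#'   per compared quantity: mean difference, CI bounds, t, df, p, and a
#'   `degenerate` flag).
#' @export
summarize_paired_data <- function(records) {
  assert_that(nrow(records) >= 2, "need at least 2 records")
  per_session <- function(session, int, yld) {
    tibble::tibble(
      session = session,
      n = length(int),
      mean_interval_h = mean(int), median_interval_h = median(int),
      min_interval_h = min(int), max_interval_h = max(int),
      mean_yield_kg = mean(yld), median_yield_kg = median(yld),
      min_yield_kg = min(yld), max_yield_kg = max(yld)
    )
  }
  sessions <- dplyr::bind_rows(
    per_session("AM", records$am_interval_h, records$am_yield_kg),
    per_session("PM", records$pm_interval_h, records$pm_yield_kg)
  )
  paired_row <- function(quantity, d) {
    n <- length(d)
    m <- mean(d)
    s <- sd(d)
    if (s == 0) {
      return(tibble::tibble(
        quantity = quantity, mean_diff = m, ci_lo = m, ci_hi = m,
        t = NA_real_, df = n - 1, p = NA_real_, degenerate = TRUE
      ))
    }
    se <- s / sqrt(n)
    tcrit <- qt(0.975, n - 1)
    tstat <- m / se
    tibble::tibble(
      quantity = quantity, mean_diff = m,
      ci_lo = m - tcrit * se, ci_hi = m + tcrit * se,
      t = tstat, df = n - 1,
      p = 2 * pt(-abs(tstat), n - 1), degenerate = FALSE
    )
  }
  paired <- dplyr::bind_rows(
    paired_row("interval_am_minus_pm_h",
               records$am_interval_h - records$pm_interval_h),
    paired_row("yield_am_minus_pm_kg",
               records$am_yield_kg - records$pm_yield_kg)
  )
  structure(list(sessions = sessions, paired = paired),
            class = "paired_summary")
}

#' @export
print.paired_summary <- function(x, ...) {
  cat("Paired AM/PM summary\n")
  print(x$sessions)
  print(x$paired)
  invisible(x)
}

## Long ("stacked") view of paired records used for model training: one
## row per record per session with the session's interval, its own yield
## x, the daily total y, and the ACF response z = y - 2x (equivalently the
## complementary-session yield minus the measured one).
stack_sessions <- function(records, sessions = SESSIONS) {
  records$.row_id <- seq_len(nrow(records))
  one <- function(session) {
    x <- if (session == "AM") records$am_yield_kg else records$pm_yield_kg
    t <- if (session == "AM") records$am_interval_h else records$pm_interval_h
    y <- records$am_yield_kg + records$pm_yield_kg
    tibble::tibble(
      row_id = records$.row_id,
      session = session,
      x = x, t = t, y = y, z = y - 2 * x,
      dim = records$dim,
      lactation_month = records$lactation_month
    )
  }
  dplyr::bind_rows(lapply(sessions, one))
}

## Single-row-per-record view at prediction time: only the measured
## session's yield/interval are used.
measured_view <- function(records) {
  is_am <- records$measured_session == "AM"
  tibble::tibble(
    row_id = seq_len(nrow(records)),
    session = records$measured_session,
    x = ifelse(is_am, records$am_yield_kg, records$pm_yield_kg),
    t = ifelse(is_am, records$am_interval_h, records$pm_interval_h),
    y = records$am_yield_kg + records$pm_yield_kg,
    dim = records$dim,
    lactation_month = records$lactation_month
  )
}
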