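## Reproducible-run plumbing: run configuration, factor-table and report
## serialization, and the simulate / factors / crossval pipeline steps.
## A thin command-line wrapper over these functions ships in
## inst/cli/ampmyield.R.

#' Number of factor cells in a cross-classification
#'
#' Additive correction factors tabulated over several categorical
#' dimensions require one cell per combination; the count is the product
#' of the cardinalities (e.g. 20 interval classes x 4 regions x 4 years
#' x 4 seasons x 2 parities = 2,560 cells), which is why high-dimensional
#' categorical ACF tables become impractical.
#'
#' @param dims Integer vector of category cardinalities (all >= 1).
#' @return The product, as a double.
#' @export
acf_cell_count <- function(dims) {
  assert_that(length(dims) > 0, "dims must be non-empty")
  assert_that(all(dims >= 1) && all(dims == floor(dims)),
              "cardinalities must be positive integers")
  prod(as.numeric(dims))
}

#' Default run configuration
#'
#' @param ... Overrides of the defaults: `input` (record file path) or
#'   `profile` (synthetic profile name), `n_cows`, `records_per_cow`,
#'   `models`, `k`, `replicates`, `fold_unit`, `grid_min_h`,
#'   `grid_max_h`, `grid_width_h`, `d0`, `acf_convention`,
#'   `m7_dim_adjust`, `m5_weighted`, `sigma2`, `seed`, `out_dir`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    input = NULL,
    profile = "holstein",
    n_cows = 1000L,
    records_per_cow = 2L,
    models = c("M0", "M1", "M2A", "M2B", "M3A", "M3B", "M4",
               "M5", "M6", "M7A", "M7B", "M8A", "M8B"),
    k = 10L,
    replicates = 30L,
    fold_unit = "record",
    grid_min_h = 6,
    grid_max_h = 20,
    grid_width_h = 1,
    d0 = 158,
    acf_convention = "interval_only",
    m7_dim_adjust = TRUE,
    m5_weighted = FALSE,
    sigma2 = "full",
    seed = 1L,
    out_dir = "."
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  assert_that(length(bad) == 0,
              "unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  assert_that(length(cfg$models) >= 1, "at least one model required")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file of `run_config()` fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), "config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

config_grid <- function(config) {
  mic_grid(config$grid_min_h, config$grid_max_h, config$grid_width_h)
}

#' Simulate a milking-record file
#'
#' Generates a synthetic dataset from the configured breed profile,
#' writes it in the exchange format together with a YAML metadata file
#' recording the profile, seed, package version and config hash. Two
#' runs with identical configs produce byte-identical record files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `records_path`, `metadata_path` and
#'   the records tibble.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  profile <- breed_profile(config$profile)
  records <- generate_milking_data(profile, config$n_cows,
                                   config$records_per_cow,
                                   seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  records_path <- file.path(config$out_dir, "milking_records.csv")
  write_milking_records(records, records_path)
  metadata_path <- file.path(config$out_dir, "milking_records_meta.yaml")
  yaml::write_yaml(list(
    profile = config$profile,
    n_cows = config$n_cows,
    records_per_cow = config$records_per_cow,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ampmyield")),
    config_hash = config_hash(unclass(config))
  ), metadata_path)
  invisible(list(records_path = records_path, metadata_path = metadata_path,
                 records = records))
}

#' Write a correction-factor table to delimited text
#'
#' ACF tables are written with columns session, bin_lo, bin_hi,
#' midpoint, delta_kg, n_train, imputed, convention, d0; MCF tables with
#' session, bin_lo, bin_hi, midpoint, F, rho, n_train, Ex, Vx, Ey, Vy,
#' gamma, d0, imputed, model_id. Absent statistics are written as empty
#' fields.
#'
#' @param table An `acf_table` or `mcf_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_factor_table <- function(table, path) {
  if (inherits(table, "acf_table")) {
    out <- tibble::tibble(
      session = table$session, bin_lo = table$bin_lo,
      bin_hi = table$bin_hi, midpoint = table$midpoint,
      delta_kg = table$delta_kg, n_train = table$n_train,
      imputed = table$imputed,
      convention = attr(table, "convention"),
      d0 = attr(table, "d0")
    )
  } else if (inherits(table, "mcf_table")) {
    gamma <- attr(table, "gamma")
    pick <- function(nm) if (nm %in% names(table)) table[[nm]] else NA_real_
    out <- tibble::tibble(
      session = table$session, bin_lo = table$bin_lo,
      bin_hi = table$bin_hi, midpoint = table$midpoint,
      F = table$F, rho = pick("rho"), n_train = pick("n_train"),
      Ex = pick("Ex"), Vx = pick("Vx"), Ey = pick("Ey"), Vy = pick("Vy"),
      gamma = if (!is.null(gamma)) unname(gamma[table$session]) else
        pick("gamma"),
      d0 = attr(table, "d0"),
      imputed = table$imputed,
      model_id = attr(table, "model_id")
    )
  } else {
    stop_dmy("not a factor table")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a correction-factor table written by [write_factor_table()]
#'
#' @param path File path.
#' @return A tibble (plain; class attributes are not reconstructed).
#' @export
read_factor_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Compute and write factor tables for a set of models
#'
#' One file per requested factor-capable model. The doubling model is
#' written as the constant table `F = 2` in every bin; requesting the
#' quadratic regression (M4), which admits no factor strategy, is an
#' explicit refusal.
#'
#' @param records Validated paired records.
#' @param config A [run_config()]; `config$models` selects the tables.
#' @return Invisibly, named list of written file paths.
#' @export
run_factor_tables <- function(records, config) {
  stopifnot(inherits(config, "run_config"))
  grid <- config_grid(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- vapply(config$models, function(m) {
    model_label(as_model_spec(m))
  }, character(1))
  assert_that(!any(labels == "M4"),
              "M4 admits no factor strategy; no factor table can be produced")
  paths <- list()
  for (lab in labels) {
    lab_factor <- sub("A$", "B", lab)
    spec <- as_model_spec(lab_factor, d0 = config$d0)
    if (spec$strategy != "factor" && spec$model_id != "M0") next
    if (spec$model_id == "M0") {
      tab <- new_mcf_table(
        dplyr::bind_rows(lapply(SESSIONS, function(s) {
          tb <- bin_frame(grid, s)
          tb$F <- 2
          tb$imputed <- FALSE
          tb
        })), "M0"
      )
    } else {
      m <- fit_dmy_model(records, spec, grid = grid,
                         acf_convention = config$acf_convention,
                         m7_dim_adjust = config$m7_dim_adjust,
                         m5_weighted = config$m5_weighted)
      tab <- if (spec$model_id == "M1") {
        m1_cells_as_table(m$fit)
      } else {
        m$table
      }
    }
    path <- file.path(config$out_dir,
                      paste0("factors_", model_label(spec), ".csv"))
    if (inherits(tab, "acf_table") || inherits(tab, "mcf_table")) {
      write_factor_table(tab, path)
    } else {
      readr::write_csv(tab, path, progress = FALSE)
    }
    paths[[model_label(spec)]] <- path
  }
  invisible(paths)
}

## M1's cell-mean table serialized in the ACF layout, one row per
## session x MIC x lactation-month cell.
m1_cells_as_table <- function(fit) {
  cells <- fit$cells
  grid <- fit$grid
  tibble::tibble(
    session = cells$session,
    bin_lo = grid$edges[cells$mic],
    bin_hi = grid$edges[cells$mic + 1],
    midpoint = grid$midpoints[cells$mic],
    lactation_month = cells$lactation_month,
    delta_kg = cells$delta,
    n_train = cells$n,
    imputed = cells$imputed,
    convention = "cell_mean",
    d0 = fit$spec$d0
  )
}

#' Run the cross-validation pipeline and write its reports
#'
#' Runs [run_crossval()] under the configuration and writes the summary
#' table (`cv_summary.csv`, one row per model with Var, Bias2, MSE, Acc
#' and Cor), the per-record accuracy file (`cv_individual.csv`) and a
#' YAML log of the plan, seed, models and config hash.
#'
#' @param records Validated paired records.
#' @param config A [run_config()].
#' @return Invisibly, the `cv_report`.
#' @export
run_cv_pipeline <- function(records, config) {
  stopifnot(inherits(config, "run_config"))
  grid <- config_grid(config)
  plan <- cv_plan(k = config$k, replicates = config$replicates,
                  unit = config$fold_unit, seed = config$seed)
  report <- run_crossval(records, config$models, plan = plan, grid = grid,
                         sigma2 = config$sigma2,
                         acf_convention = config$acf_convention,
                         m7_dim_adjust = config$m7_dim_adjust,
                         m5_weighted = config$m5_weighted)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(format_cv_table(report),
                   file.path(config$out_dir, "cv_summary.csv"),
                   progress = FALSE)
  readr::write_csv(report$per_record,
                   file.path(config$out_dir, "cv_individual.csv"),
                   progress = FALSE)
  yaml::write_yaml(list(
    models = report$models,
    k = plan$k, replicates = plan$replicates, unit = plan$unit,
    seed = plan$seed, sigma2 = report$sigma2,
    n_records = length(report$actual),
    n_failures = length(report$failures),
    config_hash = config_hash(unclass(config)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), file.path(config$out_dir, "cv_log.yaml"))
  invisible(report)
}
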