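#' Run the full forecasting pipeline from a configuration file
#'
#' Executes read → coverage filter → weekly aggregation → Monte Carlo
#' forecast → horizon → binning → (optional) validation → HTML report,
#' logging each stage with record counts to standard error and writing all
#' artifacts to an output directory. Any stage failure is re-raised with
#' the stage name so a shell caller exits non-zero with a useful message.
#'
#' The configuration is a YAML key-value file:
#'
#' ```yaml
#' seed: 42
#' output_dir: out
#' simulate:                     # optional: generate synthetic inputs
#'   n_weeks: 120
#'   base_weekly_pregnancies: 110
#'   seasonal_amplitude: 0.1
#' inputs:                       # or point at existing files
#'   records: records.csv        # filled in automatically when simulating
#'   actual_births: actual.csv   # weekly registry counts (optional)
#'   pmf: synthetic-standin      # or a PMF file path
#' coverage_threshold_pct: 55
#' forecast:
#'   n_reps: 1000
#'   ci_level: 0.95
#'   ci_method: normal
#'   bin_width: 2
#'   horizon_weeks: 13
#'   as_of_week: 2016-06-06      # optional; enables the horizon rule
#'   registration_lead_weeks: 29
#' validate:
#'   widths: [1, 2, 3]
#' report:
#'   title: Regional birth forecast
#' ```
#'
#' @param config_path Path to the YAML configuration.
#' @param out_dir Output directory override; defaults to the config's
#'   `output_dir` (itself defaulting to the config file's directory).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a named list of artifact paths (`forecast`,
#'   `forecast_binned`, `report`, and when applicable `records`,
#'   `realized_births`, `validation`).
#' @export
run_pipeline <- function(config_path, out_dir = NULL, quiet = FALSE) {
  log_stage <- function(...) if (!quiet) message("[birthcast] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cfg <- stage("config", {
    if (!file.exists(config_path)) stop("config file not found: ", config_path)
    yaml::read_yaml(config_path)
  })
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$output_dir %||% dirname(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()

  pmf <- stage("pmf", {
    p <- cfg$inputs$pmf %||% "synthetic-standin"
    if (identical(p, "synthetic-standin")) synthetic_gestation_pmf()
    else read_gestation_pmf(p)
  })
  log_stage("pmf '%s': %d offsets on [%d, %d]", pmf_id(pmf), nrow(pmf),
            min(pmf$offset_weeks), max(pmf$offset_weeks))

  if (!is.null(cfg$simulate)) {
    sim <- stage("simulate", {
      sc_args <- cfg$simulate
      if (!is.null(sc_args$municipalities)) {
        sc_args$municipalities <- dplyr::bind_rows(sc_args$municipalities)
      }
      if (!is.null(sc_args$start_week)) {
        sc_args$start_week <- as.Date(sc_args$start_week)
      }
      sc_args$gestation_pmf <- pmf
      sc_args$seed <- as.integer(sc_args$seed %||% seed)
      cohort <- generate_cohort(do.call(synthetic_config, sc_args))
      rec_path <- file.path(out_dir, "synthetic_records.csv")
      act_path <- file.path(out_dir, "synthetic_actual_births.csv")
      write_pregnancy_records(cohort$records, rec_path)
      write_birth_counts(
        cohort$realized_births[, c("municipality", "iso_year", "iso_week",
                                   "births")], act_path)
      list(records = rec_path, actual = act_path, n = nrow(cohort$records))
    })
    log_stage("simulate: %d observed records -> %s", sim$n, sim$records)
    cfg$inputs$records <- cfg$inputs$records %||% sim$records
    cfg$inputs$actual_births <- cfg$inputs$actual_births %||% sim$actual
    artifacts$records <- sim$records
    artifacts$realized_births <- sim$actual
  }

  records <- stage("read-records", {
    if (is.null(cfg$inputs$records)) stop("no records input configured")
    read_pregnancy_records(cfg$inputs$records)
  })
  log_stage("read %d pregnancy records", nrow(records))

  actual_weekly <- NULL
  if (!is.null(cfg$inputs$actual_births)) {
    actual_weekly <- stage("read-actual", {
      ab <- read_birth_counts(cfg$inputs$actual_births)
      if (!identical(attr(ab, "granularity"), "weekly")) {
        stop("actual_births must be weekly for validation/report overlays")
      }
      ab$week_start <- iso_week_start(ab$iso_year, ab$iso_week)
      ab
    })
    threshold <- cfg$coverage_threshold_pct %||% 55
    cov <- stage("coverage-filter", {
      compute_coverage(
        dplyr::count(records, .data$municipality),
        actual_weekly |>
          dplyr::summarise(n = sum(.data$births), .by = "municipality"),
        threshold_pct = threshold)
    })
    included <- filter_by_coverage(cov, threshold_pct = threshold)
    log_stage("coverage filter (>= %s%%): %d of %d municipalities included",
              threshold, length(included), nrow(cov))
    records <- dplyr::filter(records, .data$municipality %in% included)
    actual_weekly <- actual_weekly |>
      dplyr::filter(.data$municipality %in% included) |>
      dplyr::summarise(births = sum(.data$births), .by = "week_start") |>
      dplyr::arrange(.data$week_start)
  }

  fcfg <- cfg$forecast %||% list()
  fc <- stage("forecast", {
    expected <- aggregate_expected_by_week(records)
    if (nrow(expected) == 0) stop("no records to forecast from")
    mc_forecast(expected, pmf,
                n_reps = fcfg$n_reps %||% 1000,
                seed = as.integer(fcfg$seed %||% seed),
                ci_method = fcfg$ci_method %||% "normal",
                ci_level = fcfg$ci_level %||% 0.95)
  })
  log_stage("forecast: %d target weeks (%d complete), %d reps",
            nrow(fc), sum(fc$complete), attr(fc, "n_reps"))

  if (!is.null(fcfg$as_of_week)) {
    fc <- stage("horizon", {
      apply_horizon(fc, as.Date(fcfg$as_of_week),
                    horizon_weeks = fcfg$horizon_weeks %||% 13,
                    registration_lead_weeks =
                      fcfg$registration_lead_weeks %||% 29)
    })
    log_stage("horizon: %d weeks retained up to %s + %d",
              nrow(fc), fcfg$as_of_week, fcfg$horizon_weeks %||% 13)
  }

  artifacts$forecast <- file.path(out_dir, "forecast_weekly.csv")
  stage("write-forecast", write_forecast(fc, artifacts$forecast))

  bw <- fcfg$bin_width %||% 2
  fc_binned <- stage("bin", bin_series(fc, width_weeks = bw))
  artifacts$forecast_binned <- file.path(out_dir, "forecast_binned.csv")
  readr::write_csv(fc_binned, artifacts$forecast_binned)
  log_stage("binned to %d-weekly: %d bins", bw, nrow(fc_binned))

  actual_binned <- NULL
  if (!is.null(actual_weekly)) {
    if (!is.null(cfg$validate)) {
      rep_v <- stage("validate", {
        binning_validation(fc, actual_weekly,
                           widths = unlist(cfg$validate$widths %||%
                                             c(1, 2, 3)))
      })
      artifacts$validation <- file.path(out_dir, "validation.json")
      write_validation_report(rep_v, artifacts$validation)
      log_stage("validation: r = %s; weekly CI coverage %.3f",
                paste(sprintf("%.3f", rep_v$r_by_bin_width$r),
                      collapse = "/"),
                rep_v$ci_coverage_fraction)
    }
    actual_binned <- bin_series(actual_weekly, width_weeks = bw,
                                anchor = min(fc_binned$bin_start))
    actual_binned <- actual_binned[actual_binned$bin_start %in%
                                     fc_binned$bin_start, ]
  }

  artifacts$report <- file.path(out_dir, "report.html")
  stage("report", {
    render_html_report(
      fc_binned, actual = actual_binned,
      spec = report_spec(bin_width = bw,
                         ci_level = fcfg$ci_level %||% 0.95,
                         title = cfg$report$title %||%
                           "Regional birth forecast"),
      path = artifacts$report)
  })
  log_stage("report written to %s", artifacts$report)
  invisible(artifacts)
}
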