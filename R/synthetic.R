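#' Configuration for the synthetic pregnancy cohort generator
#'
#' The generator emulates the statistical structure the forecaster assumes
#' about a regional screening cohort: weekly pregnancy intake with seasonal
#' variation, a left-skewed gestational-length offset distribution, partial
#' screening-provider coverage per municipality, and registration about 29
#' weeks before the expected date (first-trimester booking bloods of a
#' 40-week term). Defaults are sized to resemble a mid-sized Dutch region:
#' about 110 registered pregnancies per week across five municipalities
#' whose coverage fractions span 0.70–1.10, three years of weeks, and mild
#' (10%) seasonal amplitude.
#'
#' @param n_weeks Number of due-date weeks to simulate.
#' @param start_week First due-date week (a Monday `Date`).
#' @param base_weekly_pregnancies Regional mean pregnancies per week (all
#'   municipalities, before coverage thinning).
#' @param seasonal_amplitude Relative sinusoidal modulation of the weekly
#'   rate, in \[0, 1).
#' @param seasonal_period Period of the seasonal cycle in weeks.
#' @param municipalities Tibble with columns `label`, `share` (relative
#'   intake, normalized internally) and `coverage_fraction` in (0, 1.2]:
#'   the probability that a pregnancy is registered with the screening
#'   provider (values above 1 emulate cross-municipality delivery flows).
#' @param gestation_pmf A [gestation_pmf] used both to realize birth weeks
#'   and (typically) to forecast.
#' @param intake `"poisson"` for stochastic weekly intake, `"fixed"` for
#'   deterministic rounded rates (the zero-noise limit used in
#'   calibration checks).
#' @param registration_lead_weeks Weeks between registration and the
#'   expected date.
#' @param seed Integer RNG seed for the generator.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_weeks = 156,
                             start_week = iso_week_start(2015, 1),
                             base_weekly_pregnancies = 110,
                             seasonal_amplitude = 0.10,
                             seasonal_period = 52,
                             municipalities = tibble::tibble(
                               label = c("Noorddorp", "Zuiddorp", "Oostwijk",
                                         "Westburg", "Middelstad"),
                               share = c(0.10, 0.15, 0.20, 0.25, 0.30),
                               coverage_fraction = c(0.70, 0.80, 0.90,
                                                     1.00, 1.10)
                             ),
                             gestation_pmf = synthetic_gestation_pmf(),
                             intake = c("poisson", "fixed"),
                             registration_lead_weeks = 29,
                             seed = 1) {
  intake <- match.arg(intake)
  stopifnot(
    n_weeks >= 1,
    base_weekly_pregnancies > 0,
    seasonal_amplitude >= 0, seasonal_amplitude < 1,
    seasonal_period > 0,
    all(c("label", "share", "coverage_fraction") %in% names(municipalities)),
    all(municipalities$share > 0),
    all(municipalities$coverage_fraction > 0),
    all(municipalities$coverage_fraction <= 1.2),
    inherits(gestation_pmf, "gestation_pmf")
  )
  municipalities$share <- municipalities$share / sum(municipalities$share)
  structure(
    list(
      n_weeks = as.integer(n_weeks),
      start_week = week_start_of(as.Date(start_week)),
      base_weekly_pregnancies = base_weekly_pregnancies,
      seasonal_amplitude = seasonal_amplitude,
      seasonal_period = seasonal_period,
      municipalities = municipalities,
      gestation_pmf = gestation_pmf,
      intake = intake,
      registration_lead_weeks = as.integer(registration_lead_weeks),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic screening cohort with ground truth
#'
#' Draws weekly pregnancy counts per municipality (Poisson around a
#' sinusoidally modulated rate, or deterministic in the zero-noise limit),
#' assigns each pregnancy an expected birth date (uniform weekday within
#' its due week), realizes its birth week as due week plus a gestational
#' offset drawn from the configured PMF, and marks it observed with
#' probability equal to the municipality's coverage fraction. Screening
#' records contain only observed pregnancies, while realized births count
#' every pregnancy — emulating a complete national registry against a
#' partial provider database. A fixed seed makes the cohort reproducible.
#'
#' For coverage fractions above 1 (cross-municipality delivery flows), the
#' excess probability is realized as additional observed-only registrations
#' cloned from the same week, so provider counts can exceed registry
#' counts as they do in practice.
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (observed pregnancies: `pregnancy_id`,
#'   `municipality`, `expected_birth_date`), `realized_births` (all
#'   pregnancies by municipality and ISO birth week: `municipality`,
#'   `iso_year`, `iso_week`, `week_start`, `births`), and `truth` (the
#'   config plus totals: `n_pregnancies`, `n_observed`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_forecast_seed(config$seed, {
    weeks <- config$start_week + 7 * (seq_len(config$n_weeks) - 1L)
    t <- seq_len(config$n_weeks) - 1L
    season <- 1 + config$seasonal_amplitude *
      sin(2 * pi * t / config$seasonal_period)
    muni <- config$municipalities
    per_week <- tidyr::expand_grid(
      municipality = muni$label,
      wk = seq_len(config$n_weeks)
    ) |>
      dplyr::left_join(
        stats::setNames(muni[, c("label", "share", "coverage_fraction")],
                        c("municipality", "share", "coverage_fraction")),
        by = "municipality"
      ) |>
      dplyr::mutate(
        rate = config$base_weekly_pregnancies * .data$share * season[.data$wk],
        n = if (config$intake == "poisson") rpois(dplyr::n(), .data$rate)
            else as.integer(round_half_away(.data$rate)),
        expected_week = weeks[.data$wk]
      )
    preg <- per_week |>
      dplyr::filter(.data$n > 0) |>
      tidyr::uncount(.data$n) |>
      dplyr::select("municipality", "coverage_fraction", "expected_week")
    n_preg <- nrow(preg)
    preg <- preg |>
      dplyr::mutate(
        expected_birth_date = .data$expected_week +
          sample(0:6, n_preg, replace = TRUE),
        offset = sample_offsets(config$gestation_pmf, n_preg),
        birth_week = .data$expected_week + 7L * .data$offset,
        observed = stats::runif(n_preg) < pmin(.data$coverage_fraction, 1)
      )
    # coverage > 1: extra observed-only registrations (deliveries credited
    # elsewhere in the registry) cloned within the same due week
    extra <- preg |>
      dplyr::filter(.data$coverage_fraction > 1) |>
      dplyr::mutate(keep = stats::runif(dplyr::n()) <
                      (.data$coverage_fraction - 1)) |>
      dplyr::filter(.data$keep) |>
      dplyr::select(-"keep")
    obs <- dplyr::bind_rows(
      dplyr::filter(preg, .data$observed),
      extra
    ) |> dplyr::arrange(.data$expected_week, .data$municipality)
    records <- tibble::tibble(
      pregnancy_id = sprintf("P%06d", seq_len(nrow(obs))),
      municipality = obs$municipality,
      expected_birth_date = obs$expected_birth_date
    )
    realized <- preg |>
      dplyr::count(.data$municipality, week_start = .data$birth_week,
                   name = "births") |>
      dplyr::arrange(.data$municipality, .data$week_start) |>
      add_iso_labels() |>
      dplyr::relocate("municipality")
    list(
      records = records,
      realized_births = realized,
      truth = list(
        config = config,
        n_pregnancies = n_preg,
        n_observed = nrow(records)
      )
    )
  })
}

#' Run the full forecasting pipeline on a synthetic cohort
#'
#' The end-to-end test harness: generates a cohort, applies the coverage
#' filter (provider registrations vs registry births, pooled per
#' municipality), aggregates due dates of the included municipalities to
#' weekly counts, runs the Monte Carlo forecast, and validates it against
#' the realized regional births with [binning_validation()]. Realized
#' births are summed over the included municipalities only, mirroring how
#' registry outcome data are restricted to the modelled area.
#'
#' @param config A [synthetic_config()].
#' @param n_reps Monte Carlo replicates for the forecast.
#' @param widths Bin widths for validation.
#' @param threshold_pct Coverage inclusion threshold.
#' @param ci_level Confidence level.
#' @return A `validation_report` with an extra element `details` (the
#'   cohort, coverage table, and forecast) for inspection.
#' @export
end_to_end_recovery <- function(config, n_reps = 500, widths = c(1, 2, 3),
                                threshold_pct = 55, ci_level = 0.95) {
  cohort <- generate_cohort(config)
  expected_by_muni <- dplyr::count(cohort$records, .data$municipality) |>
    dplyr::rename(n = "n")
  actual_by_muni <- cohort$realized_births |>
    dplyr::summarise(n = sum(.data$births), .by = "municipality")
  coverage <- compute_coverage(expected_by_muni, actual_by_muni,
                               threshold_pct = threshold_pct)
  included <- filter_by_coverage(coverage, threshold_pct = threshold_pct)
  records <- dplyr::filter(cohort$records, .data$municipality %in% included)
  expected_weekly <- aggregate_expected_by_week(records)
  fc <- mc_forecast(expected_weekly, config$gestation_pmf,
                    n_reps = n_reps, seed = config$seed + 1L,
                    ci_level = ci_level)
  actual_weekly <- cohort$realized_births |>
    dplyr::filter(.data$municipality %in% included) |>
    dplyr::summarise(births = sum(.data$births), .by = "week_start") |>
    dplyr::arrange(.data$week_start)
  report <- binning_validation(fc, actual_weekly, widths = widths)
  report$details <- list(cohort = cohort, coverage = coverage, forecast = fc)
  report
}
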