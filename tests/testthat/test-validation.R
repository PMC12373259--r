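make_fc_actual <- function(len = 20, seed = 1) {
  set.seed(seed)
  fc <- weekly_counts(rep(0, len)) |>
    dplyr::mutate(mean = 100 + 10 * sin(seq_len(len)), n = NULL)
  actual <- weekly_counts(rpois(len, 180))
  list(fc = fc, actual = actual)
}

test_that("normalization equalizes means by ratio-of-means scaling", {
  d <- make_fc_actual()
  norm <- normalize_actual_to_forecast(d$fc, d$actual)
  expect_equal(mean(norm$weeks$scaled_actual), mean(norm$weeks$forecast))
  expect_equal(norm$factor,
               mean(norm$weeks$forecast) / mean(norm$weeks$actual))

  # identical series: factor 1; doubled actual: factor 0.5
  same <- dplyr::mutate(d$fc, n = mean)
  expect_equal(normalize_actual_to_forecast(d$fc, same)$factor, 1)
  doubled <- dplyr::mutate(d$fc, n = 2 * mean)
  n2 <- normalize_actual_to_forecast(d$fc, doubled)
  expect_equal(n2$factor, 0.5)
  expect_equal(n2$weeks$scaled_actual, n2$weeks$forecast)

  # idempotence: renormalizing a normalized pair gives factor 1
  renorm <- normalize_actual_to_forecast(
    d$fc, dplyr::tibble(week_start = norm$weeks$week_start,
                        n = norm$weeks$scaled_actual))
  expect_equal(renorm$factor, 1)
})

test_that("normalization rejects degenerate input and supports the coverage variant", {
  d <- make_fc_actual()
  zero <- dplyr::mutate(d$actual, n = 0)
  expect_error(normalize_actual_to_forecast(d$fc, zero), "zero")
  expect_error(
    normalize_actual_to_forecast(d$fc[1, ], d$actual[1, ]), "2 overlapping")
  cv <- normalize_actual_to_forecast(d$fc, d$actual,
                                     method = "scale_forecast",
                                     coverage_fraction = 0.8)
  expect_equal(cv$factor, 1.25)
  expect_equal(cv$weeks$scaled_actual, cv$weeks$actual)
  expect_error(normalize_actual_to_forecast(d$fc, d$actual,
                                            method = "scale_forecast"),
               "coverage_fraction")
})

test_that("pearson_correlation matches the product-moment formula", {
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  a <- c(3, 1, 4, 1, 5)
  expect_equal(pearson_correlation(a, a), 1)
  expect_equal(pearson_correlation(a, -a), -1)
  expect_error(pearson_correlation(a, a[1:3]), "lengths differ")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  expect_error(pearson_correlation(rep(1, 5), a), "constant")
})

test_that("correlation is invariant under positive affine transforms", {
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  r <- pearson_correlation(a, b)
  expect_equal(pearson_correlation(2.5 * a + 7, b), r)
  expect_equal(pearson_correlation(a, 0.1 * b - 3), r)
})

test_that("CI coverage fraction counts weeks inside the band", {
  fc <- mc_forecast(weekly_counts(rep(100, 10)), three_point_pmf(),
                    n_reps = 200, seed = 6)
  at_mean <- tibble::tibble(week_start = fc$week_start,
                            scaled_actual = fc$mean)
  expect_equal(ci_coverage_fraction(fc, at_mean), 1)
  above <- dplyr::mutate(at_mean, scaled_actual = fc$ci_high + 10)
  expect_equal(ci_coverage_fraction(fc, above), 0)
  none <- dplyr::mutate(at_mean, week_start = week_start + 999)
  expect_error(ci_coverage_fraction(fc, none), "no overlapping")
})

test_that("binning_validation is consistent with its components", {
  cfg <- synthetic_config(n_weeks = 80, seed = 17)
  cohort <- generate_cohort(cfg)
  fc <- mc_forecast(aggregate_expected_by_week(cohort$records),
                    cfg$gestation_pmf, n_reps = 300, seed = 18)
  actual <- cohort$realized_births |>
    dplyr::summarise(births = sum(births), .by = week_start) |>
    dplyr::arrange(week_start)
  rep_v <- binning_validation(fc, actual, widths = c(1, 2, 3))

  expect_s3_class(rep_v, "validation_report")
  expect_equal(nrow(rep_v$r_by_bin_width), 3)
  expect_true(all(abs(rep_v$r_by_bin_width$r) <= 1))
  expect_gte(rep_v$ci_coverage_fraction, 0)
  expect_lte(rep_v$ci_coverage_fraction, 1)

  # the width-1 entry equals the weekly Pearson r of the normalized pair
  fc_c <- dplyr::filter(tidy(fc), complete)
  norm <- normalize_actual_to_forecast(fc_c, actual)
  expect_equal(rep_v$r_by_bin_width$r[rep_v$r_by_bin_width$width == 1],
               pearson_correlation(norm$weeks$forecast,
                                   norm$weeks$scaled_actual))
  # and r is unaffected by the normalization factor
  raw <- dplyr::inner_join(fc_c, actual, by = "week_start")
  expect_equal(rep_v$r_by_bin_width$r[1],
               pearson_correlation(raw$mean, raw$births))

  # serialization round trip
  tmp <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep_v, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$ci_coverage_fraction, rep_v$ci_coverage_fraction)
  expect_equal(back$r_by_bin_width$r, rep_v$r_by_bin_width$r)
  # tidiers
  expect_equal(tidy(rep_v), rep_v$r_by_bin_width)
  expect_equal(glance(rep_v)$n_weeks, rep_v$n_weeks)
})
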