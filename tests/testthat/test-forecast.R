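test_that("analytic forecast has exact Poisson-binomial moments", {
  # degenerate PMF: all mass stays in the source week
  af <- analytic_forecast(weekly_counts(100), degenerate_pmf())
  expect_equal(af$mean, 100)
  expect_equal(af$sd, 0)

  # single pregnancy split 50/50 over two weeks: Bernoulli(0.5) moments
  af <- analytic_forecast(weekly_counts(1), gestation_pmf(0:1, c(0.5, 0.5)))
  expect_equal(af$mean, c(0.5, 0.5))
  expect_equal(af$sd, c(0.5, 0.5))

  # conservation of total mass for arbitrary inputs
  set.seed(31)
  for (i in 1:5) {
    counts <- rpois(sample(2:10, 1), 50)
    pmf <- random_pmf()
    expect_equal(sum(analytic_forecast(weekly_counts(counts), pmf)$mean),
                 sum(counts))
  }
})

test_that("MC forecast matches the analytic oracle within MC error", {
  pmf <- three_point_pmf()
  expected <- weekly_counts(200)
  n_reps <- 1000
  fc <- mc_forecast(expected, pmf, n_reps = n_reps, seed = 42)
  af <- analytic_forecast(expected, pmf)
  expect_equal(fc$week_start, af$week_start)
  # per-week MC mean within 4 MC standard errors of the exact mean
  tol <- 4 * af$sd / sqrt(n_reps)
  expect_true(all(abs(fc$mean - af$mean) <= tol))
  # sd ratio close to 1 where variance is non-trivial
  nz <- af$sd > 0
  expect_true(all(fc$sd[nz] / af$sd[nz] > 0.8))
  expect_true(all(fc$sd[nz] / af$sd[nz] < 1.25))
  # total mass conserved exactly in every replicate
  expect_equal(sum(fc$mean), sum(expected$n))
})

test_that("MC forecast is degenerate-exact and seed-deterministic", {
  fc <- mc_forecast(weekly_counts(c(50, 70)), degenerate_pmf(),
                    n_reps = 100, seed = 9)
  expect_equal(fc$mean, c(50, 70))
  expect_equal(fc$sd, c(0, 0))
  expect_equal(fc$ci_low, fc$mean)
  expect_equal(fc$ci_high, fc$mean)

  a <- mc_forecast(weekly_counts(c(10, 30)), three_point_pmf(),
                   n_reps = 50, seed = 123)
  b <- mc_forecast(weekly_counts(c(10, 30)), three_point_pmf(),
                   n_reps = 50, seed = 123)
  expect_identical(tidy(a), tidy(b))
  c <- mc_forecast(weekly_counts(c(10, 30)), three_point_pmf(),
                   n_reps = 50, seed = 124)
  expect_false(identical(tidy(a)$mean, tidy(c)$mean))
  expect_error(mc_forecast(weekly_counts(10), three_point_pmf(),
                           n_reps = 0, seed = 1), "at least 1")
  expect_error(mc_forecast(weekly_counts(10), three_point_pmf(), n_reps = 10),
               "seed")
})

test_that("mc_forecast leaves the caller's RNG state untouched", {
  set.seed(77)
  before <- .Random.seed
  invisible(mc_forecast(weekly_counts(20), three_point_pmf(),
                        n_reps = 10, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("translation equivariance: shifting inputs shifts the forecast", {
  pmf <- three_point_pmf()
  counts <- c(30, 0, 80, 45)
  base <- mc_forecast(weekly_counts(counts), pmf, n_reps = 200, seed = 5)
  shifted <- mc_forecast(
    weekly_counts(counts, start = iso_week_start(2016, 1) + 7 * 4),
    pmf, n_reps = 200, seed = 5)
  expect_equal(shifted$week_start, base$week_start + 28)
  expect_identical(shifted$mean, base$mean)
  expect_identical(shifted$sd, base$sd)
})

test_that("ci_bounds implements normal and percentile intervals", {
  expect_equal(ci_bounds(100, 0, 0.95)$low, 100)
  nb <- ci_bounds(100, 10, 0.95)
  # z(0.975) = 1.959964 computed independently from the normal quantile
  expect_equal(nb$low, 80.40036, tolerance = 1e-6)
  expect_equal(nb$high, 119.59964, tolerance = 1e-6)
  expect_error(ci_bounds(1, 1, 1.5), "level")
  expect_error(ci_bounds(1, 1, 0.95, method = "percentile"), "replicates")

  # CLT check: percentile and normal bounds agree on a near-normal tally
  fc <- mc_forecast(weekly_counts(500), synthetic_gestation_pmf(),
                    n_reps = 10000, seed = 8, ci_method = "percentile")
  nz <- fc$mean > 30 # bulk weeks only; smaller tallies are too discrete
  normal <- ci_bounds(fc$mean, fc$sd, 0.95, "normal")
  expect_true(all(abs(fc$ci_low[nz] - normal$low[nz]) /
                    normal$low[nz] < 0.05))
  expect_true(all(abs(fc$ci_high[nz] - normal$high[nz]) /
                    normal$high[nz] < 0.05))
})

test_that("bin_series sums means, combines sds, drops trailing partials", {
  s <- weekly_counts(1:5) |> dplyr::rename(mean = "n") |>
    dplyr::mutate(mean = c(10, 20, 30, 40, 50), sd = c(1, 2, 3, 4, 5))
  b <- bin_series(s, width_weeks = 2)
  expect_equal(b$mean, c(30, 70)) # hand sums; trailing 50 dropped
  expect_equal(b$sd, c(sqrt(5), sqrt(25)))
  expect_equal(attr(b, "sd_method"), "rss-independence-approx")

  # width 1 is the identity on values
  b1 <- bin_series(s, width_weeks = 1)
  expect_equal(b1$mean, s$mean)
  expect_equal(b1$sd, s$sd)

  # conservation over covered weeks for generated series
  set.seed(41)
  for (w in 2:4) {
    s <- weekly_counts(rpois(13, 30))
    b <- bin_series(s, width_weeks = w)
    covered <- 7 * w * nrow(b)
    expect_equal(sum(b$n),
                 sum(s$n[s$week_start < min(s$week_start) + covered]))
  }
})

test_that("binned forecasts recompute the CI from the combined sd", {
  fc <- mc_forecast(weekly_counts(rep(100, 6)), three_point_pmf(),
                    n_reps = 300, seed = 2)
  b <- bin_series(fc, width_weeks = 2)
  z <- qnorm(0.975)
  expect_equal(b$ci_low, b$mean - z * b$sd)
  expect_equal(attr(b, "n_reps"), attr(fc, "n_reps"))
  expect_equal(attr(b, "pmf_id"), attr(fc, "pmf_id"))
})

test_that("apply_horizon drops far weeks and flags registration gaps", {
  pmf <- synthetic_gestation_pmf()
  expected <- weekly_counts(rep(50, 60))
  fc <- mc_forecast(expected, pmf, n_reps = 50, seed = 1)
  as_of <- iso_week_start(2016, 20)

  # horizon 0: nothing after the reporting week survives
  h0 <- apply_horizon(fc, as_of, horizon_weeks = 0)
  expect_true(all(h0$week_start <= as_of))

  # default horizon 13 retains exactly 13 future weeks
  h13 <- apply_horizon(fc, as_of, horizon_weeks = 13)
  future <- h13$week_start[h13$week_start > as_of]
  expect_length(future, 13)
  expect_equal(max(future), as_of + 7 * 13)

  # with a 29-week registration lead and 17-week preterm reach, weeks
  # beyond as_of + 12 need registrations that cannot exist yet
  flagged <- h13[h13$week_start > as_of + 7 * 12, ]
  expect_true(all(!flagged$complete))
  ok <- h13[h13$week_start <= as_of + 7 * 12 & h13$week_start >= as_of, ]
  expect_true(all(ok$complete))
})

test_that("forecast incomplete weeks undershoot while complete weeks do not", {
  # truncate registrations at a reporting date and compare against the
  # forecast from the full cohort
  cfg <- synthetic_config(n_weeks = 80, seed = 13)
  cohort <- generate_cohort(cfg)
  as_of <- cfg$start_week + 7 * 30
  lead <- cfg$registration_lead_weeks
  # records visible at as_of: due date within the registration lead
  seen <- dplyr::filter(cohort$records,
                        week_start_of(expected_birth_date) <= as_of + 7 * lead)
  fc_seen <- mc_forecast(aggregate_expected_by_week(seen),
                         cfg$gestation_pmf, n_reps = 200, seed = 99)
  fc_all <- mc_forecast(aggregate_expected_by_week(cohort$records),
                        cfg$gestation_pmf, n_reps = 200, seed = 99)
  h <- apply_horizon(fc_seen, as_of, horizon_weeks = 30,
                     registration_lead_weeks = lead)
  joint <- dplyr::inner_join(tidy(h), tidy(fc_all), by = "week_start",
                             suffix = c("_seen", "_all"))
  bad <- dplyr::filter(joint, !complete_seen, week_start > as_of + 7 * 26)
  good <- dplyr::filter(joint, complete_seen, week_start > as_of)
  # deeply incomplete weeks lose most preterm-contributing registrations
  expect_true(mean(bad$mean_seen) < 0.8 * mean(bad$mean_all))
  expect_equal(good$mean_seen, good$mean_all, tolerance = 0.05)
})

test_that("forecast tables round-trip with provenance sidecar", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  fc <- mc_forecast(weekly_counts(c(40, 60)), three_point_pmf(),
                    n_reps = 100, seed = 4)
  write_forecast(fc, tmp)
  expect_true(file.exists(paste0(tmp, ".meta.json")))
  back <- read_forecast(tmp)
  expect_equal(tidy(back), tidy(fc))
  expect_equal(attr(back, "seed"), 4L)
  expect_equal(attr(back, "pmf_id"), pmf_id(three_point_pmf()))
  g <- glance(fc)
  expect_equal(g$n_reps, 100L)
  expect_equal(g$total_mean, 100)
})
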