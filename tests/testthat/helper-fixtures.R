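# Shared fixtures for the test suite; everything is built in code.

# A small three-point offset PMF with known mean 0.1.
three_point_pmf <- function() gestation_pmf(-1:1, c(0.2, 0.5, 0.3))

# Degenerate PMF: every birth in the due-date week.
degenerate_pmf <- function() gestation_pmf(0L, 1)

# A random PMF with probabilities bounded away from zero, so that every
# reachable target week has non-negligible variance.
random_pmf <- function(n_points = sample(3:6, 1)) {
  offs <- sort(sample(-17:5, n_points))
  p <- stats::runif(n_points, min = 0.05, max = 1)
  p <- p / sum(p)
  # force exact unit sum within constructor tolerance
  p[n_points] <- 1 - sum(p[-n_points])
  gestation_pmf(offs, p)
}

# Weekly expected-count tibble on consecutive Mondays.
weekly_counts <- function(n, start = iso_week_start(2016, 1)) {
  tibble::tibble(week_start = start + 7 * (seq_along(n) - 1L), n = n)
}

# Three-record set used in round-trip tests.
sample_records <- function() {
  tibble::tibble(
    pregnancy_id = c("A1", "A2", "B1"),
    municipality = c("Noorddorp", "Noorddorp", "Zuiddorp"),
    expected_birth_date = as.Date(c("2016-03-07", "2016-03-10", "2016-04-01"))
  )
}

# Bundled pooled per-municipality counts for the Utrecht study region.
region_counts <- function() utrecht_region_counts()
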