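#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats qnorm quantile rmultinom rpois rbinom cor sd
NULL

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_forecast_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Expand a weekly count tibble onto a dense Monday grid (gaps -> 0) and
# return the grid dates plus counts.
dense_weekly_grid <- function(expected) {
  stopifnot(all(c("week_start", "n") %in% names(expected)), nrow(expected) > 0)
  ws <- as.Date(expected$week_start)
  if (any(as.integer(ws - week_start_of(ws)) != 0L)) {
    stop("week_start values must be Mondays of ISO weeks", call. = FALSE)
  }
  grid <- seq(min(ws), max(ws), by = "7 days")
  n <- integer(length(grid))
  n[match(ws, grid)] <- as.integer(expected$n)
  list(weeks = grid, n = n)
}

# Completeness of target weeks: TRUE where every contributing source week
# (target - offset, offset over the PMF support) lies inside the source span.
target_completeness <- function(target_weeks, source_min, source_max, pmf) {
  max_o <- max(pmf$offset_weeks)
  min_o <- min(pmf$offset_weeks)
  target_weeks >= source_min + 7 * max_o & target_weeks <= source_max + 7 * min_o
}

#' Exact analytic forecast (Poisson-binomial moments)
#'
#' The Monte Carlo forecaster assigns each registered pregnancy in source
#' week *s* independently to target week *s + o* with probability *p(o)*
#' from the gestational offset PMF. The tally in target week *w* is then a
#' sum of independent Bernoulli indicators — Poisson-binomial — with exact
#' moments
#' \deqn{\mu_w = \sum_s n_s\, p(w-s), \qquad
#'       \sigma^2_w = \sum_s n_s\, p(w-s)\,\{1 - p(w-s)\}.}
#' This closed form is deterministic and serves as the oracle against which
#' the Monte Carlo engine is checked; it is also useful on its own when no
#' uncertainty resampling is wanted.
#'
#' @param expected A weekly count tibble with columns `week_start` (Monday
#'   `Date`) and `n`, e.g. from [aggregate_expected_by_week()]. Gaps are
#'   treated as zero weeks.
#' @param pmf A [gestation_pmf].
#' @return A tibble with columns `iso_year`, `iso_week`, `week_start`,
#'   `mean`, `sd`, `complete`; target weeks span the source range extended
#'   by the PMF support. `complete` is `TRUE` where all contributing source
#'   weeks lie inside the data range.
#' @export
analytic_forecast <- function(expected, pmf) {
  g <- dense_weekly_grid(expected)
  offs <- pmf$offset_weeks
  probs <- pmf$probability
  target <- seq(min(g$weeks) + 7 * min(offs), max(g$weeks) + 7 * max(offs),
                by = "7 days")
  mean_w <- numeric(length(target))
  var_w <- numeric(length(target))
  src_idx <- seq_along(g$weeks)
  base <- as.integer((g$weeks[1] - target[1]) / 7)  # index of first source in target grid
  for (k in seq_along(offs)) {
    tgt <- src_idx + base + offs[k]
    mean_w[tgt] <- mean_w[tgt] + g$n * probs[k]
    var_w[tgt] <- var_w[tgt] + g$n * probs[k] * (1 - probs[k])
  }
  tibble::tibble(
    week_start = target,
    mean = mean_w,
    sd = sqrt(var_w),
    complete = target_completeness(target, min(g$weeks), max(g$weeks), pmf)
  ) |> add_iso_labels()
}

#' Monte Carlo birth forecast
#'
#' Redistributes each week's registered due-date count over the surrounding
#' weeks by drawing, per replicate, one gestational offset for every
#' pregnancy (implemented as one multinomial tally per source week per
#' replicate, which is distributionally identical and much faster), then
#' summarises the replicate tallies into a per-week mean, standard
#' deviation, and confidence band. The default 1000 replicates reproduce
#' the analytic Poisson-binomial moments to Monte Carlo error.
#'
#' Replication is by whole series: each replicate redistributes every
#' source week once with independent draws, and moments are taken across
#' replicates per target week.
#'
#' @inheritParams analytic_forecast
#' @param n_reps Number of Monte Carlo replicates (default 1000).
#' @param seed Integer RNG seed; the forecast is bit-reproducible for a
#'   fixed seed and the caller's RNG state is left untouched.
#' @param ci_method `"normal"` (mean ± z·sd) or `"percentile"` (empirical
#'   replicate quantiles; implies replicate retention).
#' @param ci_level Two-sided confidence level, default 0.95.
#' @param keep_replicates Retain the replicate tally matrix (target weeks ×
#'   replicates) as an attribute; required by the percentile method.
#' @return A `birth_forecast`: a tibble with columns `iso_year`,
#'   `iso_week`, `week_start`, `mean`, `sd`, `ci_low`, `ci_high`,
#'   `complete`, carrying provenance attributes `n_reps`, `seed`, `pmf_id`,
#'   `ci_method`, `ci_level`.
#' @examples
#' expected <- tibble::tibble(week_start = iso_week_start(2016, 10), n = 100)
#' fc <- mc_forecast(expected, synthetic_gestation_pmf(), n_reps = 200, seed = 1)
#' @export
mc_forecast <- function(expected, pmf, n_reps = 1000, seed,
                        ci_method = c("normal", "percentile"),
                        ci_level = 0.95,
                        keep_replicates = (ci_method[1] == "percentile")) {
  ci_method <- match.arg(ci_method)
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required for reproducible forecasts",
                          call. = FALSE)
  g <- dense_weekly_grid(expected)
  offs <- pmf$offset_weeks
  probs <- pmf$probability
  target <- seq(min(g$weeks) + 7 * min(offs), max(g$weeks) + 7 * max(offs),
                by = "7 days")
  base <- as.integer((g$weeks[1] - target[1]) / 7)
  tallies <- matrix(0L, nrow = length(target), ncol = n_reps)
  with_forecast_seed(seed, {
    for (i in seq_along(g$weeks)) {
      if (g$n[i] == 0L) next
      draws <- rmultinom(n_reps, size = g$n[i], prob = probs)
      rows <- i + base + offs
      tallies[rows, ] <- tallies[rows, ] + draws
    }
  })
  mean_w <- rowMeans(tallies)
  sd_w <- if (n_reps == 1L) numeric(length(target)) else {
    sqrt(rowSums((tallies - mean_w)^2) / (n_reps - 1))
  }
  ci <- ci_bounds(mean_w, sd_w, level = ci_level, method = ci_method,
                  replicates = if (ci_method == "percentile") tallies)
  out <- tibble::tibble(
    week_start = target,
    mean = mean_w,
    sd = sd_w,
    ci_low = ci$low,
    ci_high = ci$high,
    complete = target_completeness(target, min(g$weeks), max(g$weeks), pmf)
  ) |> add_iso_labels()
  attr(out, "n_reps") <- as.integer(n_reps)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "pmf_id") <- pmf_id(pmf)
  attr(out, "ci_method") <- ci_method
  attr(out, "ci_level") <- ci_level
  attr(out, "pmf_support") <- range(offs)
  if (keep_replicates) attr(out, "replicates") <- tallies
  class(out) <- c("birth_forecast", class(out))
  out
}

#' Confidence bounds for forecast means
#'
#' Normal method: `mean ± z(level) * sd`. Percentile method: empirical
#' two-sided quantiles of the retained replicate tallies (rows = weeks).
#'
#' @param mean,sd Numeric vectors of per-week forecast mean and SD.
#' @param level Two-sided confidence level in (0, 1).
#' @param method `"normal"` or `"percentile"`.
#' @param replicates For the percentile method, a matrix with one row per
#'   week and one column per replicate.
#' @return A list with numeric vectors `low` and `high`.
#' @examples
#' ci_bounds(100, 10, 0.95, "normal")  # c(80.4, 119.6)
#' @export
ci_bounds <- function(mean, sd, level = 0.95,
                      method = c("normal", "percentile"), replicates = NULL) {
  method <- match.arg(method)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  alpha <- (1 - level) / 2
  if (method == "normal") {
    z <- qnorm(1 - alpha)
    list(low = mean - z * sd, high = mean + z * sd)
  } else {
    if (is.null(replicates)) {
      stop("percentile CI requires retained replicates", call. = FALSE)
    }
    qs <- apply(replicates, 1, quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    list(low = qs[1, ], high = qs[2, ])
  }
}

#' Bin a weekly series into multi-week blocks
#'
#' Sums consecutive non-overlapping blocks of `width_weeks` weeks starting
#' at `anchor`. Forecast means (and actual counts) are summed; forecast SDs
#' are combined as the root-sum-of-squares under an independence
#' approximation (flagged in the `sd_method` attribute), and the confidence
#' band is recomputed from the combined SD at the series' level. A trailing
#' partial block is dropped rather than reported at a different width.
#'
#' @param series A weekly tibble with a `week_start` column and any of the
#'   value columns `mean`, `sd`, `n`, `births`; typically a
#'   [mc_forecast()] result or a weekly actual-count table.
#' @param width_weeks Block width in weeks (1 returns the input weeks
#'   unchanged apart from bin labelling).
#' @param anchor First week of the evaluation window (`Date`, a Monday);
#'   defaults to the first week of `series`. Weeks before `anchor` are
#'   excluded.
#' @return A tibble with `bin_start` (Monday of the block's first week),
#'   `n_weeks`, and the summed/combined value columns; attributes `width`
#'   and `sd_method`.
#' @export
bin_series <- function(series, width_weeks = 2, anchor = NULL) {
  stopifnot("week_start" %in% names(series), width_weeks >= 1)
  width_weeks <- as.integer(width_weeks)
  ws <- as.Date(series$week_start)
  anchor <- as.Date(anchor %||% min(ws))
  df <- series[ws >= anchor, , drop = FALSE]
  ws <- as.Date(df$week_start)
  bin <- as.integer(floor(as.integer(ws - anchor) / 7 / width_weeks))
  df$.bin <- bin
  ci_level <- attr(series, "ci_level")
  sums <- df |>
    tibble::as_tibble() |>
    dplyr::summarise(
      bin_start = min(.data$week_start),
      n_weeks = dplyr::n(),
      dplyr::across(dplyr::any_of(c("mean", "n", "births")), sum),
      dplyr::across(dplyr::any_of("sd"), ~ sqrt(sum(.x^2))),
      dplyr::across(dplyr::any_of("complete"), all),
      .by = ".bin"
    ) |>
    dplyr::filter(.data$n_weeks == width_weeks) |>
    dplyr::arrange(.data$bin_start) |>
    dplyr::select(-".bin")
  if (all(c("mean", "sd") %in% names(sums)) && !is.null(ci_level)) {
    ci <- ci_bounds(sums$mean, sums$sd, level = ci_level, method = "normal")
    sums$ci_low <- ci$low
    sums$ci_high <- ci$high
  }
  attr(sums, "width") <- width_weeks
  attr(sums, "sd_method") <- "rss-independence-approx"
  attr(sums, "ci_level") <- ci_level
  for (a in c("n_reps", "seed", "pmf_id", "ci_method")) {
    attr(sums, a) <- attr(series, a)
  }
  sums
}

#' Restrict a forecast to its reliable horizon
#'
#' Due dates are registered at the first-trimester screening, about 29
#' weeks before the expected date of birth, so at any reporting date
#' registrations only exist for due-date weeks up to `as_of +
#' registration_lead_weeks`. A target week is flagged incomplete when any
#' of its contributing due-date weeks (up to 5 weeks after it through 17
#' weeks before it on the birth axis, i.e. source weeks `w-min_offset` back
#' to `w-max_offset`) lies beyond that limit — such weeks systematically
#' undercount upcoming births. Weeks more than `horizon_weeks` after
#' `as_of_week` are dropped entirely; 13 weeks is the widest horizon whose
#' forecasts are stable under the default 29-week lead and −17..+5 support.
#'
#' @param forecast A `birth_forecast`.
#' @param as_of_week Reporting date (`Date`; snapped to its ISO week's
#'   Monday).
#' @param horizon_weeks Forecast horizon (default 13).
#' @param registration_lead_weeks Weeks between screening registration and
#'   the expected date (default 29).
#' @return The forecast restricted to weeks up to `as_of + horizon`, with
#'   `complete` downgraded to `FALSE` for registration-incomplete weeks.
#' @export
apply_horizon <- function(forecast, as_of_week, horizon_weeks = 13,
                          registration_lead_weeks = 29) {
  stopifnot(horizon_weeks >= 0)
  as_of <- week_start_of(as.Date(as_of_week))
  support <- attr(forecast, "pmf_support") %||% c(-17L, 5L)
  atts <- forecast_attrs(forecast)
  last_registrable <- as_of + 7 * registration_lead_weeks
  out <- forecast |>
    dplyr::filter(.data$week_start <= as_of + 7 * horizon_weeks) |>
    dplyr::mutate(
      complete = .data$complete &
        (.data$week_start - 7 * support[1]) <= last_registrable
    )
  restore_forecast_attrs(out, atts)
}

forecast_attrs <- function(forecast) {
  nm <- c("n_reps", "seed", "pmf_id", "ci_method", "ci_level", "pmf_support")
  stats::setNames(lapply(nm, function(a) attr(forecast, a)), nm)
}

restore_forecast_attrs <- function(df, atts) {
  for (nm in names(atts)) attr(df, nm) <- atts[[nm]]
  if (!inherits(df, "birth_forecast")) {
    class(df) <- c("birth_forecast", class(df))
  }
  df
}

#' Write / read a forecast table
#'
#' The forecast table is comma-delimited text with header
#' `iso_year,iso_week,mean,sd,ci_low,ci_high,complete`; provenance
#' (replicates, seed, PMF id, CI method and level) goes to a JSON sidecar
#' `<path>.meta.json` so a forecast file alone suffices to re-render a
#' report.
#'
#' @param forecast A `birth_forecast`.
#' @param path Output CSV path.
#' @return `write_forecast()` returns `path` invisibly; `read_forecast()`
#'   returns a `birth_forecast` (attributes restored from the sidecar when
#'   present).
#' @export
write_forecast <- function(forecast, path) {
  cols <- c("iso_year", "iso_week", "mean", "sd", "ci_low", "ci_high",
            "complete")
  readr::write_csv(tibble::as_tibble(forecast)[, cols], path)
  meta <- forecast_attrs(forecast)
  meta$pmf_support <- as.integer(meta$pmf_support)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_forecast
#' @export
read_forecast <- function(path) {
  df <- readr::read_csv(path, col_types = "iiddddl")
  df$week_start <- iso_week_start(df$iso_year, df$iso_week)
  df <- df[, c("iso_year", "iso_week", "week_start", "mean", "sd",
               "ci_low", "ci_high", "complete")]
  meta_path <- paste0(path, ".meta.json")
  atts <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  restore_forecast_attrs(tibble::as_tibble(df), atts)
}

#' @export
print.birth_forecast <- function(x, ...) {
  cat(sprintf(
    "<birth_forecast: %d weeks, %s reps, seed %s, pmf '%s', %s%% %s CI>\n",
    nrow(x), attr(x, "n_reps") %||% "?", attr(x, "seed") %||% "?",
    attr(x, "pmf_id") %||% "?", 100 * (attr(x, "ci_level") %||% NA),
    attr(x, "ci_method") %||% "?"))
  NextMethod()
}

#' Tidiers for forecast objects
#'
#' `tidy()` returns the per-week forecast as a plain tibble; `glance()`
#' returns a one-row provenance and totals summary.
#'
#' @param x A `birth_forecast`.
#' @param ... Unused.
#' @export
tidy.birth_forecast <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "birth_forecast")
  attr(out, "replicates") <- NULL
  out
}

#' @rdname tidy.birth_forecast
#' @export
glance.birth_forecast <- function(x, ...) {
  tibble::tibble(
    n_weeks = nrow(x),
    n_complete = sum(x$complete),
    total_mean = sum(x$mean),
    n_reps = attr(x, "n_reps") %||% NA_integer_,
    seed = attr(x, "seed") %||% NA_integer_,
    pmf_id = attr(x, "pmf_id") %||% NA_character_,
    ci_method = attr(x, "ci_method") %||% NA_character_,
    ci_level = attr(x, "ci_level") %||% NA_real_
  )
}

#' @export
autoplot.birth_forecast <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$week_start, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "week", y = "forecast births / week") +
    ggplot2::theme_minimal()
}
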