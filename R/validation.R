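#' Normalize realized births to the forecast scale
#'
#' The screening provider covers only part of the region's pregnancies, so
#' forecast totals sit systematically below registry birth counts. To
#' compare the two series' shapes (and the forecast band against realized
#' births), the actual series is rescaled by the ratio of means over the
#' common window: `factor = mean(forecast) / mean(actual)`, after which the
#' two series have equal means. Alternatively (`method =
#' "scale_forecast"`), the forecast is inflated by `1 / coverage_fraction`
#' and the actual series left untouched.
#'
#' @param forecast A weekly tibble with `week_start` and `mean` (e.g. a
#'   `birth_forecast`); only complete weeks should be supplied.
#' @param actual A weekly tibble with `week_start` and a count column `n`
#'   or `births`.
#' @param method `"scale_actual"` (default, ratio of means) or
#'   `"scale_forecast"` (divide forecast columns by `coverage_fraction`).
#' @param coverage_fraction Regional coverage in (0, 1.2], required by
#'   `"scale_forecast"`.
#' @return A list with `weeks`: a tibble of the common window
#'   (`week_start`, `forecast`, `actual`, `scaled_actual`), and `factor`:
#'   the multiplier applied to the actual series (or `1/coverage` applied
#'   to the forecast).
#' @export
normalize_actual_to_forecast <- function(forecast, actual,
                                         method = c("scale_actual",
                                                    "scale_forecast"),
                                         coverage_fraction = NULL) {
  method <- match.arg(method)
  actual_col <- intersect(c("n", "births"), names(actual))[1]
  if (is.na(actual_col)) stop("`actual` needs a count column `n` or `births`",
                              call. = FALSE)
  joint <- dplyr::inner_join(
    tibble::as_tibble(forecast)[, c("week_start", "mean")],
    stats::setNames(tibble::as_tibble(actual)[, c("week_start", actual_col)],
                    c("week_start", "actual")),
    by = "week_start"
  ) |> dplyr::rename(forecast = "mean") |> dplyr::arrange(.data$week_start)
  if (nrow(joint) < 2) stop("need at least 2 overlapping weeks", call. = FALSE)
  if (method == "scale_actual") {
    if (mean(joint$actual) == 0) {
      stop("mean of actual series is zero; normalization undefined",
           call. = FALSE)
    }
    factor <- mean(joint$forecast) / mean(joint$actual)
    joint$scaled_actual <- factor * joint$actual
  } else {
    if (is.null(coverage_fraction) || coverage_fraction <= 0) {
      stop("`coverage_fraction` required for method = 'scale_forecast'",
           call. = FALSE)
    }
    factor <- 1 / coverage_fraction
    joint$forecast <- joint$forecast * factor
    joint$scaled_actual <- joint$actual
  }
  list(weeks = joint, factor = factor)
}

#' Pearson product-moment correlation with validity checks
#'
#' Standard Pearson r via [stats::cor()], but refusing the degenerate cases
#' (fewer than 3 points, or a constant series) where the coefficient is
#' undefined or meaningless, rather than returning `NA`.
#'
#' @param a,b Equal-length numeric vectors, length ≥ 3, both non-constant.
#' @return Pearson r in \[−1, 1\].
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 points", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  cor(a, b, method = "pearson")
}

#' Fraction of weeks whose realized births fall inside the forecast CI
#'
#' After normalization, counts the proportion of aligned weeks for which
#' the (scaled) realized birth count lies inside `[ci_low, ci_high]`. On
#' data matching the model's assumptions this empirical coverage should be
#' statistically compatible with the nominal CI level.
#'
#' @param forecast A `birth_forecast` (with `ci_low` / `ci_high`).
#' @param scaled_actual A weekly tibble with `week_start` and
#'   `scaled_actual` (e.g. `normalize_actual_to_forecast()$weeks`).
#' @return The coverage fraction in \[0, 1\].
#' @export
ci_coverage_fraction <- function(forecast, scaled_actual) {
  stopifnot(all(c("ci_low", "ci_high") %in% names(forecast)),
            all(c("week_start", "scaled_actual") %in% names(scaled_actual)))
  joint <- dplyr::inner_join(
    tibble::as_tibble(forecast)[, c("week_start", "ci_low", "ci_high")],
    scaled_actual[, c("week_start", "scaled_actual")],
    by = "week_start"
  )
  if (nrow(joint) == 0) stop("no overlapping weeks", call. = FALSE)
  mean(joint$scaled_actual >= joint$ci_low &
         joint$scaled_actual <= joint$ci_high)
}

#' Validate a forecast against realized births across bin widths
#'
#' The validation protocol: normalize the actual series to the forecast
#' scale once on the weekly common window, then for each bin width sum
#' both series into aligned non-overlapping bins (same anchor week) and
#' compute Pearson r, recording the weekly (width-1) CI coverage fraction
#' alongside. Wider bins trade temporal granularity for predictive
#' stability, so r typically rises with width.
#'
#' Only forecast weeks flagged `complete` enter the comparison.
#'
#' @param forecast A `birth_forecast`.
#' @param actual A weekly tibble with `week_start` and count column `n` or
#'   `births`.
#' @param widths Integer bin widths to evaluate (default `c(1, 2, 3)`).
#' @param method,coverage_fraction Passed to
#'   [normalize_actual_to_forecast()].
#' @return A `validation_report` list: `normalization_factor`,
#'   `r_by_bin_width` (tibble `width`, `r`, `n_bins`),
#'   `ci_coverage_fraction` (weekly), `n_weeks`, `window` (first/last
#'   week), `widths`.
#' @export
binning_validation <- function(forecast, actual, widths = c(1, 2, 3),
                               method = "scale_actual",
                               coverage_fraction = NULL) {
  fc <- dplyr::filter(tibble::as_tibble(forecast), .data$complete)
  fc <- restore_forecast_attrs(fc, forecast_attrs(forecast))
  norm <- normalize_actual_to_forecast(fc, actual, method = method,
                                       coverage_fraction = coverage_fraction)
  weeks <- norm$weeks
  if (nrow(weeks) < 3 * max(widths)) {
    stop("overlapping window too short: need at least 3 bins at width ",
         max(widths), call. = FALSE)
  }
  anchor <- min(weeks$week_start)
  r_tbl <- purrr::map_dfr(widths, function(w) {
    fb <- bin_series(weeks[, c("week_start", "forecast")] |>
                       dplyr::rename(mean = "forecast"),
                     width_weeks = w, anchor = anchor)
    ab <- bin_series(weeks[, c("week_start", "scaled_actual")] |>
                       dplyr::rename(n = "scaled_actual"),
                     width_weeks = w, anchor = anchor)
    stopifnot(identical(fb$bin_start, ab$bin_start))
    tibble::tibble(width = as.integer(w),
                   r = pearson_correlation(fb$mean, ab$n),
                   n_bins = nrow(fb))
  })
  cover <- ci_coverage_fraction(fc, weeks[, c("week_start", "scaled_actual")])
  structure(
    list(
      normalization_factor = norm$factor,
      r_by_bin_width = r_tbl,
      ci_coverage_fraction = cover,
      n_weeks = nrow(weeks),
      window = range(weeks$week_start),
      widths = as.integer(widths)
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  window: %s .. %s (%d weeks)\n",
              x$window[1], x$window[2], x$n_weeks))
  cat(sprintf("  normalization factor: %.4f\n", x$normalization_factor))
  for (i in seq_len(nrow(x$r_by_bin_width))) {
    cat(sprintf("  r (width %d): %.3f over %d bins\n",
                x$r_by_bin_width$width[i], x$r_by_bin_width$r[i],
                x$r_by_bin_width$n_bins[i]))
  }
  cat(sprintf("  weekly CI coverage: %.3f\n", x$ci_coverage_fraction))
  invisible(x)
}

#' @export
tidy.validation_report <- function(x, ...) x$r_by_bin_width

#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n_weeks = x$n_weeks,
    window_start = x$window[1],
    window_end = x$window[2],
    normalization_factor = x$normalization_factor,
    ci_coverage_fraction = x$ci_coverage_fraction
  )
}

#' Serialize a validation report to JSON
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(
    list(
      normalization_factor = report$normalization_factor,
      r_by_bin_width = report$r_by_bin_width,
      ci_coverage_fraction = report$ci_coverage_fraction,
      n_weeks = report$n_weeks,
      window = as.character(report$window),
      widths = report$widths
    ),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
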