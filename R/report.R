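#' Report specification
#'
#' Display options for the HTML forecast report. The defaults mirror the
#' deployed tool's stakeholder-chosen settings: 2-weekly bins and a 95%
#' confidence band, optionally overlaid with the average over preceding
#' years.
#'
#' @param bin_width Bin width in weeks (≥ 1).
#' @param show_historical_average Overlay a historical per-bin average when
#'   one is supplied.
#' @param ci_level Confidence level displayed in labels.
#' @param title,subtitle Report strings.
#' @return A `report_spec` list.
#' @export
report_spec <- function(bin_width = 2, show_historical_average = FALSE,
                        ci_level = 0.95,
                        title = "Regional birth forecast",
                        subtitle = NULL) {
  stopifnot(bin_width >= 1)
  structure(list(bin_width = as.integer(bin_width),
                 show_historical_average = show_historical_average,
                 ci_level = ci_level, title = title, subtitle = subtitle),
            class = "report_spec")
}

#' Render a self-contained HTML forecast report
#'
#' Produces a single HTML file with no external resources: an inline-SVG
#' chart of the binned forecast with its confidence band, optionally the
#' realized births rescaled onto the forecast axis (shown against a
#' secondary axis on the original scale), an optional historical-average
#' overlay, a numbers table, and a provenance footer (PMF id, replicates,
#' seed, timestamp). The file can be regenerated from a serialized
#' forecast table alone via [read_forecast()].
#'
#' @param forecast A binned forecast tibble from [bin_series()] (columns
#'   `bin_start`, `mean`, `ci_low`, `ci_high`), or a `birth_forecast`
#'   (binned internally at `spec$bin_width`).
#' @param actual Optional binned actual series aligned to the same bins
#'   (columns `bin_start` and `n` or `births`).
#' @param historical_average Optional per-bin series (columns `bin_start`,
#'   `mean`) with the average over preceding years.
#' @param spec A [report_spec()].
#' @param path Output HTML path.
#' @return `path`, invisibly. Errors (empty series, misaligned bins) leave
#'   no file behind.
#' @export
render_html_report <- function(forecast, actual = NULL,
                               historical_average = NULL,
                               spec = report_spec(), path) {
  if (inherits(forecast, "birth_forecast")) {
    forecast <- bin_series(forecast, width_weeks = spec$bin_width)
  }
  if (nrow(forecast) == 0) stop("empty forecast series", call. = FALSE)
  stopifnot(all(c("bin_start", "mean", "ci_low", "ci_high")
                %in% names(forecast)))
  factor <- NA_real_
  if (!is.null(actual)) {
    acol <- intersect(c("n", "births"), names(actual))[1]
    if (is.na(acol)) stop("`actual` needs a count column `n` or `births`",
                          call. = FALSE)
    if (!all(actual$bin_start %in% forecast$bin_start)) {
      stop("actual series bins are not aligned with the forecast bins",
           call. = FALSE)
    }
    actual <- stats::setNames(
      tibble::as_tibble(actual)[, c("bin_start", acol)],
      c("bin_start", "actual"))
    factor <- mean(forecast$mean[match(actual$bin_start,
                                       forecast$bin_start)]) /
      mean(actual$actual)
    actual$scaled <- actual$actual * factor
  }

  p <- ggplot2::ggplot(forecast,
                       ggplot2::aes(x = .data$bin_start, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high,
                                      fill = "forecast CI"), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(color = "forecast"), linewidth = 0.8) +
    ggplot2::scale_fill_manual(NULL, values = c("forecast CI" = "steelblue")) +
    ggplot2::labs(
      x = sprintf("%d-weekly bins", attr(forecast, "width") %||%
                    spec$bin_width),
      y = "forecast births per bin",
      title = spec$title, subtitle = spec$subtitle
    ) +
    ggplot2::theme_minimal()
  colors <- c("forecast" = "steelblue")
  if (!is.null(actual)) {
    p <- p + ggplot2::geom_line(
      data = actual,
      ggplot2::aes(x = .data$bin_start, y = .data$scaled, color = "actual"),
      linewidth = 0.8)
    colors <- c(colors, "actual" = "firebrick")
    p <- p + ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / factor,
                                   name = "actual births per bin"))
  }
  if (spec$show_historical_average && !is.null(historical_average)) {
    p <- p + ggplot2::geom_line(
      data = historical_average,
      ggplot2::aes(x = .data$bin_start, y = .data$mean,
                   color = "historical average"),
      linetype = "dashed")
    colors <- c(colors, "historical average" = "grey40")
  }
  p <- p + ggplot2::scale_color_manual(NULL, values = colors)

  svg_file <- tempfile(fileext = ".svg")
  on.exit(unlink(svg_file), add = TRUE)
  grDevices::svg(svg_file, width = 9, height = 4.5)
  print(p)
  grDevices::dev.off()
  svg_markup <- paste(readr::read_lines(svg_file), collapse = "\n")
  # strip the XML prolog so the SVG inlines cleanly
  svg_markup <- sub("^<\\?xml[^>]*\\?>\\s*", "", svg_markup)
  svg_markup <- sub("^<!DOCTYPE[^>]*>\\s*", "", svg_markup)

  tbl_rows <- paste(sprintf(
    "<tr><td>%s</td><td>%.1f</td><td>%.1f</td><td>%.1f</td>%s</tr>",
    format(forecast$bin_start, "%Y-%m-%d"),
    forecast$mean, forecast$ci_low, forecast$ci_high,
    if (!is.null(actual)) {
      sprintf("<td>%s</td>",
              ifelse(forecast$bin_start %in% actual$bin_start,
                     format(actual$actual[match(forecast$bin_start,
                                                actual$bin_start)]),
                     ""))
    } else ""
  ), collapse = "\n")

  meta <- sprintf(
    "PMF: %s | replicates: %s | seed: %s | CI: %s%% | generated: %s",
    attr(forecast, "pmf_id") %||% "n/a",
    attr(forecast, "n_reps") %||% "n/a",
    attr(forecast, "seed") %||% "n/a",
    format(100 * spec$ci_level),
    format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))

  html <- glue::glue(
    '<!DOCTYPE html>
<html lang="en"><head><meta charset="utf-8">
<title>{spec$title}</title>
<style>
 body {{ font-family: system-ui, sans-serif; max-width: 70rem; margin: 2rem auto; }}
 table {{ border-collapse: collapse; margin-top: 1rem; }}
 td, th {{ border: 1px solid #ccc; padding: 0.25rem 0.6rem; text-align: right; }}
 footer {{ color: #666; font-size: 0.85rem; margin-top: 1.5rem; }}
</style></head>
<body>
<h1>{spec$title}</h1>
<figure>{svg_markup}</figure>
{if (!is.na(factor)) sprintf(
  "<p>Actual births are shown normalized onto the forecast axis (factor %.4f); the right axis gives the original scale.</p>",
  factor) else ""}
<table>
<tr><th>bin start</th><th>forecast mean</th><th>CI low</th><th>CI high</th>{if (!is.null(actual)) "<th>actual</th>" else ""}</tr>
{tbl_rows}
</table>
<footer>{meta}</footer>
</body></html>')
  writeLines(html, path)
  invisible(path)
}
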