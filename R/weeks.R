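#' ISO-8601 week helpers
#'
#' All weekly series in birthcast are keyed by the Monday (`week_start`) of an
#' ISO-8601 week. These helpers convert between calendar dates, ISO
#' year/week labels, and week-start Mondays. Week arithmetic throughout the
#' package is plain date arithmetic in multiples of 7 days, which is immune
#' to the year-boundary pitfalls of (year, week) pairs.
#'
#' @param iso_year,iso_week Integer vectors of ISO year and week number.
#' @param date A `Date` vector.
#' @return `iso_week_start()` returns the `Date` of the Monday of the given
#'   ISO week; `week_start_of()` returns the Monday of the ISO week
#'   containing `date`.
#' @examples
#' iso_week_start(2015, 1)      # "2014-12-29"
#' week_start_of(as.Date("2016-01-01"))
#' @name iso-weeks
NULL

#' @rdname iso-weeks
#' @export
iso_week_start <- function(iso_year, iso_week) {
  stopifnot(length(iso_year) == length(iso_week) || length(iso_year) == 1L ||
              length(iso_week) == 1L)
  # Jan 4 always falls in ISO week 1 of its year.
  jan4 <- as.Date(sprintf("%d-01-04", iso_year))
  wd <- lubridate::wday(jan4, week_start = 1) # Monday = 1
  monday_w1 <- jan4 - (wd - 1L)
  monday_w1 + (iso_week - 1L) * 7L
}

#' @rdname iso-weeks
#' @export
week_start_of <- function(date) {
  date <- as.Date(date)
  wd <- lubridate::wday(date, week_start = 1)
  date - (wd - 1L)
}

# Attach iso_year / iso_week label columns for a week_start column.
add_iso_labels <- function(df) {
  dplyr::mutate(df,
    iso_year = lubridate::isoyear(.data$week_start),
    iso_week = lubridate::isoweek(.data$week_start),
    .before = "week_start"
  )
}

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
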