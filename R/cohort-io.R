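#' Read and write pregnancy screening records
#'
#' A pregnancy record is one screening registration: an opaque pregnancy id,
#' the mother's municipality, and the expected date of birth as recorded on
#' the first-trimester (booking-blood) lab order form. The file format is
#' comma-delimited UTF-8 text with required header
#' `pregnancy_id,municipality,expected_birth_date` and ISO-8601
#' (`YYYY-MM-DD`) dates.
#'
#' Municipality labels are whitespace-trimmed and matched case-sensitively.
#' Duplicate pregnancy ids and unparseable dates are errors that name the
#' offending id/row, since silently dropping records would bias the weekly
#' counts the forecast is built on.
#'
#' @param path File path.
#' @param municipality_filter Optional character vector; when given, records
#'   from other municipalities are dropped (e.g. the output of
#'   [filter_by_coverage()]).
#' @param quiet Suppress the record-count message.
#' @return A tibble with columns `pregnancy_id` (character), `municipality`
#'   (character), `expected_birth_date` (Date).
#' @export
read_pregnancy_records <- function(path, municipality_filter = NULL,
                                   quiet = TRUE) {
  if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    pregnancy_id = readr::col_character(),
    municipality = readr::col_character(),
    expected_birth_date = readr::col_character()
  ))
  need <- c("pregnancy_id", "municipality", "expected_birth_date")
  if (!all(need %in% names(df))) {
    stop("records file must have header ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df <- dplyr::mutate(df, municipality = trimws(.data$municipality))
  dates <- as.Date(df$expected_birth_date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    stop(sprintf("unparseable expected_birth_date at data row %d: '%s'",
                 bad, df$expected_birth_date[bad]), call. = FALSE)
  }
  df$expected_birth_date <- dates
  dup <- df$pregnancy_id[duplicated(df$pregnancy_id)]
  if (length(dup) > 0) {
    stop("duplicate pregnancy_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  n_read <- nrow(df)
  if (!is.null(municipality_filter)) {
    df <- dplyr::filter(df, .data$municipality %in% municipality_filter)
  }
  if (!quiet) {
    message(sprintf("read %d pregnancy records (%d after municipality filter)",
                    n_read, nrow(df)))
  }
  df
}

#' @rdname read_pregnancy_records
#' @param records A tibble of pregnancy records.
#' @export
write_pregnancy_records <- function(records, path) {
  stopifnot(all(c("pregnancy_id", "municipality", "expected_birth_date")
                %in% names(records)))
  out <- dplyr::mutate(
    records[, c("pregnancy_id", "municipality", "expected_birth_date")],
    expected_birth_date = format(as.Date(.data$expected_birth_date), "%Y-%m-%d")
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write registry birth-count tables
#'
#' Two delimited-text layouts are accepted: weekly counts with header
#' `municipality,iso_year,iso_week,births`, or annual counts with header
#' `municipality,year,births` (annual tables are sufficient for the
#' coverage filter, which pools counts over the study period).
#'
#' @param path File path.
#' @return A tibble mirroring the file columns, with a `granularity`
#'   attribute of `"weekly"` or `"annual"`.
#' @export
read_birth_counts <- function(path) {
  if (!file.exists(path)) stop("birth-count file not found: ", path, call. = FALSE)
  hdr <- strsplit(readr::read_lines(path, n_max = 1), ",")[[1]]
  if (identical(hdr, c("municipality", "iso_year", "iso_week", "births"))) {
    df <- readr::read_csv(path, col_types = "ciii")
    attr(df, "granularity") <- "weekly"
  } else if (identical(hdr, c("municipality", "year", "births"))) {
    df <- readr::read_csv(path, col_types = "cii")
    attr(df, "granularity") <- "annual"
  } else {
    stop("unrecognized birth-count header: ", paste(hdr, collapse = ","),
         call. = FALSE)
  }
  df$municipality <- trimws(df$municipality)
  if (any(df$births < 0)) stop("negative birth counts in ", path, call. = FALSE)
  df
}

#' @rdname read_birth_counts
#' @param counts A tibble of weekly or annual birth counts.
#' @export
write_birth_counts <- function(counts, path) {
  readr::write_csv(counts, path)
  invisible(path)
}

#' Municipality coverage of the screening provider
#'
#' For each municipality, coverage is the percentage of registry-reported
#' births for which the screening provider holds a registered due date:
#' `100 * expected_count / actual_count`, rounded half-away-from-zero to an
#' integer. Coverage can exceed 100% because mothers may deliver in a
#' hospital outside their home municipality, which moves the birth's
#' registered municipality. Municipalities whose coverage falls below the
#' threshold are excluded from forecasting so that the modelled population
#' is representative.
#'
#' @param expected A tibble with columns `municipality` and `n` (pooled
#'   count of provider-registered due dates), e.g.
#'   `dplyr::count(records, municipality)`.
#' @param actual A tibble with columns `municipality` and `n` (pooled
#'   registry birth count). Every municipality in `expected` must appear.
#' @param threshold_pct Inclusion threshold in percent (default 55, i.e.
#'   at least 55% of births covered).
#' @return A tibble with one row per municipality in `expected`, ordered by
#'   label: `municipality`, `expected_count`, `actual_count`,
#'   `coverage_pct` (integer), `included` (logical).
#' @examples
#' expected <- tibble::tibble(municipality = "A", n = 367)
#' actual   <- tibble::tibble(municipality = "A", n = 536)
#' compute_coverage(expected, actual)   # coverage_pct 68
#' @export
compute_coverage <- function(expected, actual, threshold_pct = 55) {
  stopifnot(all(c("municipality", "n") %in% names(expected)),
            all(c("municipality", "n") %in% names(actual)))
  expected <- dplyr::mutate(expected, municipality = trimws(.data$municipality))
  actual   <- dplyr::mutate(actual,   municipality = trimws(.data$municipality))
  missing <- setdiff(expected$municipality, actual$municipality)
  if (length(missing) > 0) {
    stop("municipalities missing from actual counts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- expected |>
    dplyr::rename(expected_count = "n") |>
    dplyr::left_join(
      dplyr::summarise(actual, actual_count = sum(.data$n),
                       .by = "municipality"),
      by = "municipality"
    ) |>
    dplyr::arrange(.data$municipality)
  if (any(out$actual_count == 0)) {
    stop("actual birth count is zero for: ",
         paste(out$municipality[out$actual_count == 0], collapse = ", "),
         " (coverage percentage undefined)", call. = FALSE)
  }
  out |>
    dplyr::mutate(
      coverage_pct = as.integer(
        round_half_away(100 * .data$expected_count / .data$actual_count)),
      included = .data$coverage_pct >= threshold_pct
    )
}

#' @rdname compute_coverage
#' @param coverage A coverage tibble from [compute_coverage()].
#' @return `filter_by_coverage()` returns the character vector of included
#'   municipality labels.
#' @export
filter_by_coverage <- function(coverage, threshold_pct = 55) {
  stopifnot("coverage_pct" %in% names(coverage))
  sort(coverage$municipality[coverage$coverage_pct >= threshold_pct])
}

#' Aggregate due dates to weekly counts
#'
#' Assigns each record to the ISO-8601 week (Monday start) containing its
#' expected birth date and counts records per week. Weeks with no records
#' are simply absent from the output (downstream code treats gaps as zero);
#' the total of the counts always equals the number of input records.
#'
#' @param records A tibble of pregnancy records (see
#'   [read_pregnancy_records()]).
#' @return A tibble with columns `iso_year`, `iso_week`, `week_start`
#'   (Monday `Date`), `n`, ordered by week.
#' @export
aggregate_expected_by_week <- function(records) {
  stopifnot("expected_birth_date" %in% names(records))
  if (nrow(records) == 0L) {
    return(tibble::tibble(iso_year = integer(), iso_week = integer(),
                          week_start = as.Date(character()), n = integer()))
  }
  records |>
    dplyr::mutate(week_start = week_start_of(.data$expected_birth_date)) |>
    dplyr::count(.data$week_start) |>
    dplyr::arrange(.data$week_start) |>
    add_iso_labels()
}

#' Bundled example coverage counts for the greater Utrecht region
#'
#' Pooled per-municipality counts for the 14 municipalities of the greater
#' Utrecht study region: provider-registered expected dates of birth
#' (2014–2019 screening registrations) against registry-reported births
#' (2015–2017). Useful for demonstrating [compute_coverage()] and
#' [filter_by_coverage()] on real published aggregates.
#'
#' @return A list with tibbles `expected` and `actual`, each with columns
#'   `municipality` and `n`.
#' @export
utrecht_region_counts <- function() {
  path <- system.file("extdata", "utrecht_municipality_counts.csv",
                      package = "birthcast")
  df <- readr::read_csv(path, col_types = "cii")
  list(
    expected = tibble::tibble(municipality = df$municipality, n = df$expected_n),
    actual   = tibble::tibble(municipality = df$municipality, n = df$actual_n)
  )
}
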