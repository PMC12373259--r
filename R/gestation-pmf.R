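#' Discrete gestational-length offset distributions
#'
#' A gestational offset is the difference, in whole weeks, between the week a
#' birth actually occurs and the week of the expected date of birth (the due
#' date, anchored at gestational week 40). Offsets are negative for preterm
#' deliveries; the default support is −17 to +5 weeks, i.e. deliveries from
#' gestational week 23 through 45. The forecasting engine redistributes
#' weekly due-date counts over surrounding weeks according to such a
#' probability mass function (PMF).
#'
#' `gestation_pmf()` validates and constructs a PMF from offset/probability
#' vectors. Probabilities must already sum to 1: deviations below `1e-9`
#' (floating-point dust) are silently renormalized, anything larger is an
#' error, so that a mistyped distribution file cannot pass unnoticed.
#'
#' @param offsets Integer vector of week offsets (birth week minus
#'   expected-date week). Must be distinct; stored in increasing order.
#' @param probs Numeric vector of probabilities, same length as `offsets`,
#'   non-negative, summing to 1 within `1e-9`.
#' @param pmf_id Character label recorded in forecast provenance so outputs
#'   state which distribution produced them.
#' @return A tibble of class `gestation_pmf` with columns `offset_weeks` and
#'   `probability`, ordered by offset, and a `pmf_id` attribute.
#' @examples
#' pmf <- gestation_pmf(-1:1, c(0.2, 0.5, 0.3))
#' pmf_mean(pmf)
#' @export
gestation_pmf <- function(offsets, probs, pmf_id = "user") {
  if (length(offsets) != length(probs)) {
    stop("`offsets` and `probs` must have the same length", call. = FALSE)
  }
  if (length(offsets) == 0L) stop("PMF must have at least one offset", call. = FALSE)
  offsets <- as.integer(offsets)
  if (anyNA(offsets) || anyNA(probs)) stop("PMF contains missing values", call. = FALSE)
  if (anyDuplicated(offsets)) {
    stop("duplicate offsets in PMF: ",
         paste(unique(offsets[duplicated(offsets)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(probs < 0)) stop("probabilities must be non-negative", call. = FALSE)
  s <- sum(probs)
  if (abs(s - 1) >= 1e-9) {
    stop(sprintf("probabilities sum to %.12f, not 1 (tolerance 1e-9)", s),
         call. = FALSE)
  }
  ord <- order(offsets)
  out <- tibble::tibble(
    offset_weeks = offsets[ord],
    probability  = probs[ord] / s
  )
  attr(out, "pmf_id") <- pmf_id
  class(out) <- c("gestation_pmf", class(out))
  out
}

#' @export
print.gestation_pmf <- function(x, ...) {
  cat(sprintf("<gestation_pmf '%s': %d offsets on [%d, %d], mean %.3f wk>\n",
              pmf_id(x), nrow(x), min(x$offset_weeks), max(x$offset_weeks),
              pmf_mean(x)))
  NextMethod()
}

#' @rdname gestation_pmf
#' @param pmf A `gestation_pmf` object.
#' @export
pmf_mean <- function(pmf) sum(pmf$offset_weeks * pmf$probability)

#' @rdname gestation_pmf
#' @export
pmf_id <- function(pmf) attr(pmf, "pmf_id") %||% "unknown"

#' Synthetic stand-in gestational offset distribution
#'
#' The Dutch national perinatal registry publishes the gestational-length
#' distribution used operationally, but its week-by-week values are not
#' openly redistributable, so birthcast ships a clearly labelled synthetic
#' stand-in: a left-skewed discrete distribution on offsets −17..+5 with its
#' mode at 0 (delivery in the due-date week), roughly 7% of mass below −3
#' (preterm, before week 37) and a thin post-term tail, matching the broad
#' shape of national gestational-age statistics. Any analysis can override
#' it with a registry-derived file via [read_gestation_pmf()]; forecast
#' provenance records which PMF was used.
#'
#' @return A `gestation_pmf` with `pmf_id = "synthetic-standin-v1"`.
#' @examples
#' synthetic_gestation_pmf()
#' @export
synthetic_gestation_pmf <- function() {
  # offsets -17..+5 <=> gestational weeks 23..45 at delivery
  probs <- c(
    0.0004, 0.0005, 0.0006, 0.0008, 0.0010,   # weeks 23-27, extreme preterm
    0.0014, 0.0018, 0.0025, 0.0035, 0.0050,   # weeks 28-32
    0.0080, 0.0130, 0.0220, 0.0400,           # weeks 33-36, moderate/late preterm
    0.0800, 0.1500, 0.2200, 0.2400, 0.1700,   # weeks 37-41, term bulk
    0.0350, 0.0038, 0.0005, 0.0002            # weeks 42-45, post-term tail
  )
  gestation_pmf(-17:5, probs, pmf_id = "synthetic-standin-v1")
}

#' Read / write a gestational offset PMF file
#'
#' The on-disk format is a comma-delimited text file with header
#' `offset_weeks,probability`, integer offsets, and decimal probabilities
#' summing to 1. This is the interchange format for registry-derived
#' distributions.
#'
#' @param path File path.
#' @param pmf_id Label for provenance; defaults to the file name.
#' @return `read_gestation_pmf()` returns a [gestation_pmf];
#'   `write_gestation_pmf()` returns `path` invisibly.
#' @export
read_gestation_pmf <- function(path, pmf_id = basename(path)) {
  if (!file.exists(path)) stop("PMF file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    offset_weeks = readr::col_integer(),
    probability  = readr::col_double()
  ))
  gestation_pmf(df$offset_weeks, df$probability, pmf_id = pmf_id)
}

#' @rdname read_gestation_pmf
#' @param pmf A `gestation_pmf`.
#' @export
write_gestation_pmf <- function(pmf, path) {
  readr::write_csv(tibble::as_tibble(pmf)[, c("offset_weeks", "probability")],
                   path)
  invisible(path)
}

#' Sample week offsets from a gestational PMF
#'
#' Draws `n` independent offsets. Used by the synthetic cohort generator;
#' the Monte Carlo forecaster uses equivalent multinomial tallies for speed.
#' Sampling is deterministic under a fixed RNG state (`set.seed()`).
#'
#' @param pmf A [gestation_pmf].
#' @param n Number of draws (non-negative integer).
#' @return Integer vector of length `n`.
#' @examples
#' set.seed(1)
#' sample_offsets(synthetic_gestation_pmf(), 5)
#' @export
sample_offsets <- function(pmf, n) {
  stopifnot(n >= 0)
  if (n == 0L) return(integer(0))
  sample(pmf$offset_weeks, size = n, replace = TRUE, prob = pmf$probability)
}

#' @export
autoplot.gestation_pmf <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$offset_weeks, y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "offset (birth week − expected-date week)",
      y = "probability",
      title = sprintf("Gestational offset distribution (%s)", pmf_id(object))
    ) +
    ggplot2::theme_minimal()
}
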