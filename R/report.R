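#' Five-number summaries per treatment series
#'
#' For every (genus, response, varied factor) treatment series, computes
#' the box-plot statistics: minimum, lower quartile, median, upper
#' quartile, maximum. Quartiles use linear interpolation between order
#' statistics (the default `stats::quantile()` type 7 convention).
#'
#' @param table A non-empty experiment table.
#' @param responses Response columns to summarize.
#' @return Tibble: `genus`, `response`, `varied_factor`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
summarize_by_series <- function(table, responses = response_names()) {
  if (nrow(table) == 0) stop("table must be non-empty", call. = FALSE)
  long <- tidyr::pivot_longer(
    table[c("genus", "varied_factor", responses)],
    dplyr::all_of(responses), names_to = "response", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$genus, .data$response, .data$varied_factor),
    min = min(.data$value),
    q1 = stats::quantile(.data$value, 0.25, names = FALSE),
    median = stats::median(.data$value),
    q3 = stats::quantile(.data$value, 0.75, names = FALSE),
    max = max(.data$value),
    .groups = "drop"
  )
  out
}

#' Pearson correlation matrix of numeric factors and responses
#'
#' Correlations among the four numeric cultivation factors and the nine
#' responses (the categorical light colour is excluded). The matrix is
#' symmetric with unit diagonal; a zero-variance column yields `NA` entries
#' (flagged with a warning) rather than a silent drop.
#'
#' @param table An experiment table with at least 3 rows.
#' @return Symmetric numeric matrix with factor and response rows/columns.
#' @export
correlation_matrix <- function(table) {
  if (nrow(table) < 3) stop("need at least 3 rows", call. = FALSE)
  cols <- c("co2_pct", "temperature_C", "light_intensity_lux", "pH",
            response_names())
  x <- as.matrix(table[cols])
  sds <- apply(x, 2, stats::sd)
  flat <- sds < .Machine$double.eps
  if (any(flat)) {
    warning("zero-variance column(s): ", paste(cols[flat], collapse = ", "),
            "; their correlations are NA", call. = FALSE)
  }
  cm <- suppressWarnings(stats::cor(x))
  cm[flat, ] <- NA_real_
  cm[, flat] <- NA_real_
  diag(cm) <- ifelse(flat, NA_real_, 1)
  cm
}
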