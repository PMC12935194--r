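#' Summarise per-report completeness scores
#'
#' The dataset-level description of a scored line listing: mean and SD
#' (n-1 denominator) of the per-report mean scores, median with IQR (25th
#' and 75th percentiles), range, the number and percentage of well-documented
#' reports (mean score >= 0.8), and the histogram of the number of distinct
#' combination-score values per report in the bins 1 (one value calculated,
#' or no difference between values), 2, 3, 4, and 5 or more.
#'
#' @param reports Per-report tibble from [score_reports()] (or the `reports`
#'   element of a [score_linelisting()] result).
#' @return A list of class `vigi_summary` with elements `stats` (one-row
#'   tibble) and `distinct_values` (five-row tibble of histogram bins).
#' @export
summarize_scores <- function(reports) {
  if (inherits(reports, "vigi_scores")) {
    reports <- reports$reports
  }
  if (!is.data.frame(reports) || nrow(reports) == 0) {
    stop("Cannot summarise an empty report-score set.", call. = FALSE)
  }
  x <- reports$mean_score
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  stats <- tibble::tibble(
    n_reports = nrow(reports),
    mean = mean(x),
    sd = stats::sd(x),
    median = q[2],
    iqr_lower = q[1],
    iqr_upper = q[3],
    min = min(x),
    max = max(x),
    n_well_documented = sum(reports$well_documented),
    pct_well_documented = 100 * sum(reports$well_documented) / nrow(reports)
  )
  bin <- cut(
    pmin(reports$n_distinct_scores, 5L),
    breaks = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5),
    labels = c("1", "2", "3", "4", ">=5")
  )
  counts <- as.integer(table(bin))
  distinct_values <- tibble::tibble(
    n_distinct = c("1", "2", "3", "4", ">=5"),
    n_reports = counts,
    pct_reports = 100 * counts / nrow(reports)
  )
  structure(
    list(stats = stats, distinct_values = distinct_values),
    class = "vigi_summary"
  )
}

#' @export
print.vigi_summary <- function(x, ...) {
  s <- x$stats
  cat("<vigi_summary> ", s$n_reports, " report(s)\n", sep = "")
  cat(sprintf("  mean (SD): %.2f (+/- %.2f)\n", s$mean, s$sd))
  cat(sprintf(
    "  median [IQR]: %.2f [%.2f - %.2f]\n",
    s$median, s$iqr_lower, s$iqr_upper
  ))
  cat(sprintf("  range: %.2f - %.2f\n", s$min, s$max))
  cat(sprintf(
    "  well-documented (>= 0.8): %d (%.1f%%)\n",
    s$n_well_documented, s$pct_well_documented
  ))
  cat("  distinct score values per report:\n")
  for (i in seq_len(nrow(x$distinct_values))) {
    cat(sprintf(
      "    %-3s %6d (%.1f%%)\n",
      x$distinct_values$n_distinct[i],
      x$distinct_values$n_reports[i],
      x$distinct_values$pct_reports[i]
    ))
  }
  invisible(x)
}

#' @rdname summarize_scores
#' @param x A `vigi_summary`.
#' @param ... Unused.
#' @export
glance.vigi_summary <- function(x, ...) x$stats

#' @rdname summarize_scores
#' @export
tidy.vigi_summary <- function(x, ...) x$distinct_values

#' Plot the per-report score distribution
#'
#' Violin-and-box view of the per-report mean completeness scores with the
#' well-documented threshold (0.8) marked.
#'
#' @param object A `vigi_scores` result or per-report tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vigi_scores <- function(object, ...) {
  reports <- object$reports
  ggplot2::ggplot(reports, ggplot2::aes(x = "", y = .data$mean_score)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::geom_boxplot(width = 0.12, outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dotted", colour = "red") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Completeness score (per-report mean)",
      title = "Per-report completeness scores",
      subtitle = "Dotted line: well-documented threshold (0.8)"
    ) +
    ggplot2::theme_minimal()
}
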