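#' Intraclass correlation between two score sets
#'
#' Agreement between two scorings of the same reports, computed from the
#' two-way ANOVA mean squares of the reports-by-raters table. The default
#' form is ICC(2,1): two-way random effects, absolute agreement, single
#' measurement — the natural model for the same reports scored by two
#' systems, where a constant shift between systems counts against agreement.
#' ICC(3,1) (two-way mixed, consistency) is available for sensitivity
#' analysis. The confidence interval uses the standard F-distribution bounds
#' for the chosen form.
#'
#' @param x,y Numeric vectors of paired scores (same reports, same order).
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @param conf_level Confidence level for the interval, default 0.95.
#' @return A one-row tibble: `estimate`, `conf_low`, `conf_high`, `type`,
#'   `n`. When the table is fully degenerate (no variance anywhere) the
#'   estimate and interval are `NA` with `type = "undefined"`.
#' @examples
#' compute_icc(c(0.2, 0.5, 0.8, 0.9), c(0.25, 0.45, 0.8, 0.95))
#' @export
compute_icc <- function(x, y, type = c("agreement", "consistency"),
                        conf_level = 0.95) {
  type <- match.arg(type)
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) {
    stop("ICC needs at least 3 complete pairs.", call. = FALSE)
  }
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  ss_total <- sum((dat - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  if (ss_total < 1e-14) {
    return(tibble::tibble(
      estimate = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
      type = "undefined", n = n
    ))
  }

  alpha <- 1 - conf_level
  if (type == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse < 1e-14) {
      return(tibble::tibble(
        estimate = 1, conf_low = 1, conf_high = 1,
        type = "ICC(3,1) consistency", n = n
      ))
    }
    f_obs <- msr / mse
    f_low <- f_obs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_up <- f_obs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((f_low - 1) / (f_low + k - 1), (f_up - 1) / (f_up + k - 1))
    return(tibble::tibble(
      estimate = est, conf_low = ci[1], conf_high = ci[2],
      type = "ICC(3,1) consistency", n = n
    ))
  }

  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (mse < 1e-14 && msc < 1e-14) {
    # the two columns are identical: perfect absolute agreement
    return(tibble::tibble(
      estimate = 1, conf_low = 1, conf_high = 1,
      type = "ICC(2,1) agreement", n = n
    ))
  }
  # Satterthwaite degrees of freedom for the CI of ICC(2,1)
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_star <- stats::qf(1 - alpha / 2, n - 1, v)
  lower <- n * (msr - f_star * mse) /
    (f_star * (k * msc + (k * n - k - n) * mse) + n * msr)
  f_star2 <- stats::qf(1 - alpha / 2, v, n - 1)
  upper <- n * (f_star2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_star2 * msr)
  tibble::tibble(
    estimate = est,
    conf_low = min(lower, est),
    conf_high = max(upper, est),
    type = "ICC(2,1) agreement", n = n
  )
}

#' Compare per-report scores against a reference score set
#'
#' Pairs each report's score (mean by default, best score optionally) with a
#' reference score for the same report, computes the differences
#' (own - reference) with their mean/SD and median/IQR, the intraclass
#' correlation with its confidence interval, and flags reports whose
#' difference reaches the deviation threshold (inclusive, both directions;
#' default 0.3). Reports present on only one side are excluded from pairing
#' and reported via a message.
#'
#' @param own Per-report tibble from [score_reports()], or a `vigi_scores`
#'   result.
#' @param reference A data frame with columns `report_id` and `score` (extra
#'   columns ignored), or a named numeric vector keyed by report id.
#' @param use_best Compare the best (maximum) combination score per report
#'   instead of the mean.
#' @param threshold Absolute deviation at which a report is flagged,
#'   inclusive. Default 0.3.
#' @param icc_type Passed to [compute_icc()].
#' @return A list of class `score_comparison`: `pairs` (per-report tibble
#'   with `own`, `reference`, `difference`, `flagged`, `direction`),
#'   `stats` (one-row summary tibble including the ICC), `icc`, `threshold`,
#'   `score_used`.
#' @export
compare_scores <- function(own, reference, use_best = FALSE, threshold = 0.3,
                           icc_type = "agreement") {
  if (inherits(own, "vigi_scores")) {
    own <- own$reports
  }
  if (is.numeric(reference) && !is.null(names(reference))) {
    reference <- tibble::tibble(report_id = names(reference), score = unname(reference))
  }
  stopifnot(is.data.frame(reference), all(c("report_id", "score") %in% colnames(reference)))
  if (threshold <= 0) {
    stop("Deviation threshold must be positive.", call. = FALSE)
  }
  score_col <- if (use_best) "best_score" else "mean_score"

  pairs <- dplyr::inner_join(
    dplyr::select(own, "report_id", own = dplyr::all_of(score_col)),
    dplyr::select(reference, "report_id", reference = "score"),
    by = "report_id"
  )
  n_unmatched <- nrow(own) - nrow(pairs) + nrow(reference) - nrow(pairs)
  if (nrow(pairs) == 0) {
    stop("No report ids shared between the two score sets.", call. = FALSE)
  }
  if (n_unmatched > 0) {
    message(n_unmatched, " report(s) present on only one side; excluded from pairing.")
  }
  pairs <- pairs |>
    dplyr::mutate(
      difference = .data$own - .data$reference,
      flagged = .data$difference >= threshold | .data$difference <= -threshold,
      direction = dplyr::case_when(
        !.data$flagged ~ "none",
        .data$difference > 0 ~ "positive",
        TRUE ~ "negative"
      )
    )
  icc <- if (nrow(pairs) >= 3) {
    compute_icc(pairs$own, pairs$reference, type = icc_type)
  } else {
    tibble::tibble(
      estimate = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
      type = "undefined (fewer than 3 pairs)", n = nrow(pairs)
    )
  }
  q <- stats::quantile(pairs$difference, c(0.25, 0.5, 0.75), names = FALSE)
  stats <- tibble::tibble(
    n_pairs = nrow(pairs),
    mean_difference = mean(pairs$difference),
    sd_difference = stats::sd(pairs$difference),
    median_difference = q[2],
    iqr_lower = q[1],
    iqr_upper = q[3],
    n_flagged = sum(pairs$flagged),
    pct_flagged = 100 * sum(pairs$flagged) / nrow(pairs),
    n_exact_agreement = sum(pairs$difference == 0),
    icc = !!icc$estimate,
    icc_conf_low = !!icc$conf_low,
    icc_conf_high = !!icc$conf_high
  )
  structure(
    list(
      pairs = pairs, stats = stats, icc = icc,
      threshold = threshold,
      score_used = if (use_best) "best" else "mean"
    ),
    class = "score_comparison"
  )
}

#' @export
print.score_comparison <- function(x, ...) {
  s <- x$stats
  cat(
    "<score_comparison> ", s$n_pairs, " paired report(s), ",
    x$score_used, " score vs reference\n",
    sep = ""
  )
  cat(sprintf(
    "  difference mean (SD): %.3f (+/- %.3f); median [IQR]: %.2f [%.2f - %.2f]\n",
    s$mean_difference, s$sd_difference, s$median_difference,
    s$iqr_lower, s$iqr_upper
  ))
  cat(sprintf(
    "  ICC: %.3f [%.3f - %.3f] (%s)\n",
    s$icc, s$icc_conf_low, s$icc_conf_high, x$icc$type
  ))
  cat(sprintf(
    "  flagged (|difference| >= %.2f): %d (%.1f%%)\n",
    x$threshold, s$n_flagged, s$pct_flagged
  ))
  invisible(x)
}

#' @rdname compare_scores
#' @param x A `score_comparison`.
#' @param ... Unused.
#' @export
tidy.score_comparison <- function(x, ...) x$pairs

#' @rdname compare_scores
#' @export
glance.score_comparison <- function(x, ...) x$stats

#' Plot the distribution of score differences
#'
#' Bar chart of per-report differences (own - reference) binned at 0.1,
#' with the deviation thresholds marked.
#'
#' @param object A `score_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_comparison <- function(object, ...) {
  pairs <- object$pairs |>
    dplyr::mutate(bin = round(.data$difference, 1))
  thr <- object$threshold
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::geom_vline(
      xintercept = c(-thr, thr),
      linetype = "dotted", colour = "red"
    ) +
    ggplot2::labs(
      x = "Difference (own - reference)", y = "Reports",
      title = "Differences between score sets",
      subtitle = sprintf("Dotted lines: deviation threshold +/- %.1f", thr)
    ) +
    ggplot2::theme_minimal()
}
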