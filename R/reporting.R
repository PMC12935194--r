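round2 <- function(x) round(x, 2)

#' Score a line listing and write the export documents
#'
#' The file-producing front end of the scoring pipeline. Three csv documents
#' are written to `out_dir`:
#' \describe{
#'   \item{`full_calculation_per_reaction_drug.csv`}{one row per ADR-drug
#'     combination with all ten presence flags, the time to onset, the exact
#'     score (`score_exact`) and the 2-decimal display score (`score`).}
#'   \item{`per_report.csv`}{one row per report: mean and best score (exact
#'     and 2-decimal display), number of combinations, number of distinct
#'     score values, well-documented flag.}
#'   \item{`dataset_summary.csv`}{the dataset statistics (mean/SD,
#'     median/IQR, range, well-documented count and percentage, distinct-
#'     value histogram) as metric/value rows.}
#' }
#' Display columns are rounded to 2 decimals; exact columns keep full
#' precision so downstream averaging never accumulates rounding. Outputs are
#' byte-identical across re-runs on identical input.
#'
#' @param input Path to a line listing (csv or xlsx), or a listing tibble.
#' @param out_dir Output directory (created if needed).
#' @param config A [vigi_config()].
#' @param format,delim,sheet Passed to [read_line_listing()] when `input`
#'   is a path.
#' @param keep_vaccines Skip the vaccine-report removal.
#' @return The `vigi_scores` result, invisibly; paths written are attached
#'   as attribute `paths`.
#' @export
run_score <- function(input, out_dir, config = vigi_config(),
                      format = "auto", delim = ",", sheet = 1,
                      keep_vaccines = FALSE) {
  listing <- if (is.character(input)) {
    read_line_listing(input, format = format, delim = delim, sheet = sheet)
  } else {
    tibble::as_tibble(input)
  }
  scores <- score_linelisting(listing, config, keep_vaccines = keep_vaccines)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  combos_out <- scores$combinations |>
    dplyr::mutate(score_exact = .data$score, score = round2(.data$score)) |>
    dplyr::select(
      "report_id", "drug_name", "drug_role", "reaction_term",
      dplyr::all_of(score_categories()), "tto_days", "score", "score_exact"
    )
  reports_out <- scores$reports |>
    dplyr::transmute(
      report_id = .data$report_id,
      mean_score_exact = .data$mean_score,
      best_score_exact = .data$best_score,
      mean_score = round2(.data$mean_score_exact),
      best_score = round2(.data$best_score_exact),
      n_combinations = .data$n_combinations,
      n_distinct_scores = .data$n_distinct_scores,
      well_documented = .data$well_documented
    )
  summary <- summarize_scores(scores$reports)
  summary_out <- dplyr::bind_rows(
    tidyr::pivot_longer(summary$stats, dplyr::everything(),
      names_to = "metric", values_to = "value"
    ),
    summary$distinct_values |>
      dplyr::transmute(
        metric = paste0("n_reports_distinct_", .data$n_distinct),
        value = as.numeric(.data$n_reports)
      ),
    summary$distinct_values |>
      dplyr::transmute(
        metric = paste0("pct_reports_distinct_", .data$n_distinct),
        value = .data$pct_reports
      )
  )

  paths <- file.path(out_dir, c(
    "full_calculation_per_reaction_drug.csv", "per_report.csv",
    "dataset_summary.csv"
  ))
  readr::write_csv(combos_out, paths[1])
  readr::write_csv(reports_out, paths[2])
  readr::write_csv(summary_out, paths[3])
  attr(scores, "paths") <- paths
  invisible(scores)
}

#' Generate a synthetic line listing and write it with its ground truth
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param basename File stem for the outputs.
#' @return The `synth_linelisting`, invisibly; paths written attached as
#'   attribute `paths`.
#' @export
run_simulate <- function(out_dir, config = synth_config(), seed = 1L,
                         basename = "synthetic") {
  sim <- generate_linelisting(config, seed = seed)
  paths <- write_synthetic(sim, out_dir, basename = basename)
  attr(sim, "paths") <- paths
  invisible(sim)
}

#' Compare scored output against a reference score set and write the results
#'
#' Reads the per-report scores written by [run_score()] and a two-column
#' reference csv (`report_id`, `score`), runs [compare_scores()], and writes
#' `differences.csv` (per paired report), `comparison_summary.csv`
#' (difference statistics and ICC with CI), and `flagged.csv` (reports at or
#' beyond the deviation threshold, with category attribution when presence
#' tables for both sides are supplied).
#'
#' @param scores Path to a `per_report.csv` from [run_score()], or a
#'   per-report tibble / `vigi_scores` result.
#' @param reference Path to a csv with columns `report_id` and `score`, or
#'   an equivalent data frame.
#' @param out_dir Output directory (created if needed).
#' @param use_best,threshold,icc_type Passed to [compare_scores()].
#' @param own_presence,reference_presence Optional presence tables (paths or
#'   tibbles with `report_id`, `drug_name`, `reaction_term` and the ten
#'   category columns) enabling [attribute_discrepancies()] on the flagged
#'   reports.
#' @param mask Categories excluded from attribution, see
#'   [attribute_discrepancies()].
#' @return The `score_comparison`, invisibly; attribution (if computed)
#'   attached as attribute `attribution`, paths as attribute `paths`.
#' @export
run_compare <- function(scores, reference, out_dir,
                        use_best = FALSE, threshold = 0.3,
                        icc_type = "agreement",
                        own_presence = NULL, reference_presence = NULL,
                        mask = character(0)) {
  read_tbl <- function(x, what) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        stop("Cannot read ", what, ", file does not exist: ", x, call. = FALSE)
      }
      readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
    } else {
      x
    }
  }
  own <- read_tbl(scores, "scored output")
  if (inherits(own, "vigi_scores")) {
    own <- own$reports
  }
  # per_report.csv carries rounded display columns plus exact columns
  if ("mean_score_exact" %in% colnames(own)) {
    own <- dplyr::mutate(own,
      mean_score = .data$mean_score_exact,
      best_score = .data$best_score_exact
    )
  }
  reference <- read_tbl(reference, "reference scores")
  comparison <- compare_scores(own, reference,
    use_best = use_best,
    threshold = threshold, icc_type = icc_type
  )

  attribution <- NULL
  flagged_out <- comparison$pairs |> dplyr::filter(.data$flagged)
  if (!is.null(own_presence) && !is.null(reference_presence)) {
    attribution <- attribute_discrepancies(
      comparison,
      read_tbl(own_presence, "own presence table"),
      read_tbl(reference_presence, "reference presence table"),
      mask = mask
    )
    flagged_out <- dplyr::left_join(flagged_out, attribution$reports,
      by = "report_id"
    )
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c(
    "differences.csv", "comparison_summary.csv", "flagged.csv"
  ))
  readr::write_csv(comparison$pairs, paths[1])
  readr::write_csv(
    tidyr::pivot_longer(comparison$stats, dplyr::everything(),
      names_to = "metric", values_to = "value"
    ),
    paths[2]
  )
  readr::write_csv(flagged_out, paths[3])
  attr(comparison, "attribution") <- attribution
  attr(comparison, "paths") <- paths
  invisible(comparison)
}
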