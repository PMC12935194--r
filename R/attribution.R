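#' Attribute flagged score deviations to information categories
#'
#' For each flagged report, works out which presence/absence judgements
#' differ between the own scoring and the reference scoring, and at which
#' level. Report-level categories (sex, age, country, primary reporter,
#' report type, comments) are compared first; if any differs, the report is
#' attributed at report level with those categories. Only when the report
#' level is clean are the combination-level categories (time to onset,
#' indication, outcome, dose) compared per ADR-drug combination, attributing
#' at ADR-drug level. Reports without reference presence data are reported
#' as unattributable, never an error.
#'
#' @param flagged Character vector of flagged report ids, or a
#'   [compare_scores()] result (its flagged reports are used).
#' @param own_presence,reference_presence Tibbles with columns `report_id`,
#'   `drug_name`, `reaction_term` and the ten logical category columns of
#'   [score_categories()] — e.g. the `combinations` element of a
#'   [score_linelisting()] result, or a ground-truth/reference combination
#'   table.
#' @param mask Categories excluded from the comparison, e.g. `"comments"`
#'   when the reference system has no narrative fields. Default: none.
#' @return A list of class `discrepancy_attribution`: `reports` (one row per
#'   flagged report: `report_id`, `level` in
#'   report/adr_drug/none_found/unattributable, `categories` collapsed to a
#'   comma-separated string), and `category_counts` (rows of `level`,
#'   `category`, `n_reports`).
#' @export
attribute_discrepancies <- function(flagged, own_presence, reference_presence,
                                    mask = character(0)) {
  if (inherits(flagged, "score_comparison")) {
    flagged <- flagged$pairs$report_id[flagged$pairs$flagged]
  }
  flagged <- unique(as.character(flagged))
  bad <- setdiff(mask, score_categories())
  if (length(bad) > 0) {
    stop("Unknown categories in mask: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  needed <- c("report_id", "drug_name", "reaction_term", score_categories())
  for (nm in c("own_presence", "reference_presence")) {
    df <- get(nm)
    if (!all(needed %in% colnames(df))) {
      stop(nm, " must carry columns: ", paste(needed, collapse = ", "),
        call. = FALSE
      )
    }
  }
  rep_cats <- setdiff(report_level_categories(), mask)
  com_cats <- setdiff(combination_level_categories(), mask)

  one_report <- function(id) {
    own <- dplyr::filter(own_presence, .data$report_id == id)
    ref <- dplyr::filter(reference_presence, .data$report_id == id)
    if (nrow(ref) == 0 || nrow(own) == 0) {
      return(tibble::tibble(report_id = id, level = "unattributable", categories = ""))
    }
    # report-level flags are constant within a report; any() collapses them
    rep_mismatch <- rep_cats[purrr::map_lgl(
      rep_cats,
      \(cat) any(own[[cat]]) != any(ref[[cat]])
    )]
    if (length(rep_mismatch) > 0) {
      return(tibble::tibble(
        report_id = id, level = "report",
        categories = paste(rep_mismatch, collapse = ",")
      ))
    }
    joined <- dplyr::inner_join(
      own, ref,
      by = c("report_id", "drug_name", "reaction_term"),
      suffix = c("_own", "_ref")
    )
    if (nrow(joined) == 0) {
      return(tibble::tibble(report_id = id, level = "unattributable", categories = ""))
    }
    com_mismatch <- com_cats[purrr::map_lgl(
      com_cats,
      \(cat) any(joined[[paste0(cat, "_own")]] != joined[[paste0(cat, "_ref")]])
    )]
    if (length(com_mismatch) > 0) {
      return(tibble::tibble(
        report_id = id, level = "adr_drug",
        categories = paste(com_mismatch, collapse = ",")
      ))
    }
    tibble::tibble(report_id = id, level = "none_found", categories = "")
  }

  reports <- purrr::map(flagged, one_report) |> purrr::list_rbind()
  if (nrow(reports) == 0) {
    reports <- tibble::tibble(
      report_id = character(), level = character(), categories = character()
    )
  }
  category_counts <- reports |>
    dplyr::filter(.data$categories != "") |>
    tidyr::separate_rows("categories", sep = ",") |>
    dplyr::count(.data$level, category = .data$categories, name = "n_reports") |>
    dplyr::arrange(.data$level, dplyr::desc(.data$n_reports))
  structure(
    list(reports = reports, category_counts = category_counts),
    class = "discrepancy_attribution"
  )
}

#' @export
print.discrepancy_attribution <- function(x, ...) {
  cat(
    "<discrepancy_attribution> ", nrow(x$reports), " flagged report(s): ",
    sum(x$reports$level == "report"), " report-level, ",
    sum(x$reports$level == "adr_drug"), " ADR-drug-level, ",
    sum(x$reports$level == "none_found"), " without presence difference, ",
    sum(x$reports$level == "unattributable"), " unattributable\n",
    sep = ""
  )
  if (nrow(x$category_counts) > 0) {
    print(x$category_counts, ...)
  }
  invisible(x)
}

#' @rdname attribute_discrepancies
#' @param x A `discrepancy_attribution`.
#' @param ... Unused.
#' @export
tidy.discrepancy_attribution <- function(x, ...) x$reports

#' @rdname attribute_discrepancies
#' @export
glance.discrepancy_attribution <- function(x, ...) {
  tibble::tibble(
    n_flagged = nrow(x$reports),
    n_report_level = sum(x$reports$level == "report"),
    n_adr_drug_level = sum(x$reports$level == "adr_drug"),
    n_none_found = sum(x$reports$level == "none_found"),
    n_unattributable = sum(x$reports$level == "unattributable")
  )
}
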