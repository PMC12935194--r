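#' Time to onset in days
#'
#' Days from drug start to reaction start, defined only when both dates are
#' complete valid calendar dates and the difference is non-negative (a
#' reaction starting the same day counts: 0 days is available). Anything
#' else — a missing or partial date, or a reaction dated before the drug —
#' yields `NA` and downstream the 50% penalty.
#'
#' @param drug_start,reaction_start `Date` vectors (recycled to a common
#'   length).
#' @return Integer days, `NA` where not computable as `>= 0`.
#' @examples
#' compute_time_to_onset(as.Date("2020-01-01"), as.Date("2020-01-05"))
#' @export
compute_time_to_onset <- function(drug_start, reaction_start) {
  days <- as.integer(reaction_start - drug_start)
  days[is.na(days) | days < 0] <- NA_integer_
  days
}

#' Assess presence of the ten scored categories
#'
#' Applies the per-category decision rules to placeholder-normalised
#' combination records: time to onset is present iff computable as `>= 0`
#' whole days from complete dates; age iff a numeric age value is given (no
#' age-group fallback); dose iff the dose text contains at least one digit
#' (any unit counts); comments iff any of narrative, reporter's comment or
#' sender's comment was filled; the remaining categories iff the field is
#' non-missing.
#'
#' @param combinations Combination tibble from [expand_combinations()].
#' @return The input with ten logical presence columns (named as
#'   [score_categories()]) and a `tto_days` column appended. Where a
#'   category shares its name with a raw field (`sex`, `age`, `country`,
#'   `report_type`), the column becomes the logical presence flag.
#' @export
assess_presence <- function(combinations) {
  combinations |>
    dplyr::mutate(
      tto_days = compute_time_to_onset(.data$drug_start_date, .data$reaction_start_date),
      time_to_onset = !is.na(.data$tto_days),
      indication = !is.na(.data$indication_text),
      outcome = !is.na(.data$outcome_text),
      sex = !is.na(.data$sex),
      age = !is.na(.data$age),
      dose = !is.na(.data$dose_text) & stringr::str_detect(.data$dose_text, "\\d"),
      country = !is.na(.data$country),
      primary_reporter = !is.na(.data$reporter_qualification),
      report_type = !is.na(.data$report_type),
      comments = .data$narrative_present
    )
}

#' Score presence patterns
#'
#' The completeness score of one ADR-drug combination is the product over the
#' ten categories of `(1 - penalty)` for each absent category (present
#' categories contribute a factor of 1). It ranges from
#' `prod(1 - penalty_scheme())` = 0.0709 (all absent, printed 0.07) to 1.0
#' (all present).
#'
#' @param presence A logical matrix or data frame with the ten category
#'   columns of [score_categories()] (`TRUE` = information present).
#' @param scheme Penalty scheme, see [penalty_scheme()].
#' @return Numeric vector of scores in `[0.0709, 1]`.
#' @examples
#' all_absent <- as.data.frame(as.list(setNames(rep(FALSE, 10), score_categories())))
#' score_combination(all_absent)
#' @export
score_combination <- function(presence, scheme = penalty_scheme()) {
  scheme <- validate_penalty_scheme(scheme)
  absent <- !as.matrix(as.data.frame(presence)[, score_categories(), drop = FALSE])
  # sequential product in canonical category order (not exp-sum-log), so
  # scores are bit-identical to any straightforward product of the factors
  score <- rep(1, nrow(absent))
  for (i in seq_along(scheme)) {
    score <- score * (1 - scheme[[i]] * absent[, i])
  }
  as.numeric(score)
}

#' Score every ADR-drug combination of a record set
#'
#' Convenience layer over [assess_presence()] and [score_combination()]:
#' appends the presence flags, the time to onset, and the combination score.
#' Non-spontaneous report types are scored like any other (the type category
#' only asks whether a type is given) but are reported with a warning, since
#' the score is validated for spontaneous reports.
#'
#' @inheritParams assess_presence
#' @param scheme Penalty scheme, see [penalty_scheme()].
#' @return The combination tibble with presence columns and a `score` column.
#' @export
score_combinations <- function(combinations, scheme = penalty_scheme()) {
  # the raw report_type values are shadowed by the presence flag below,
  # so inspect them first
  types <- unique(combinations$report_type)
  odd <- types[!is.na(types) & !stringr::str_detect(tolower(types), "spontaneous")]
  if (length(odd) > 0) {
    warning(
      "Non-spontaneous report type value(s) present: ",
      paste(odd, collapse = ", "),
      ". The completeness score is validated for spontaneous reports.",
      call. = FALSE
    )
  }
  scored <- assess_presence(combinations)
  scored$score <- score_combination(
    scored[, score_categories(), drop = FALSE],
    scheme
  )
  scored
}

#' Remove vaccine and hyposensitisation reports
#'
#' Removal is at report level: when any drug of a report matches a term of
#' the list (case-insensitive substring on the drug name), every combination
#' of that report is removed. Removed report ids are reported via a message.
#'
#' @param combinations Combination tibble (scored or not).
#' @param terms Term list, see [default_vaccine_terms()]. An empty list
#'   leaves the input unchanged.
#' @return The combination tibble without the matching reports.
#' @export
exclude_vaccines <- function(combinations, terms = default_vaccine_terms()) {
  if (length(terms) == 0 || nrow(combinations) == 0) {
    return(combinations)
  }
  pattern <- paste0(
    stringr::str_replace_all(tolower(terms), "([.\\\\+*?\\[^\\]$(){}=!<>|:#-])", "\\\\\\1"),
    collapse = "|"
  )
  hit <- stringr::str_detect(tolower(combinations$drug_name), pattern)
  removed <- unique(combinations$report_id[hit])
  if (length(removed) > 0) {
    message(
      length(removed), " report(s) removed (vaccine/hyposensitisation): ",
      paste(utils::head(removed, 20), collapse = ", "),
      if (length(removed) > 20) ", ..." else ""
    )
  }
  dplyr::filter(combinations, !(.data$report_id %in% removed))
}

#' Aggregate combination scores to per-report scores
#'
#' Per report, over its suspected and interacting (never concomitant)
#' ADR-drug combinations: the arithmetic mean score, the best (maximum)
#' score, the number of combinations, the number of distinct score values
#' (after rounding to 2 decimals, the reporting precision), and whether the
#' report is well-documented (mean `>= 0.8`, inclusive). Reports whose
#' combinations are all concomitant cannot be scored and are dropped with a
#' warning.
#'
#' @param scored Combination tibble from [score_combinations()].
#' @return A tibble with one row per report: `report_id`, `mean_score`,
#'   `best_score`, `n_combinations`, `n_distinct_scores`, `well_documented`.
#' @export
score_reports <- function(scored) {
  stopifnot(nrow(scored) > 0)
  scoreable <- dplyr::filter(scored, .data$drug_role != "concomitant")
  dropped <- setdiff(unique(scored$report_id), unique(scoreable$report_id))
  if (length(dropped) > 0) {
    warning(
      length(dropped), " report(s) excluded (only concomitant drugs): ",
      paste(utils::head(dropped, 20), collapse = ", "),
      if (length(dropped) > 20) ", ..." else "",
      call. = FALSE
    )
  }
  scoreable |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(
      mean_score = mean(.data$score),
      best_score = max(.data$score),
      n_combinations = dplyr::n(),
      n_distinct_scores = dplyr::n_distinct(round(.data$score, 2)),
      .groups = "drop"
    ) |>
    dplyr::mutate(well_documented = .data$mean_score >= 0.8) |>
    dplyr::arrange(match(.data$report_id, unique(scored$report_id)))
}

#' Score a whole line listing
#'
#' The full pipeline: resolve columns by keyword, expand each report into its
#' ADR-drug combinations, remove vaccine/hyposensitisation reports, assess
#' the ten categories, apply the multiplicative penalties, and aggregate per
#' report. Exclusions are reported as messages/warnings, never silent.
#'
#' @param listing Line-listing tibble from [read_line_listing()] (or built
#'   in code).
#' @param config A [vigi_config()].
#' @param keep_vaccines If `TRUE`, skip the vaccine-report removal (the
#'   score is not validated for vaccine reports).
#' @return A list of class `vigi_scores` with elements `combinations`
#'   (per-combination tibble with presence flags and scores) and `reports`
#'   (per-report tibble from [score_reports()]).
#' @examples
#' listing <- tibble::tibble(
#'   `Worldwide Case Identification` = "EV-1",
#'   `Report Type` = "Spontaneous",
#'   `Primary Source Qualification` = "Physician",
#'   `Primary Source Country` = "DE",
#'   `Patient Sex` = "Female",
#'   `Patient Age Group/Age` = "34 Years",
#'   `Case Narrative` = "Reaction after first dose.",
#'   `Drug Name` = "Examplecillin",
#'   `Drug Role` = "Suspect",
#'   `Drug Start Date` = "01/01/2020",
#'   `Drug Dose` = "40 mg",
#'   `Drug Indication` = "Hypertension",
#'   `Reaction PT` = "Pyrexia",
#'   `Reaction Start Date` = "05/01/2020",
#'   `Reaction Outcome` = "Recovered"
#' )
#' score_linelisting(listing)$reports
#' @export
score_linelisting <- function(listing, config = vigi_config(),
                              keep_vaccines = FALSE) {
  cmap <- resolve_columns(listing, config$keywords)
  combos <- expand_combinations(listing, cmap, config)
  if (!keep_vaccines) {
    combos <- exclude_vaccines(combos, config$vaccine_terms)
  }
  if (nrow(combos) == 0) {
    stop("No scoreable reports remain after exclusions.", call. = FALSE)
  }
  scored <- score_combinations(combos, config$penalties)
  reports <- score_reports(scored)
  structure(
    list(combinations = scored, reports = reports),
    class = "vigi_scores"
  )
}

#' @export
print.vigi_scores <- function(x, ...) {
  cat(
    "<vigi_scores> ", nrow(x$reports), " report(s), ",
    nrow(x$combinations), " ADR-drug combination(s)\n",
    sep = ""
  )
  print(x$reports, ...)
  invisible(x)
}
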