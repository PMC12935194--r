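#' Scored information categories
#'
#' The ten information categories of the completeness score, in canonical
#' order. The first six are report-level (constant across the ADR-drug
#' combinations of one report in this dialect: sex, age, country, reporter,
#' report type, comments), the remaining four vary per ADR-drug combination
#' (time to onset, indication, outcome, dose).
#'
#' @return Character vector of the ten category names.
#' @export
score_categories <- function() {
  c(
    "time_to_onset", "indication", "outcome", "sex", "age",
    "dose", "country", "primary_reporter", "report_type", "comments"
  )
}

# categories compared at report level vs. ADR-drug level during attribution
report_level_categories <- function() {
  c("sex", "age", "country", "primary_reporter", "report_type", "comments")
}

combination_level_categories <- function() {
  c("time_to_onset", "indication", "outcome", "dose")
}

#' Default penalty scheme
#'
#' The multiplicative penalty fractions of the Vigi4Eudra completeness score:
#' absence of a category multiplies the score by `1 - penalty`. Time to onset
#' carries 50%; indication, outcome, sex and age carry 30%; dose, country,
#' primary reporter, report type and the narrative/comments carry 10%. With
#' every category absent the score bottoms out at
#' \eqn{\prod_i (1 - P_i) = 0.0709} (printed as 0.07); with everything present
#' it is 1.0.
#'
#' @param overrides Optional named numeric vector of penalty fractions to
#'   override, e.g. `c(age = 0.1)`. Overriding changes the meaning of the
#'   score and is reported with a message.
#' @return A named numeric vector of length ten, one penalty fraction per
#'   category of [score_categories()], each in (0, 1).
#' @examples
#' penalty_scheme()
#' prod(1 - penalty_scheme()) # score floor, 0.0709
#' @export
penalty_scheme <- function(overrides = NULL) {
  scheme <- c(
    time_to_onset = 0.50,
    indication = 0.30,
    outcome = 0.30,
    sex = 0.30,
    age = 0.30,
    dose = 0.10,
    country = 0.10,
    primary_reporter = 0.10,
    report_type = 0.10,
    comments = 0.10
  )
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), names(scheme))
    if (length(bad) > 0) {
      stop("Unknown penalty categories: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    scheme[names(overrides)] <- as.numeric(overrides)
    message(
      "Penalty scheme overridden for: ",
      paste(names(overrides), collapse = ", "),
      ". Scores are no longer comparable to the default Vigi4Eudra score."
    )
  }
  validate_penalty_scheme(scheme)
  scheme
}

validate_penalty_scheme <- function(scheme) {
  if (!is.numeric(scheme) || length(scheme) != 10L ||
    !setequal(names(scheme), score_categories())) {
    stop("A penalty scheme must be a named numeric vector with exactly the ",
      "ten categories of score_categories().",
      call. = FALSE
    )
  }
  if (any(scheme <= 0 | scheme >= 1)) {
    stop("Every penalty fraction must lie strictly between 0 and 1.",
      call. = FALSE
    )
  }
  invisible(scheme[score_categories()])
}
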