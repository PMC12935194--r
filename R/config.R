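#' Default column keyword map
#'
#' Line-listing exports are matched to semantic fields by case-insensitive
#' substring search on the column labels, so the reader survives minor
#' renamings as long as a keyword remains in the title. Each semantic field
#' lists its keywords in priority order; the field maps to the first column
#' whose label contains any of them.
#'
#' Required fields are `report_id`, `drug_names` and `reaction_terms`; all
#' others may be absent from a listing (they then score as missing).
#'
#' @return Named list of character vectors (semantic field -> keywords).
#' @export
default_keywords <- function() {
  list(
    report_id = c("case identification", "case number", "local number", "report id"),
    report_type = c("report type"),
    reporter_qualification = c("qualification", "primary source qual"),
    country = c("country"),
    sex = c("sex", "gender"),
    age = c("patient age", "age group/age"),
    narrative = c("narrative"),
    reporter_comment = c("reporter's comment", "reporter comment"),
    sender_comment = c("sender's comment", "sender comment"),
    drug_names = c("drug name", "substance name", "medicinal product"),
    drug_roles = c("drug role", "drug characteri"),
    drug_start_dates = c("drug start", "therapy start"),
    drug_doses = c("dose"),
    drug_indications = c("indication"),
    reaction_terms = c("reaction pt", "reaction term", "reaction meddra"),
    reaction_start_dates = c("reaction start", "onset date"),
    reaction_outcomes = c("outcome")
  )
}

required_fields <- function() c("report_id", "drug_names", "reaction_terms")

#' Default absence placeholders
#'
#' Strings that EudraVigilance-style listings use to mark an absent value.
#' Compared case-insensitively after trimming whitespace; the empty string
#' counts as absent.
#'
#' @return Character vector of placeholder strings.
#' @export
default_placeholders <- function() {
  c("not available", "not specified", "unknown", "")
}

#' Default vaccine / hyposensitisation term list
#'
#' Reports in which any drug name contains one of these terms (case-
#' insensitive substring) are removed before scoring: the score is validated
#' for drug reports only.
#'
#' @return Character vector of drug-name terms.
#' @export
default_vaccine_terms <- function() {
  c(
    "vaccine", "vaccin", "toxoid", "bcg", "hyposensiti",
    "allergen extract", "immunotherapy extract"
  )
}

#' Assemble a scoring configuration
#'
#' Bundles every tunable of the pipeline: column keywords, absence
#' placeholders, the penalty scheme, the vaccine term list and the
#' intra-cell separator used for multi-valued drug/reaction cells.
#'
#' @param keywords Named list of keyword vectors, see [default_keywords()].
#' @param placeholders Character vector, see [default_placeholders()].
#' @param penalties Named numeric vector, see [penalty_scheme()].
#' @param vaccine_terms Character vector, see [default_vaccine_terms()].
#' @param sep Separator between the values of a multi-valued cell. Defaults
#'   to a newline inside the cell; `"|"` is a common csv-friendly choice.
#' @return A list of class `vigi_config`.
#' @export
vigi_config <- function(keywords = default_keywords(),
                        placeholders = default_placeholders(),
                        penalties = penalty_scheme(),
                        vaccine_terms = default_vaccine_terms(),
                        sep = "\n") {
  validate_penalty_scheme(penalties)
  stopifnot(is.list(keywords), length(keywords) > 0)
  if (!all(required_fields() %in% names(keywords))) {
    stop("keywords must cover the required fields: ",
      paste(required_fields(), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      keywords = keywords,
      placeholders = placeholders,
      penalties = penalties[score_categories()],
      vaccine_terms = vaccine_terms,
      sep = sep
    ),
    class = "vigi_config"
  )
}

#' Read a scoring configuration from a YAML file
#'
#' Any of the keys `keywords`, `placeholders`, `penalties`, `vaccine_terms`
#' and `sep` may be present; absent keys fall back to the package defaults.
#' Keyword entries merge field-by-field over [default_keywords()], penalty
#' entries over [penalty_scheme()] (with a prominent message, since overriding
#' a penalty changes the score's meaning).
#'
#' @param path Path to a YAML file.
#' @return A `vigi_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("Configuration file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  kw <- default_keywords()
  if (!is.null(raw$keywords)) {
    for (field in names(raw$keywords)) {
      kw[[field]] <- as.character(unlist(raw$keywords[[field]]))
    }
  }
  penalties <- if (is.null(raw$penalties)) {
    penalty_scheme()
  } else {
    penalty_scheme(overrides = raw$penalties)
  }
  vigi_config(
    keywords = kw,
    placeholders = if (is.null(raw$placeholders)) default_placeholders() else as.character(unlist(raw$placeholders)),
    penalties = penalties,
    vaccine_terms = if (is.null(raw$vaccine_terms)) default_vaccine_terms() else as.character(unlist(raw$vaccine_terms)),
    sep = if (is.null(raw$sep)) "\n" else raw$sep
  )
}
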