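#' Configuration for the synthetic line-listing generator
#'
#' Defines the study conditions a generated listing emulates: how many
#' reports, how many drugs and reactions per report, the drug role mix, the
#' per-category probability that a piece of information is absent, how often
#' a report involves a vaccine-term drug, and how often an absent date shows
#' up as a partial (MM/YYYY or YYYY) string instead of a placeholder.
#'
#' Default missingness is chosen to put the expected combination score around
#' 0.44, in the range typical of spontaneous-report datasets; dates are drawn
#' so that whenever both the drug and the reaction carry a complete date the
#' time to onset is a non-negative number of days.
#'
#' @param n_reports Number of reports to generate.
#' @param missingness Named numeric vector over [score_categories()]:
#'   probability that the category's information is absent.
#' @param drugs_per_report,reactions_per_report Named probability vectors
#'   over counts (names are the counts, e.g. `c("1" = .6, "2" = .4)`).
#' @param role_mix Probabilities over `suspect`, `interacting`,
#'   `concomitant` for drugs after the first; the first drug of a report is
#'   always suspect (a valid spontaneous report carries at least one
#'   suspected drug).
#' @param vaccine_fraction Probability that a report contains a vaccine-term
#'   drug (such reports are removed by the scoring pipeline).
#' @param partial_date_fraction When a date is meant absent, probability it
#'   is emitted as a partial date string rather than a placeholder.
#' @param placeholder_style The placeholder string emitted for absent values.
#' @param date_start,date_end Window the drug start dates are drawn from.
#' @param sep Intra-cell separator for multi-valued cells.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_reports = 1000,
                         missingness = c(
                           time_to_onset = 0.55, indication = 0.45,
                           outcome = 0.30, sex = 0.10, age = 0.35,
                           dose = 0.40, country = 0.05,
                           primary_reporter = 0.10, report_type = 0.05,
                           comments = 0.50
                         ),
                         drugs_per_report = c(
                           "1" = 0.60, "2" = 0.20, "3" = 0.10,
                           "4" = 0.06, "5" = 0.04
                         ),
                         reactions_per_report = c(
                           "1" = 0.50, "2" = 0.30, "3" = 0.12,
                           "4" = 0.05, "5" = 0.03
                         ),
                         role_mix = c(
                           suspect = 0.75, interacting = 0.05,
                           concomitant = 0.20
                         ),
                         vaccine_fraction = 0.05,
                         partial_date_fraction = 0.30,
                         placeholder_style = "Not available",
                         date_start = as.Date("2019-01-01"),
                         date_end = as.Date("2021-12-31"),
                         sep = "\n") {
  fail <- function(field, why) {
    stop("Invalid synthetic configuration: ", field, " ", why, call. = FALSE)
  }
  if (!is.numeric(n_reports) || length(n_reports) != 1 || n_reports < 1) {
    fail("n_reports", "must be a positive integer")
  }
  if (!setequal(names(missingness), score_categories())) {
    fail("missingness", "must name all ten score categories")
  }
  missingness <- missingness[score_categories()]
  if (any(missingness < 0 | missingness > 1)) {
    fail("missingness", "probabilities must lie in [0, 1]")
  }
  check_dist <- function(p, field) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8 || is.null(names(p))) {
      fail(field, "must be a named probability vector summing to 1")
    }
  }
  check_dist(drugs_per_report, "drugs_per_report")
  check_dist(reactions_per_report, "reactions_per_report")
  if (!setequal(names(role_mix), c("suspect", "interacting", "concomitant"))) {
    fail("role_mix", "must name suspect, interacting, concomitant")
  }
  check_dist(role_mix, "role_mix")
  for (p in c(vaccine_fraction = vaccine_fraction, partial_date_fraction = partial_date_fraction)) {
    if (p < 0 || p > 1) fail("fraction", "probabilities must lie in [0, 1]")
  }
  if (date_end <= date_start) fail("date window", "must be non-empty")
  structure(
    list(
      n_reports = as.integer(n_reports),
      missingness = missingness,
      drugs_per_report = drugs_per_report,
      reactions_per_report = reactions_per_report,
      role_mix = role_mix[c("suspect", "interacting", "concomitant")],
      vaccine_fraction = vaccine_fraction,
      partial_date_fraction = partial_date_fraction,
      placeholder_style = placeholder_style,
      date_start = date_start,
      date_end = date_end,
      sep = sep
    ),
    class = "synth_config"
  )
}

synth_lexicon <- function() {
  list(
    drugs = c(
      "Examplecillin", "Fictramine", "Placebolol", "Nullaprofen",
      "Mockumab", "Synthax", "Demozolam", "Fauxparin", "Pseudomycin",
      "Imaginib"
    ),
    vaccines = c(
      "Synthovax influenza vaccine", "Demovax covid vaccine",
      "Hyposensitisation solution grass pollen"
    ),
    reactions = c(
      "Pyrexia", "Nausea", "Headache", "Rash", "Dizziness",
      "Anaphylactic reaction", "Vomiting", "Pruritus", "Fatigue",
      "Dyspnoea"
    ),
    indications = c(
      "Hypertension", "Pain", "Depression", "Asthma", "Epilepsy",
      "Infection", "Diabetes mellitus"
    ),
    outcomes = c(
      "Recovered", "Recovering", "Not recovered",
      "Recovered with sequelae", "Fatal"
    ),
    doses = c("40 mg", "10 mg", "500 mg", "2 tablets", "5 ml", "100 units"),
    countries = c("DE", "FR", "IT", "ES", "NL", "SE"),
    sexes = c("Female", "Male"),
    qualifications = c(
      "Physician", "Pharmacist", "Other health professional", "Consumer"
    )
  )
}

# penalties written out literally so ground-truth scores are computed
# independently of the scoring module
truth_score <- function(p) {
  (1 - 0.5 * !p$time_to_onset) *
    (1 - 0.3 * !p$indication) *
    (1 - 0.3 * !p$outcome) *
    (1 - 0.3 * !p$sex) *
    (1 - 0.3 * !p$age) *
    (1 - 0.1 * !p$dose) *
    (1 - 0.1 * !p$country) *
    (1 - 0.1 * !p$primary_reporter) *
    (1 - 0.1 * !p$report_type) *
    (1 - 0.1 * !p$comments)
}

truth_reports_from_combinations <- function(combos) {
  combos |>
    dplyr::filter(.data$drug_role != "concomitant") |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(
      true_mean_score = mean(.data$true_score),
      true_best_score = max(.data$true_score),
      n_combinations = dplyr::n(),
      vaccine = any(.data$vaccine),
      .groups = "drop"
    )
}

#' Generate a synthetic line listing with ground truth
#'
#' Emits a listing in the documented EudraVigilance-style dialect together
#' with a per-combination ground truth (the true presence flags and the true
#' score, computed by an inline product independent of the scoring module)
#' and a per-report ground truth (true mean and best score over
#' non-concomitant combinations, vaccine flag). A given configuration and
#' seed always reproduce the identical listing.
#'
#' Time to onset presence is realised through the dates: each drug and each
#' reaction independently carries a complete DD/MM/YYYY date with probability
#' `sqrt(1 - missingness["time_to_onset"])`, so a combination has a
#' computable onset (both dates complete, reaction on or after drug start)
#' with probability `1 - missingness["time_to_onset"]`. Absent dates are
#' emitted as partial strings (MM/YYYY or YYYY) with
#' `partial_date_fraction`, else as the placeholder, and count as onset
#' absent in the ground truth either way.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; all randomness of the run derives from it.
#' @return A list of class `synth_linelisting`: `listing` (tibble in the
#'   line-listing dialect), `truth` (list with `combinations` and `reports`
#'   tibbles), `config`, `seed`.
#' @export
generate_linelisting <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  lex <- synth_lexicon()
  ph <- config$placeholder_style
  m <- config$missingness
  p_date_good <- sqrt(1 - m[["time_to_onset"]])

  partial_or_placeholder <- function(date) {
    if (stats::runif(1) < config$partial_date_fraction) {
      if (stats::runif(1) < 0.5) format(date, "%m/%Y") else format(date, "%Y")
    } else {
      ph
    }
  }

  one_report <- function(r) {
    id <- sprintf("EV-%06d", r)
    n_drug <- as.integer(sample(
      names(config$drugs_per_report), 1,
      prob = config$drugs_per_report
    ))
    n_reac <- as.integer(sample(
      names(config$reactions_per_report), 1,
      prob = config$reactions_per_report
    ))
    vaccine <- stats::runif(1) < config$vaccine_fraction

    roles <- c(
      "Suspect",
      if (n_drug > 1) {
        sample(c("Suspect", "Interacting", "Concomitant"), n_drug - 1,
          replace = TRUE, prob = config$role_mix
        )
      }
    )
    drug_names <- sample(lex$drugs, n_drug, replace = n_drug > length(lex$drugs))
    if (vaccine) {
      drug_names[1] <- sample(lex$vaccines, 1)
    }

    # report-level presence draws
    present <- stats::setNames(
      stats::runif(6) >= m[report_level_categories()],
      report_level_categories()
    )

    # per-drug and per-reaction draws
    ind_present <- stats::runif(n_drug) >= m[["indication"]]
    dose_present <- stats::runif(n_drug) >= m[["dose"]]
    drug_date_good <- stats::runif(n_drug) < p_date_good
    out_present <- stats::runif(n_reac) >= m[["outcome"]]
    reac_date_good <- stats::runif(n_reac) < p_date_good

    window <- as.integer(config$date_end - config$date_start) - 90L
    drug_dates <- config$date_start +
      sample.int(max(window, 1L), n_drug, replace = TRUE) - 1L
    reac_dates <- max(drug_dates) + sample.int(60L, n_reac, replace = TRUE) - 1L

    drug_date_cell <- purrr::map_chr(seq_len(n_drug), function(d) {
      if (drug_date_good[d]) {
        format(drug_dates[d], "%d/%m/%Y")
      } else {
        partial_or_placeholder(drug_dates[d])
      }
    })
    reac_date_cell <- purrr::map_chr(seq_len(n_reac), function(j) {
      if (reac_date_good[j]) {
        format(reac_dates[j], "%d/%m/%Y")
      } else {
        partial_or_placeholder(reac_dates[j])
      }
    })

    reac_terms <- sample(lex$reactions, n_reac, replace = n_reac > length(lex$reactions))
    age_years <- sample(1:90, 1)

    sep <- config$sep
    row <- tibble::tibble(
      `Worldwide Unique Case Identification Number` = id,
      `Report Type` = if (present[["report_type"]]) "Spontaneous" else ph,
      `Primary Source Qualification` = if (present[["primary_reporter"]]) sample(lex$qualifications, 1) else ph,
      `Primary Source Country` = if (present[["country"]]) sample(lex$countries, 1) else ph,
      `Patient Sex` = if (present[["sex"]]) sample(lex$sexes, 1) else ph,
      `Patient Age Group/Age` = if (present[["age"]]) paste(age_years, "Years") else ph,
      `Case Narrative` = if (present[["comments"]]) "Patient developed the reported reaction after drug intake." else ph,
      `Reporter's Comment` = ph,
      `Sender's Comment` = ph,
      `Drug Name` = paste(drug_names, collapse = sep),
      `Drug Role` = paste(roles, collapse = sep),
      `Drug Start Date` = paste(drug_date_cell, collapse = sep),
      `Drug Dose` = paste(
        ifelse(dose_present, sample(lex$doses, n_drug, replace = TRUE), ph),
        collapse = sep
      ),
      `Drug Indication` = paste(
        ifelse(ind_present, sample(lex$indications, n_drug, replace = TRUE), ph),
        collapse = sep
      ),
      `Reaction PT` = paste(reac_terms, collapse = sep),
      `Reaction Start Date` = paste(reac_date_cell, collapse = sep),
      `Reaction Outcome` = paste(
        ifelse(out_present, sample(lex$outcomes, n_reac, replace = TRUE), ph),
        collapse = sep
      )
    )

    truth <- tidyr::crossing(
      drug_index = seq_len(n_drug),
      reaction_index = seq_len(n_reac)
    ) |>
      dplyr::mutate(
        report_id = id,
        drug_name = drug_names[.data$drug_index],
        drug_role = tolower(roles[.data$drug_index]),
        reaction_term = reac_terms[.data$reaction_index],
        time_to_onset = drug_date_good[.data$drug_index] & reac_date_good[.data$reaction_index],
        indication = ind_present[.data$drug_index],
        outcome = out_present[.data$reaction_index],
        sex = present[["sex"]],
        age = present[["age"]],
        dose = dose_present[.data$drug_index],
        country = present[["country"]],
        primary_reporter = present[["primary_reporter"]],
        report_type = present[["report_type"]],
        comments = present[["comments"]],
        vaccine = vaccine
      )
    truth$true_score <- truth_score(truth)
    list(row = row, truth = truth)
  }

  parts <- purrr::map(seq_len(config$n_reports), one_report)
  listing <- purrr::list_rbind(purrr::map(parts, "row"))
  combos <- purrr::list_rbind(purrr::map(parts, "truth")) |>
    dplyr::select(
      "report_id", "drug_index", "drug_name", "drug_role",
      "reaction_index", "reaction_term",
      dplyr::all_of(score_categories()), "true_score", "vaccine"
    )
  structure(
    list(
      listing = listing,
      truth = list(
        combinations = combos,
        reports = truth_reports_from_combinations(combos)
      ),
      config = config,
      seed = as.integer(seed)
    ),
    class = "synth_linelisting"
  )
}

#' @export
print.synth_linelisting <- function(x, ...) {
  cat(
    "<synth_linelisting> ", nrow(x$listing), " report(s), ",
    nrow(x$truth$combinations), " ADR-drug combination(s), seed ",
    x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Perturb a ground truth into a synthetic reference score set
#'
#' Produces a "reference" scoring of the same reports that differs from the
#' generated truth in known categories, for exercising score comparison and
#' discrepancy attribution. Report-level categories (sex, age, country,
#' reporter, report type, comments) are flipped per report — consistently
#' across the report's combinations, as a second scoring system would see
#' them — while combination-level categories (time to onset, indication,
#' outcome, dose) are flipped per combination. Reference scores are
#' recomputed with the same independent inline product the generator uses.
#'
#' @param truth A `synth_linelisting` or its `truth` list.
#' @param flip Named numeric vector: per-category probability of flipping
#'   that category's presence in the reference copy. Categories not named
#'   are never flipped.
#' @param seed Integer seed for the flip draws.
#' @return A list of class `synth_reference`: `combinations` and `reports`
#'   tibbles shaped like the truth (scores in `true_score` etc.), and
#'   `flips`, a tibble of the flips applied (`report_id`, `drug_name`,
#'   `reaction_term`, `category`).
#' @export
perturb_reference <- function(truth, flip = numeric(0), seed = 1L) {
  if (inherits(truth, "synth_linelisting")) {
    truth <- truth$truth
  }
  combos <- truth$combinations
  bad <- setdiff(names(flip), score_categories())
  if (length(bad) > 0) {
    stop("Unknown categories in flip: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(flip < 0 | flip > 1)) {
    stop("Flip probabilities must lie in [0, 1].", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  flips <- list()
  report_ids <- unique(combos$report_id)
  for (cat in names(flip)) {
    p <- flip[[cat]]
    if (p == 0) next
    if (cat %in% report_level_categories()) {
      hit_reports <- report_ids[stats::runif(length(report_ids)) < p]
      hit <- combos$report_id %in% hit_reports
    } else {
      hit <- stats::runif(nrow(combos)) < p
    }
    if (any(hit)) {
      combos[[cat]][hit] <- !combos[[cat]][hit]
      flips[[cat]] <- combos[hit, c("report_id", "drug_name", "reaction_term")] |>
        dplyr::mutate(category = cat)
    }
  }
  combos$true_score <- truth_score(combos)
  structure(
    list(
      combinations = combos,
      reports = truth_reports_from_combinations(combos),
      flips = if (length(flips) > 0) {
        purrr::list_rbind(unname(flips))
      } else {
        tibble::tibble(
          report_id = character(), drug_name = character(),
          reaction_term = character(), category = character()
        )
      }
    ),
    class = "synth_reference"
  )
}

#' Write a synthetic listing and its ground truth to csv
#'
#' The listing goes to `<basename>.csv` in the line-listing dialect; the
#' ground truth sidecars go to `<basename>_truth_combinations.csv` (keyed by
#' report id + drug name + reaction term) and `<basename>_truth_reports.csv`.
#'
#' @param sim A `synth_linelisting`.
#' @param dir Output directory (created if needed).
#' @param basename File stem, default `"synthetic"`.
#' @return Character vector of the paths written, invisibly.
#' @export
write_synthetic <- function(sim, dir, basename = "synthetic") {
  stopifnot(inherits(sim, "synth_linelisting"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(
    basename,
    c(".csv", "_truth_combinations.csv", "_truth_reports.csv")
  ))
  write_line_listing(sim$listing, paths[1])
  readr::write_csv(sim$truth$combinations, paths[2])
  readr::write_csv(sim$truth$reports, paths[3])
  invisible(paths)
}
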