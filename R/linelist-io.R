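#' Read a line listing
#'
#' Reads an EudraVigilance-style line listing — one row per ADR report, one
#' column per information category — from csv or xlsx. Cells are returned as
#' raw character strings; no placeholder normalisation happens here, so a
#' written-and-reread listing reproduces every cell exactly.
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"xlsx"`, or `"auto"` (default: decide from the
#'   file extension, falling back to csv).
#' @param delim Field delimiter for csv input (default comma).
#' @param sheet Sheet for xlsx input (default: first sheet).
#' @return A tibble of character columns; column labels preserved verbatim.
#' @export
read_line_listing <- function(path, format = c("auto", "csv", "xlsx"),
                              delim = ",", sheet = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("Cannot read line listing, file does not exist: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  listing <- if (format == "xlsx") {
    readxl::read_excel(path, sheet = sheet, col_types = "text")
  } else {
    readr::read_delim(
      path,
      delim = delim,
      col_types = readr::cols(.default = readr::col_character()),
      na = character(), # keep "" and "NA" as literal cell content
      progress = FALSE,
      show_col_types = FALSE
    )
  }
  listing <- tibble::as_tibble(listing)
  if (ncol(listing) == 0 || nrow(listing) == 0) {
    stop("Line listing is empty (no data rows): ", path, call. = FALSE)
  }
  # xlsx empty cells come back NA; align with the csv reader's ""
  listing <- dplyr::mutate(listing, dplyr::across(
    dplyr::everything(),
    \(x) dplyr::coalesce(as.character(x), "")
  ))
  attr(listing, "source_format") <- format
  listing
}

#' Write a line listing to csv
#'
#' The inverse of [read_line_listing()] for the csv dialect: every cell is
#' written verbatim so the round trip is exact.
#'
#' @param listing A line-listing tibble.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_line_listing <- function(listing, path, delim = ",") {
  readr::write_delim(listing, path, delim = delim, na = "")
  invisible(path)
}

#' Resolve line-listing columns to semantic fields
#'
#' Maps each semantic field (report id, sex, drug names, ...) to the first
#' column whose label contains one of the field's keywords, matched
#' case-insensitively as substrings. This keeps the reader working across
#' minor header renamings. Fields with no matching column are recorded as
#' unmapped unless required.
#'
#' @param listing A line-listing tibble from [read_line_listing()].
#' @param keywords Named list of keyword vectors, see [default_keywords()].
#' @return Named character vector (semantic field -> column label); unmapped
#'   optional fields are `NA`.
#' @export
resolve_columns <- function(listing, keywords = default_keywords()) {
  stopifnot(is.list(keywords), length(keywords) > 0)
  labels <- colnames(listing)
  labels_lc <- tolower(labels)
  cmap <- purrr::map_chr(keywords, function(kws) {
    for (kw in tolower(kws)) {
      hit <- which(stringr::str_detect(labels_lc, stringr::fixed(kw)))
      if (length(hit) > 0) {
        return(labels[hit[1]])
      }
    }
    NA_character_
  })
  missing_req <- intersect(required_fields(), names(cmap)[is.na(cmap)])
  if (length(missing_req) > 0) {
    stop(
      "No column found for required field(s) ",
      paste(missing_req, collapse = ", "),
      ". Available column labels: ", paste(labels, collapse = "; "),
      call. = FALSE
    )
  }
  dup <- cmap[!is.na(cmap)][duplicated(cmap[!is.na(cmap)])]
  if (length(dup) > 0) {
    clashes <- purrr::map_chr(unique(dup), function(lbl) {
      flds <- names(cmap)[!is.na(cmap) & cmap == lbl]
      paste0("'", lbl, "' matched by ", paste(flds, collapse = " and "))
    })
    stop("Ambiguous column mapping: ", paste(clashes, collapse = "; "),
      call. = FALSE
    )
  }
  cmap
}

#' Normalise absence placeholders
#'
#' Turns placeholder strings ("not available", "not specified", "unknown",
#' empty) into `NA` and trims whitespace from everything else. Comparison is
#' case-insensitive after trimming. Total function: never errors.
#'
#' @param x Character vector of raw cell values.
#' @param placeholders Placeholder strings, see [default_placeholders()].
#' @return Character vector with placeholders replaced by `NA`.
#' @examples
#' normalize_missing(c("Not Available", "  Pyrexia ", "unknown"))
#' @export
normalize_missing <- function(x, placeholders = default_placeholders()) {
  x <- stringr::str_trim(as.character(x))
  x[is.na(x) | tolower(x) %in% tolower(stringr::str_trim(placeholders))] <- NA_character_
  x
}

#' Parse a strict DD/MM/YYYY date
#'
#' Returns a `Date` only for complete, calendar-valid DD/MM/YYYY strings.
#' Partial dates (MM/YYYY, YYYY), impossible dates (31/02/2021), placeholders
#' and anything else come back `NA`: the time to onset can be computed
#' precisely or not at all.
#'
#' @param x Character vector.
#' @return `Date` vector, `NA` where the string is not a complete valid date.
#' @examples
#' parse_date(c("05/01/2020", "01/2020", "31/02/2021"))
#' @export
parse_date <- function(x) {
  x <- stringr::str_trim(as.character(x))
  out <- rep(as.Date(NA), length(x))
  shaped <- !is.na(x) & stringr::str_detect(x, "^\\d{2}/\\d{2}/\\d{4}$")
  if (any(shaped)) {
    parsed <- as.Date(x[shaped], format = "%d/%m/%Y")
    # as.Date tolerates some impossible dates by rolling over on some
    # platforms; re-format to confirm the round trip
    ok <- !is.na(parsed) & format(parsed, "%d/%m/%Y") == x[shaped]
    parsed[!ok] <- NA
    out[shaped] <- parsed
  }
  out
}

parse_drug_role <- function(x) {
  role <- dplyr::case_when(
    is.na(x) ~ NA_character_,
    stringr::str_detect(tolower(x), "interact") ~ "interacting",
    stringr::str_detect(tolower(x), "concomitant|not suspect") ~ "concomitant",
    stringr::str_detect(tolower(x), "suspect") ~ "suspect",
    TRUE ~ "unrecognised"
  )
  n_bad <- sum(role %in% "unrecognised")
  if (n_bad > 0) {
    warning(
      n_bad, " drug role value(s) not recognised (e.g. '",
      x[role == "unrecognised"][1],
      "'); treated as suspect so they are scored.",
      call. = FALSE
    )
  }
  # a missing or unrecognised role is scored: conservative default
  role[is.na(role) | role == "unrecognised"] <- "suspect"
  role
}

split_multi <- function(cell, sep) {
  if (is.na(cell)) {
    return(character(0))
  }
  stringr::str_split_1(cell, stringr::fixed(sep))
}

pad_to <- function(x, n, report_id, what) {
  if (length(x) > n) {
    return(x[seq_len(n)])
  }
  if (length(x) < n && length(x) > 0) {
    warning(
      "Report ", report_id, ": ", what, " list has ", length(x),
      " value(s) for ", n, " entries; padding with missing.",
      call. = FALSE
    )
  }
  c(x, rep(NA_character_, n - length(x)))
}

extract_numeric_age <- function(x) {
  num <- stringr::str_extract(x, "\\d+(\\.\\d+)?")
  suppressWarnings(as.numeric(num))
}

#' Expand a line listing into ADR-drug combination records
#'
#' The unit of the completeness score is one (drug, reaction) pair. Each
#' report row is split on the configured intra-cell separator into its drug
#' and reaction lists (per-drug and per-reaction attribute lists are aligned
#' positionally), placeholders are normalised away, and the Cartesian product
#' of drugs x reactions is emitted, each record carrying the report-level
#' fields. Attribute lists shorter than their drug/reaction list are padded
#' with missing values (with a warning); drug entries are never dropped.
#' Reports with no parseable drug or reaction are skipped with a warning.
#'
#' @param listing A line-listing tibble.
#' @param cmap Column map from [resolve_columns()].
#' @param config A [vigi_config()] (placeholders and separator are taken from
#'   it).
#' @return A tibble with one row per ADR-drug combination: identifiers,
#'   per-drug fields (`drug_name`, `drug_role`, `drug_start_date`,
#'   `dose_text`, `indication_text`), per-reaction fields (`reaction_term`,
#'   `reaction_start_date`, `outcome_text`), report-level fields (`sex`,
#'   `age`, `country`, `reporter_qualification`, `report_type`,
#'   `narrative_present`). Dates are parsed `Date`s (`NA` unless complete
#'   valid DD/MM/YYYY); `age` is the numeric age (`NA` when no numeric value
#'   is given).
#' @export
expand_combinations <- function(listing, cmap = resolve_columns(listing),
                                config = vigi_config()) {
  ph <- config$placeholders
  sep <- config$sep

  col <- function(row, field) {
    lbl <- cmap[[field]]
    if (is.null(lbl) || is.na(lbl)) {
      return(NA_character_)
    }
    as.character(row[[lbl]])
  }

  ids <- normalize_missing(listing[[cmap[["report_id"]]]], ph)
  if (anyNA(ids)) {
    stop("Line listing has rows with a missing report identifier.", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(
      "Duplicate report identifier(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }

  one_report <- function(i) {
    row <- listing[i, ]
    id <- ids[i]

    drugs_raw <- purrr::map(
      c("drug_names", "drug_roles", "drug_start_dates", "drug_doses", "drug_indications"),
      \(f) split_multi(normalize_missing(col(row, f), ph)[1], sep)
    )
    names(drugs_raw) <- c("name", "role", "start", "dose", "indication")
    keep <- !is.na(normalize_missing(drugs_raw$name, ph))
    n_drug <- sum(keep)
    if (n_drug == 0) {
      warning("Report ", id, " has no parseable drug; skipped.", call. = FALSE)
      return(NULL)
    }
    n_slots <- length(drugs_raw$name)
    drugs <- tibble::tibble(
      drug_name = normalize_missing(drugs_raw$name, ph)[keep],
      drug_role_raw = normalize_missing(pad_to(drugs_raw$role, n_slots, id, "drug role"), ph)[keep],
      drug_start_raw = normalize_missing(pad_to(drugs_raw$start, n_slots, id, "drug start date"), ph)[keep],
      dose_text = normalize_missing(pad_to(drugs_raw$dose, n_slots, id, "dose"), ph)[keep],
      indication_text = normalize_missing(pad_to(drugs_raw$indication, n_slots, id, "indication"), ph)[keep],
      drug_index = seq_len(n_drug)
    )

    reac_raw <- purrr::map(
      c("reaction_terms", "reaction_start_dates", "reaction_outcomes"),
      \(f) split_multi(normalize_missing(col(row, f), ph)[1], sep)
    )
    names(reac_raw) <- c("term", "start", "outcome")
    keep_r <- !is.na(normalize_missing(reac_raw$term, ph))
    n_reac <- sum(keep_r)
    if (n_reac == 0) {
      warning("Report ", id, " has no parseable reaction; skipped.", call. = FALSE)
      return(NULL)
    }
    n_slots_r <- length(reac_raw$term)
    reactions <- tibble::tibble(
      reaction_term = normalize_missing(reac_raw$term, ph)[keep_r],
      reaction_start_raw = normalize_missing(pad_to(reac_raw$start, n_slots_r, id, "reaction start date"), ph)[keep_r],
      outcome_text = normalize_missing(pad_to(reac_raw$outcome, n_slots_r, id, "outcome"), ph)[keep_r],
      reaction_index = seq_len(n_reac)
    )

    narrative_bits <- c(
      normalize_missing(col(row, "narrative"), ph),
      normalize_missing(col(row, "reporter_comment"), ph),
      normalize_missing(col(row, "sender_comment"), ph)
    )

    tidyr::crossing(drugs, reactions) |>
      dplyr::mutate(
        report_id = id,
        sex = normalize_missing(col(row, "sex"), ph),
        age = extract_numeric_age(normalize_missing(col(row, "age"), ph)),
        country = normalize_missing(col(row, "country"), ph),
        reporter_qualification = normalize_missing(col(row, "reporter_qualification"), ph),
        report_type = normalize_missing(col(row, "report_type"), ph),
        narrative_present = any(!is.na(narrative_bits))
      )
  }

  out <- purrr::map(seq_len(nrow(listing)), one_report) |>
    purrr::list_rbind()
  if (nrow(out) == 0) {
    return(empty_combinations())
  }
  out |>
    dplyr::mutate(
      drug_role = parse_drug_role(.data$drug_role_raw),
      drug_start_date = parse_date(.data$drug_start_raw),
      reaction_start_date = parse_date(.data$reaction_start_raw)
    ) |>
    dplyr::arrange(
      match(.data$report_id, ids),
      .data$drug_index, .data$reaction_index
    ) |>
    dplyr::select(
      "report_id", "drug_index", "drug_name", "drug_role",
      "drug_start_date", "dose_text", "indication_text",
      "reaction_index", "reaction_term", "reaction_start_date",
      "outcome_text", "sex", "age", "country",
      "reporter_qualification", "report_type", "narrative_present"
    )
}

empty_combinations <- function() {
  tibble::tibble(
    report_id = character(), drug_index = integer(), drug_name = character(),
    drug_role = character(), drug_start_date = as.Date(character()),
    dose_text = character(), indication_text = character(),
    reaction_index = integer(), reaction_term = character(),
    reaction_start_date = as.Date(character()), outcome_text = character(),
    sex = character(), age = numeric(), country = character(),
    reporter_qualification = character(), report_type = character(),
    narrative_present = logical()
  )
}
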