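# Fixture builders shared across the suite. Everything is generated in code;
# nothing is stored on disk.

# One fully populated report row in the line-listing dialect. Multi-valued
# fields take strings pre-joined with "\n". Override any field to build
# degenerate cases.
listing_row <- function(id = "EV-1",
                        report_type = "Spontaneous",
                        qualification = "Physician",
                        country = "DE",
                        sex = "Female",
                        age = "34 Years",
                        narrative = "Reaction after first dose.",
                        reporter_comment = "Not available",
                        sender_comment = "Not available",
                        drug_names = "Examplecillin",
                        drug_roles = "Suspect",
                        drug_starts = "01/01/2020",
                        doses = "40 mg",
                        indications = "Hypertension",
                        reactions = "Pyrexia",
                        reaction_starts = "05/01/2020",
                        outcomes = "Recovered") {
  tibble::tibble(
    `Worldwide Unique Case Identification Number` = id,
    `Report Type` = report_type,
    `Primary Source Qualification` = qualification,
    `Primary Source Country` = country,
    `Patient Sex` = sex,
    `Patient Age Group/Age` = age,
    `Case Narrative` = narrative,
    `Reporter's Comment` = reporter_comment,
    `Sender's Comment` = sender_comment,
    `Drug Name` = drug_names,
    `Drug Role` = drug_roles,
    `Drug Start Date` = drug_starts,
    `Drug Dose` = doses,
    `Drug Indication` = indications,
    `Reaction PT` = reactions,
    `Reaction Start Date` = reaction_starts,
    `Reaction Outcome` = outcomes
  )
}

# A row with every scored category absent (placeholders everywhere, no
# computable time to onset).
empty_listing_row <- function(id = "EV-1") {
  listing_row(
    id = id,
    report_type = "Not available", qualification = "Not available",
    country = "Not available", sex = "Not available", age = "Not available",
    narrative = "Not available",
    drug_starts = "Not available", doses = "Not available",
    indications = "Not available",
    reaction_starts = "Not available", outcomes = "Not available"
  )
}

# A presence tibble row set for attribution tests: report_id, drug_name,
# reaction_term plus the ten logical category columns.
presence_tbl <- function(report_id, drug_name = "DrugA",
                         reaction_term = "Pyrexia", ...) {
  flags <- stats::setNames(rep(TRUE, 10), score_categories())
  over <- list(...)
  flags[names(over)] <- unlist(over)
  tibble::tibble(
    report_id = report_id, drug_name = drug_name,
    reaction_term = reaction_term, !!!as.list(flags)
  )
}

# Convert a csv line listing to xlsx through Python/openpyxl, so the two
# readers can be compared on identical content without a binary fixture in
# the repository.
csv_to_xlsx <- function(csv_path, xlsx_path) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import csv, sys",
    "from openpyxl import Workbook",
    "wb = Workbook()",
    "ws = wb.active",
    "with open(sys.argv[1], newline='', encoding='utf-8') as f:",
    "    for row in csv.reader(f):",
    "        ws.append(row)",
    "wb.save(sys.argv[2])"
  ), script)
  status <- system2("python", c(script, csv_path, xlsx_path),
    stdout = TRUE, stderr = TRUE
  )
  if (!file.exists(xlsx_path)) {
    stop("csv->xlsx conversion failed: ", paste(status, collapse = "\n"))
  }
  xlsx_path
}

# Independent brute-force completeness score: explicit loop and literal
# penalty values, no shared code with score_combination().
brute_force_score <- function(presence_row) {
  pens <- c(
    time_to_onset = 0.5, indication = 0.3, outcome = 0.3, sex = 0.3,
    age = 0.3, dose = 0.1, country = 0.1, primary_reporter = 0.1,
    report_type = 0.1, comments = 0.1
  )
  s <- 1
  for (cat in names(pens)) {
    if (!isTRUE(presence_row[[cat]])) s <- s * (1 - pens[[cat]])
  }
  s
}

# Independent ICC oracle: mean squares from stats::aov on long-format data,
# then the textbook single-measure formulas.
icc_oracle <- function(x, y, type = "agreement") {
  n <- length(x)
  k <- 2
  long <- data.frame(
    score = c(x, y),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  ms <- summary(stats::aov(score ~ subject + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}
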