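test_that("time to onset is defined exactly for ordered complete dates, zero inclusive", {
  d <- as.Date("2020-01-05")
  expect_equal(compute_time_to_onset(as.Date("2020-01-01"), d), 4L)
  expect_true(is.na(compute_time_to_onset(d, as.Date("2020-01-01")))) # reversed
  expect_equal(compute_time_to_onset(d, d), 0L) # same day counts
  expect_true(is.na(compute_time_to_onset(as.Date(NA), d)))

  # exhaustive check over a window of date pairs
  dates <- seq(as.Date("2021-02-20"), by = "day", length.out = 20)
  grid <- expand.grid(drug = dates, reaction = dates)
  got <- compute_time_to_onset(grid$drug, grid$reaction)
  want <- as.integer(grid$reaction - grid$drug)
  want[want < 0] <- NA_integer_
  expect_identical(got, want)
})

test_that("presence assessment follows the per-category decision rules", {
  full <- expand_combinations(listing_row())
  p <- assess_presence(full)
  expect_true(all(unlist(p[, score_categories()])))
  expect_equal(p$tto_days, 4L)

  # dose needs at least one numeric token, any unit
  for (dose in list(c("40 mg", TRUE), c("2 tablets", TRUE), c("100 units", TRUE),
                    c("as needed", FALSE))) {
    p <- assess_presence(expand_combinations(listing_row(doses = dose[[1]])))
    expect_identical(p$dose, as.logical(dose[[2]]), label = dose[[1]])
  }

  # age needs a numeric value; an age-group word does not count
  p <- assess_presence(expand_combinations(listing_row(age = "Adult")))
  expect_false(p$age)
  p <- assess_presence(expand_combinations(listing_row(age = "Not available")))
  expect_false(p$age)

  # partial drug date kills the time to onset only
  p <- assess_presence(expand_combinations(listing_row(drug_starts = "01/2020")))
  expect_false(p$time_to_onset)
  expect_true(p$indication)

  # comments present if any of narrative / reporter's / sender's comment is
  p <- assess_presence(expand_combinations(
    listing_row(narrative = "Not available", sender_comment = "See attached.")
  ))
  expect_true(p$comments)
  p <- assess_presence(expand_combinations(listing_row(narrative = "Not available")))
  expect_false(p$comments)
})

test_that("combination score equals the brute-force product over all 1024 patterns", {
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 10))
  colnames(patterns) <- score_categories()
  got <- score_combination(patterns)
  want <- vapply(seq_len(nrow(patterns)), function(i) {
    brute_force_score(as.list(patterns[i, ]))
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= prod(1 - penalty_scheme()) - 1e-12 & got <= 1 + 1e-12))
  # bounds attained exactly at all-absent / all-present
  expect_equal(min(got), prod(1 - penalty_scheme()))
  expect_equal(max(got), 1)
  expect_equal(round(prod(1 - penalty_scheme()), 4), 0.0709)
})

test_that("flipping any absent category to present multiplies the score by 1/(1-P)", {
  scheme <- penalty_scheme()
  set.seed(42)
  for (rep in 1:25) {
    pattern <- stats::setNames(as.list(sample(c(TRUE, FALSE), 10, replace = TRUE)), score_categories())
    base <- score_combination(as.data.frame(pattern))
    for (cat in score_categories()[!unlist(pattern)]) {
      flipped <- pattern
      flipped[[cat]] <- TRUE
      expect_equal(
        score_combination(as.data.frame(flipped)),
        base / (1 - scheme[[cat]]),
        tolerance = 1e-12
      )
    }
  }
})

test_that("worked single-category examples: missing sex scores 0.70", {
  sex_only_missing <- as.data.frame(as.list(
    stats::setNames(score_categories() != "sex", score_categories())
  ))
  expect_equal(score_combination(sex_only_missing), 0.70, tolerance = 1e-12)
})

test_that("per-report aggregation: mean, best, distinctness, threshold inclusive", {
  scored <- tibble::tibble(
    report_id = c("R1", "R1", "R2"),
    drug_role = "suspect",
    score = c(0.5, 0.7, 0.9)
  )
  rep <- score_reports(scored)
  r1 <- dplyr::filter(rep, report_id == "R1")
  expect_equal(r1$mean_score, 0.6)
  expect_equal(r1$best_score, 0.7)
  expect_equal(r1$n_distinct_scores, 2L)
  r2 <- dplyr::filter(rep, report_id == "R2")
  expect_equal(r2$n_combinations, 1L)
  expect_true(r2$well_documented)

  # threshold is inclusive at exactly 0.8
  at <- score_reports(tibble::tibble(report_id = "R", drug_role = "suspect", score = 0.8))
  expect_true(at$well_documented)

  # duplicating a combination at the mean's exact value leaves the mean unchanged
  dup <- dplyr::bind_rows(scored, tibble::tibble(report_id = "R1", drug_role = "suspect", score = 0.6))
  expect_equal(
    dplyr::filter(score_reports(dup), report_id == "R1")$mean_score,
    0.6
  )

  # distinctness works at reporting precision, not floating-point noise
  noisy <- tibble::tibble(
    report_id = "R", drug_role = "suspect",
    score = c(0.7, 0.7 + 1e-9)
  )
  expect_equal(score_reports(noisy)$n_distinct_scores, 1L)
})

test_that("concomitant combinations never enter the per-report mean", {
  scored <- tibble::tibble(
    report_id = c("R1", "R1", "R2"),
    drug_role = c("suspect", "concomitant", "concomitant"),
    score = c(0.4, 1.0, 0.9)
  )
  expect_warning(rep <- score_reports(scored), "R2")
  expect_identical(rep$report_id, "R1")
  expect_equal(rep$mean_score, 0.4) # concomitant 1.0 ignored
})

test_that("vaccine exclusion removes whole reports, and only matching ones", {
  combos <- tibble::tibble(
    report_id = c("R1", "R1", "R2"),
    drug_name = c("Covid vaccine X", "Paracetamol", "Paracetamol")
  )
  expect_message(out <- exclude_vaccines(combos), "R1")
  expect_identical(unique(out$report_id), "R2") # all of R1 removed
  expect_identical(exclude_vaccines(combos, terms = character(0)), combos)

  sim <- generate_linelisting(synth_config(n_reports = 200, vaccine_fraction = 0.2), seed = 3)
  truth <- sim$truth$combinations
  combos <- expand_combinations(sim$listing)
  kept <- suppressMessages(exclude_vaccines(combos))
  vaccine_reports <- unique(truth$report_id[truth$vaccine])
  expect_gt(length(vaccine_reports), 0)
  expect_setequal(
    setdiff(unique(combos$report_id), unique(kept$report_id)),
    vaccine_reports
  )
})

test_that("dataset summary matches an independent recomputation", {
  reports <- tibble::tibble(
    report_id = c("a", "b", "c"),
    mean_score = c(0.2, 0.5, 0.8),
    best_score = c(0.2, 0.5, 0.8),
    n_combinations = 1L,
    n_distinct_scores = 1L,
    well_documented = c(FALSE, FALSE, TRUE)
  )
  s <- summarize_scores(reports)
  expect_equal(s$stats$mean, 0.5)
  expect_equal(s$stats$median, 0.5)
  expect_equal(s$stats$n_well_documented, 1L)
  expect_equal(s$stats$sd, stats::sd(c(0.2, 0.5, 0.8)))
  expect_equal(sum(s$distinct_values$n_reports), 3)

  same <- dplyr::mutate(reports, mean_score = 0.4)
  expect_equal(summarize_scores(same)$stats$sd, 0)

  # synthetic dataset: every statistic re-derived directly from the scores
  sim <- generate_linelisting(synth_config(n_reports = 150), seed = 9)
  res <- suppressMessages(score_linelisting(sim$listing))
  s <- summarize_scores(res$reports)
  x <- res$reports$mean_score
  expect_equal(s$stats$n_reports, length(x))
  expect_equal(s$stats$mean, mean(x))
  expect_equal(s$stats$sd, stats::sd(x))
  expect_equal(s$stats$median, stats::median(x))
  expect_equal(s$stats$iqr_lower, unname(stats::quantile(x, 0.25)))
  expect_equal(s$stats$iqr_upper, unname(stats::quantile(x, 0.75)))
  expect_equal(s$stats$min, min(x))
  expect_equal(s$stats$max, max(x))
  expect_equal(s$stats$n_well_documented, sum(x >= 0.8))
  bins <- table(factor(pmin(res$reports$n_distinct_scores, 5), levels = 1:5))
  expect_equal(s$distinct_values$n_reports, as.integer(bins))

  expect_error(summarize_scores(reports[0, ]), "empty")
})

test_that("scoring a dataset is deterministic and permutation-invariant", {
  sim <- generate_linelisting(synth_config(n_reports = 60), seed = 21)
  combos <- suppressMessages(exclude_vaccines(expand_combinations(sim$listing)))
  a <- score_combinations(combos)
  b <- score_combinations(combos[sample(nrow(combos)), ])
  expect_equal(sort(a$score), sort(b$score))
  expect_identical(a, score_combinations(combos))
})

test_that("penalty overrides are validated and reported", {
  expect_message(s <- penalty_scheme(overrides = c(age = 0.1)), "overridden")
  expect_equal(s[["age"]], 0.1)
  expect_error(penalty_scheme(overrides = c(nope = 0.5)), "nope")
  expect_error(validate_penalty_scheme(c(a = 0.5)), "ten categories")
  bad <- penalty_scheme()
  bad[["sex"]] <- 1.5
  expect_error(validate_penalty_scheme(bad), "between 0 and 1")
})
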