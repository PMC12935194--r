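test_that("ICC agreement form matches an independent ANOVA oracle", {
  # small hand-built table of paired scores
  x <- c(0.10, 0.32, 0.55, 0.70, 0.82, 0.95)
  y <- c(0.15, 0.30, 0.50, 0.75, 0.80, 1.00)
  got <- compute_icc(x, y)
  expect_equal(got$estimate, icc_oracle(x, y, "agreement"), tolerance = 1e-10)
  expect_identical(got$type, "ICC(2,1) agreement")

  cons <- compute_icc(x, y, type = "consistency")
  expect_equal(cons$estimate, icc_oracle(x, y, "consistency"), tolerance = 1e-10)

  # random paired tables keep matching the oracle
  set.seed(101)
  for (i in 1:10) {
    a <- stats::runif(20)
    b <- a + stats::rnorm(20, sd = 0.1)
    expect_equal(compute_icc(a, b)$estimate, icc_oracle(a, b, "agreement"),
      tolerance = 1e-10
    )
  }
})

test_that("ICC is symmetric, permutation-invariant, inside its own CI", {
  set.seed(7)
  a <- stats::runif(30)
  b <- a + stats::rnorm(30, sd = 0.15)
  i1 <- compute_icc(a, b)
  expect_equal(compute_icc(b, a)$estimate, i1$estimate, tolerance = 1e-12)
  ord <- sample(30)
  expect_equal(compute_icc(a[ord], b[ord])$estimate, i1$estimate, tolerance = 1e-12)
  expect_true(i1$conf_low <= i1$estimate && i1$estimate <= i1$conf_high)
})

test_that("absolute agreement punishes constant shifts that consistency forgives", {
  set.seed(11)
  a <- stats::runif(50)
  b <- a + 0.5 # perfectly correlated, systematically shifted
  agree <- compute_icc(a, b)$estimate
  expect_lt(agree, 0.5)
  expect_gt(compute_icc(a, b, type = "consistency")$estimate, 0.999)
})

test_that("ICC handles identical and degenerate columns explicitly", {
  x <- c(0.2, 0.5, 0.8, 0.9)
  perfect <- compute_icc(x, x)
  expect_equal(perfect$estimate, 1)
  expect_equal(perfect$conf_low, 1)

  flat <- compute_icc(rep(0.5, 5), rep(0.5, 5))
  expect_identical(flat$type, "undefined")
  expect_true(is.na(flat$estimate))

  expect_error(compute_icc(c(1, 2), c(1, 2)), "at least 3")
})

test_that("confidence intervals tighten as the number of pairs grows", {
  gen <- function(n, seed) {
    set.seed(seed)
    a <- stats::runif(n)
    list(a = a, b = a + stats::rnorm(n, sd = 0.1))
  }
  small <- gen(30, 1)
  big <- gen(300, 1)
  w_small <- with(compute_icc(small$a, small$b), conf_high - conf_low)
  w_big <- with(compute_icc(big$a, big$b), conf_high - conf_low)
  expect_lt(w_big, w_small)
})

test_that("comparing a score set to itself gives zero differences and ICC 1", {
  sim <- generate_linelisting(synth_config(n_reports = 80), seed = 30)
  own <- sim$truth$reports |>
    dplyr::transmute(report_id,
      mean_score = true_mean_score,
      best_score = true_best_score
    )
  ref <- dplyr::transmute(own, report_id, score = mean_score)
  cmp <- compare_scores(own, ref)
  expect_true(all(cmp$pairs$difference == 0))
  expect_equal(cmp$stats$n_flagged, 0)
  expect_equal(cmp$stats$icc, 1)
  # linearity: mean of differences equals difference of means
  expect_equal(
    cmp$stats$mean_difference,
    mean(cmp$pairs$own) - mean(cmp$pairs$reference)
  )
})

test_that("deviations are flagged inclusively at the threshold, with sign", {
  own <- tibble::tibble(
    report_id = c("a", "b", "c", "d"),
    mean_score = c(0.5, 0.6, 0.9, 0.5),
    best_score = c(0.5, 0.6, 0.9, 0.5)
  )
  ref <- tibble::tibble(report_id = c("a", "b", "c", "d"), score = c(0.9, 0.3, 0.9, 0.21))
  cmp <- compare_scores(own, ref)
  pairs <- cmp$pairs
  expect_equal(pairs$difference[pairs$report_id == "a"], -0.4)
  expect_identical(pairs$direction[pairs$report_id == "a"], "negative")
  expect_identical(pairs$direction[pairs$report_id == "b"], "positive") # exactly +0.3
  expect_identical(pairs$direction[pairs$report_id == "c"], "none")
  expect_false(pairs$flagged[pairs$report_id == "d"]) # 0.29 stays below
  expect_equal(cmp$stats$n_flagged, 2)
})

test_that("unmatched report ids are excluded with a message; empty pairing is fatal", {
  own <- tibble::tibble(report_id = c("a", "b", "c"), mean_score = c(0.4, 0.5, 0.6), best_score = 0.6)
  ref <- tibble::tibble(report_id = c("b", "c", "zz"), score = c(0.5, 0.6, 0.2))
  expect_message(cmp <- compare_scores(own, ref), "excluded")
  expect_setequal(cmp$pairs$report_id, c("b", "c"))
  expect_error(
    compare_scores(own, tibble::tibble(report_id = "q", score = 0.5)),
    "shared"
  )
})

test_that("best-score comparison uses the per-report maximum", {
  own <- tibble::tibble(
    report_id = c("a", "b", "c"),
    mean_score = c(0.4, 0.5, 0.6),
    best_score = c(0.9, 0.8, 0.7)
  )
  ref <- tibble::tibble(report_id = c("a", "b", "c"), score = c(0.9, 0.8, 0.7))
  cmp <- compare_scores(own, ref, use_best = TRUE)
  expect_true(all(cmp$pairs$difference == 0))
  expect_identical(cmp$score_used, "best")
})

test_that("attribution distinguishes report level, ADR-drug level and unattributable", {
  own <- dplyr::bind_rows(
    presence_tbl("r-age"),
    presence_tbl("r-tto", drug_name = "D1"),
    presence_tbl("r-tto", drug_name = "D2"),
    presence_tbl("r-none"),
    presence_tbl("r-missing")
  )
  ref <- dplyr::bind_rows(
    presence_tbl("r-age", age = FALSE), # report-level mismatch
    presence_tbl("r-tto", drug_name = "D1", time_to_onset = FALSE), # combo-level
    presence_tbl("r-tto", drug_name = "D2"),
    presence_tbl("r-none") # identical
  )
  att <- attribute_discrepancies(
    c("r-age", "r-tto", "r-none", "r-missing"),
    own, ref
  )
  rows <- att$reports
  expect_identical(rows$level[rows$report_id == "r-age"], "report")
  expect_identical(rows$categories[rows$report_id == "r-age"], "age")
  expect_identical(rows$level[rows$report_id == "r-tto"], "adr_drug")
  expect_identical(rows$categories[rows$report_id == "r-tto"], "time_to_onset")
  expect_identical(rows$level[rows$report_id == "r-none"], "none_found")
  expect_identical(rows$level[rows$report_id == "r-missing"], "unattributable")
  expect_equal(
    att$category_counts$n_reports[att$category_counts$category == "age"], 1
  )
})

test_that("a report-level mismatch takes precedence over combination-level ones", {
  own <- presence_tbl("r1")
  ref <- presence_tbl("r1", sex = FALSE, time_to_onset = FALSE)
  att <- attribute_discrepancies("r1", own, ref)
  expect_identical(att$reports$level, "report")
  expect_identical(att$reports$categories, "sex")
})

test_that("masked categories are invisible to attribution", {
  own <- presence_tbl("r1")
  ref <- presence_tbl("r1", comments = FALSE)
  att <- attribute_discrepancies("r1", own, ref, mask = "comments")
  expect_identical(att$reports$level, "none_found")
  expect_error(attribute_discrepancies("r1", own, ref, mask = "bogus"), "bogus")
})

test_that("single-category perturbations are recovered 100% by attribution", {
  sim <- generate_linelisting(synth_config(n_reports = 250), seed = 55)
  own_rep <- sim$truth$reports |>
    dplyr::transmute(report_id,
      mean_score = true_mean_score,
      best_score = true_best_score
    )
  for (case in list(
    list(cat = "age", level = "report"),
    list(cat = "time_to_onset", level = "adr_drug"),
    list(cat = "dose", level = "adr_drug")
  )) {
    ref <- perturb_reference(sim$truth, flip = stats::setNames(1, case$cat), seed = 56)
    ref_scores <- dplyr::transmute(ref$reports, report_id, score = true_mean_score)
    # a low threshold flags every perturbed report so attribution sees them all
    cmp <- compare_scores(own_rep, ref_scores, threshold = 0.01)
    expect_gt(cmp$stats$n_flagged, 0)
    att <- attribute_discrepancies(cmp, sim$truth$combinations, ref$combinations)
    expect_setequal(unique(att$reports$level), case$level)
    expect_setequal(unique(att$reports$categories), case$cat)
  }
})
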