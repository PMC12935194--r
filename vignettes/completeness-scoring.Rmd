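---
title: "Completeness scoring of ADR line listings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Completeness scoring of ADR line listings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigicomplete)
```

## The model

Spontaneous adverse drug reaction (ADR) reports are assessed one ADR-drug
combination at a time. Ten information categories are judged present or
absent, and the completeness score of a combination is the multiplicative
penalty product

$$\mathrm{score} \;=\; \prod_{i=1}^{10} \bigl(1 - P_i\,[\text{category } i \text{ absent}]\bigr),$$

with penalty fractions $P_i$: time to onset 0.50; indication, outcome, sex
and age 0.30; dose, country, primary reporter, report type and
narrative/comments 0.10. A present category contributes a factor of 1, so
the score runs from $\prod_i(1-P_i) = 0.5\cdot0.7^4\cdot0.9^5 = 0.0709$
(reported as 0.07) to 1.0. The per-report value is the arithmetic mean over
the report's suspected and interacting combinations; concomitant drugs are
expanded but never averaged. A report with mean $\ge 0.8$ (inclusive) is
*well-documented*.

Two categories behave differently in the EudraVigilance line-listing
format than in the original VigiBase setting, and the score here reflects
that:

* **Time to onset is binary.** The listing carries no precomputed onset and
  no partial-precision machinery, so the onset is computable precisely —
  when both the drug start date and the reaction start date are complete,
  valid `DD/MM/YYYY` strings and the difference is a non-negative whole
  number of days — or not at all. Same-day onset (0 days) counts as
  available; a reversed pair, a partial date (`MM/YYYY`, `YYYY`) or an
  impossible calendar date does not. There are no graded uncertainty
  penalties: absence always costs the full 50%.
* **Age is binary.** The structured format carries no age groups, so age is
  present exactly when a numeric age value is given; an age-group word
  ("Adult") does not count, and there is no reduced age-group penalty.

Per-category presence rules for the remaining categories: dose counts as
available when the dose text contains at least one numeric token,
regardless of unit (mg, ml, tablets, units, ...); comments count when any
of the narrative, reporter's comment or sender's comment fields is filled;
sex, country, primary reporter qualification, report type, indication and
outcome count when the respective field is non-missing after placeholder
normalisation. The report-type category only asks whether a type is
recorded; non-spontaneous values are scored like any other but reported
with a warning, because the score is validated for spontaneous reports.

## The input dialect

Line listings are one row per report, one column per information category,
with absent values encoded as placeholder strings ("not available", "not
specified", "unknown", empty; the list is configuration, compared
case-insensitively after trimming). Because export column headers drift
across versions, columns are resolved by case-insensitive substring
keywords on the labels (`resolve_columns()`); each semantic field takes
the first matching column, a required field without a match is a fatal
error listing the available labels, and two fields claiming one column is
a fatal ambiguity. Multi-valued cells (several drugs or reactions per
report) use a configurable intra-cell separator — newline within the cell
by default, `"|"` as a csv-friendly alternative — with per-drug and
per-reaction attribute lists aligned positionally. This dialect is an
explicit, documented choice: the native export format cannot be
redistributed, so the package defines a testable dialect rather than
reverse-engineering one. Attribute lists shorter than the drug/reaction
list are padded with missing values and warned about, never the other way
around: silently losing a drug would change the report mean, while a
missing attribute only lowers one combination's score. Duplicate report
identifiers are fatal because per-report aggregation is ill-defined with
them. Drug roles are mapped by keyword (suspect / interacting /
concomitant); a missing or unrecognised role is scored as suspect — the
conservative choice, since it keeps the combination in the mean — with a
warning.

The processing order is fixed: vaccine/hyposensitisation exclusion
(report-level: if any drug of a report matches the term list, the whole
report is removed), then combination expansion, then concomitant
filtering, then scoring. Every exclusion is logged with the report id.

## Numerical choices

* Scores are carried at full precision internally. Display columns in the
  export files are rounded to 2 decimals (the reporting precision of the
  score), and a full-precision column sits alongside so downstream
  averaging never accumulates rounding.
* The number of *distinct* score values per report — the headline of the
  distinct-value histogram (bins 1, 2, 3, 4, ≥5) — is computed after
  2-decimal rounding, so floating-point noise cannot manufacture
  distinctness.
* The combination score is evaluated as a sequential product in the
  canonical category order, not via `exp(sum(log(...)))`, so it is
  bit-identical to any straightforward product of the same factors
  (including the synthetic generator's independent ground-truth
  computation).
* The well-documented threshold (0.8) and the deviation threshold (±0.3)
  are both inclusive.
* Dataset SD uses the $n-1$ denominator; the IQR is the 25th–75th
  percentile pair (default quantile type).

## Score comparison and the ICC

`compare_scores()` pairs each report's mean (or best, i.e. maximum)
combination score with a reference score for the same report, summarises
the differences (own − reference), and flags reports with
$|\Delta| \ge 0.3$. Agreement is quantified by the intraclass correlation
computed from the two-way ANOVA mean squares of the reports × raters
table. The form is **ICC(2,1)** — two-way random effects, absolute
agreement, single measurement — because the design is "the same reports
scored by two systems", where a systematic shift between systems must
count against agreement. ICC(3,1) (consistency) is available as a
configuration for sensitivity analysis. The 95% confidence interval uses
the standard F-distribution bounds with Satterthwaite degrees of freedom.
Degenerate inputs are explicit, not numeric accidents: a table with no
variance at all returns an undefined result, identical columns with spread
return exactly 1, and fewer than three pairs yields an undefined ICC
while the difference summary still stands.

Flagged reports are attributed with `attribute_discrepancies()` in two
stages: the report-level categories (sex, age, country, primary reporter,
report type, comments) are compared first, and only reports clean at that
level are examined per ADR-drug combination on the combination-level
categories (time to onset, indication, outcome, dose). A per-category mask
excludes categories the reference system cannot see — typically
`comments`, since narrative fields are not part of VigiBase-style
reference listings. Reports without reference presence data are reported
as unattributable rather than erroring.

## The synthetic generator

Real line listings cannot be shipped, so `generate_linelisting()` emits
listings in the documented dialect together with exact ground truth: per
combination the true presence flags and the true score (computed by an
inline literal-penalty product, deliberately independent of the scoring
module), per report the true mean/best score and a vaccine flag. A fixed
configuration and seed reproduce the output byte for byte, and the
caller's random stream is left untouched.

Default conditions, chosen once as a realistic spontaneous-report mix:
1,000 reports; per-category missingness time to onset 0.55, indication
0.45, comments 0.50, dose 0.40, age 0.35, outcome 0.30, primary reporter
0.10, sex 0.10, country 0.05, report type 0.05 — giving an expected
combination score of about 0.44, inside the 0.41–0.59 band typical of
published spontaneous-report datasets; drugs and reactions per report
skewed towards 1 (60%/50% singletons, up to 5); role mix 75% suspect, 5%
interacting, 20% concomitant for drugs after the first, with the first
drug always suspect because a valid spontaneous report names at least one
suspected drug; 5% vaccine reports; 30% of absent dates emitted as partial
strings rather than placeholders. Time-to-onset presence is realised
through the dates themselves: each drug and each reaction carries a
complete date with probability $\sqrt{1-m_{\mathrm{tto}}}$, reaction dates
are drawn on or after every drug start date, so a combination's onset is
computable with probability $1-m_{\mathrm{tto}}$ and is always
non-negative when computable.

`perturb_reference()` turns the truth into a controlled "second rater":
report-level categories flip per report (consistently across its
combinations), combination-level categories per combination, with
recorded flips — which is what lets the tests demand that attribution
recovers *exactly* the perturbed category in 100% of attributable flagged
reports.

What the generator does **not** emulate: correlation between categories
(real reports missing a narrative tend to miss more than that), realistic
drug/reaction vocabularies (a small invented lexicon plus flagged vaccine
terms is used — no real product names), within-dataset heterogeneity of
reporting channels, and the empirical score distributions of any real
dataset. Passing the recovery suites therefore demonstrates that the
pipeline computes the defined score exactly on the defined dialect — not
that any particular real dataset would attain a particular mean.

## Problem sizes and test design

The pipeline-recovery suite runs on 1,000 generated reports (roughly
2,700 combinations) and requires exact score equality; empirical
missingness rates are checked at 600 reports against a 3-standard-
deviation binomial band computed conservatively with $n$ = number of
reports, since onset presence is coupled across combinations that share a
drug or reaction. The scoring formula is verified against a brute-force
product over all $2^{10} = 1024$ presence patterns at $10^{-12}$, and the
ICC against an independent ANOVA-based computation at $10^{-10}$ on
hand-built and randomised tables. Reader equivalence between the csv and
xlsx paths is tested on generated content converted to xlsx at test time.

## Known limitations

* Only the documented line-listing dialect is parsed — not native E2B/ICSR
  XML, not the public-access superordinate listing format, and no EMA
  service is queried.
* The score judges presence, never content: a one-word narrative counts
  the same as a thorough one.
* Scoring vaccine or hyposensitisation reports is possible via
  `keep_vaccines = TRUE` but unvalidated; the default removes them.
* Column keyword defaults are best-effort against header drift and must
  remain configurable; exports with changed intra-cell separators need the
  separator set in the configuration.
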