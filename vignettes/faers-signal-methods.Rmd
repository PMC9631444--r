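---
title: "Methods: disproportionality, priority scoring and time-to-onset in faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, priority scoring and time-to-onset in faersignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical methods, the data contracts, the
numerical choices and the known limitations of `faersignal`. It is the
package's reference for *why* things are computed the way they are; the
README shows *how* to run them.

## The data model and deduplication

FAERS distributes quarterly `$`-delimited ASCII tables: DEMO
(demographics, one row per report version), DRUG, REAC (MedDRA preferred
terms), OUTC (outcome codes), THER (therapy dates) and INDI
(indications), plus a list of caseids deleted by the FDA or
manufacturers. Reports are *versioned*: a case (caseid) may appear under
several primaryids as follow-up information arrives. All counting in this
package is done on the deduplicated universe: per caseid the row with the
numerically largest primaryid survives (ties: the last-read row, matching
file order semantics), and deleted caseids are dropped entirely. The
operation is idempotent and order-independent, which the test suite
verifies by shuffling input rows.

Demographic fields are normalized on load: age unit codes are converted
to years (MON ÷ 12, DEC × 10, WK ÷ 52.1775, DY ÷ 365.25, HR ÷ 8765.8),
weights to kg (LBS × 0.453592, GMS ÷ 1000), and anything unconvertible or
non-positive degrades to missing. Dates parse only from complete 8-digit
`YYYYMMDD` entries; partial entries (`YYYY`, `YYYYMM`) are treated as
missing for interval arithmetic but retain their year for reporting-year
tabulation, since annual report counts are meaningful even when the day
is not recorded.

Cohort membership requires a primary-suspect (PS) drug record whose name
matches a configured generic or brand name — exact token match after
upper-casing and trimming, with generics also checked against the active
ingredient field. No fuzzy matching is attempted: the intended use is a
drug with a short, known name list, and fuzzy matching would make the
cohort definition irreproducible. PT-to-SOC classification is multi-axial
aware: a PT counts toward the target SOC if *any* of its SOC links
matches, because restricting to primary links silently loses events such
as secondary gastrointestinal manifestations of neoplasms; PTs absent
from the user-supplied map are routed to an "unmapped" report, never
dropped.

## Reporting odds ratio

For each event definition the deduplicated universe is partitioned into
the classic 2×2 (`a`: target drug & event, `b`, `c`, `d`), and

$$\mathrm{ROR} = \frac{ad}{bc}, \qquad
\mathrm{CI}_{95} = \exp\!\left(\ln \mathrm{ROR} \pm z_{0.975}
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right).$$

Design choices, all deliberate:

* **Comparator** is "all other drugs in the universe", not an active
  comparator — the standard spontaneous-report disproportionality frame.
* **Screening threshold**: only PTs with `a ≥ min_reports` (default 10)
  are evaluated, to limit false positives from tiny counts; sub-threshold
  PTs are listed separately rather than discarded.
* **Signal rule**: positive iff ROR025 > 1.
* **No Haldane–Anscombe correction**: a zero cell yields a flagged
  undefined result. Silent 0.5-corrections materially distort small-count
  RORs, and an explicit "undefined" is more honest than a corrected
  number.
* **Rounding** (2 decimals) happens only at serialization, never before
  the signal rule is applied.
* **Stratification** (sex, age bands, weight bands, reporter type)
  restricts the universe *before* table construction; cases missing the
  stratification variable are excluded from both margins of that
  stratification, since keeping them on one margin only would bias the
  comparator. Band edges default to 18/65 years and 80/100 kg and are
  configurable.

The unit of event counting is the (case, PT) pair: one case contributes
at most once to a PT's count but may contribute to many PTs, which is why
a cohort can carry roughly twice as many events as cases.

## Severity comparisons

A case is serious iff it carries any outcome code (DE → death, LT →
life-threatening, HO → hospitalization, DS → disability, CA/RI/OT →
other). Per PT, the (has event) × (serious) 2×2 over the cohort is tested
with the *uncorrected* Pearson χ² when all four expected counts under
independence are ≥ 5, otherwise with the two-sided Fisher exact test
using the probability-ordering rule (sum of hypergeometric probabilities
no larger than the observed table's). Both choices are verified in the
test suite: the uncorrected formula and the probability-ordering rule
reproduce published reference statistics exactly, and the expected-count
rule reproduces a published 45-row test assignment in full. The
Mann–Whitney test uses the tie-corrected normal approximation without
continuity correction — appropriate for the thousands-scale samples this
package targets — and reports the Z of group 1 (Z < 0 when group 1 ranks
lower); the sign convention is documented here precisely because it is
often left implicit.

No multiplicity adjustment is applied across PTs, matching standard
practice for descriptive severity tables; the p-values are screening
aids, not confirmatory tests.

## Clinical priority score

Five features, each mapped to points by a step function and summed to
0–10, banded weak (0–4) / moderate (5–7) / strong (8–10):

| feature | default points |
|---|---|
| ROR025 | [1, 2): 1, [2, 5): 2, ≥ 5: 3 |
| report count | ≥ 50: 1 |
| death proportion | ≥ 20%: 1, ≥ 50%: 2 |
| DME / IME status | DME: 2, IME: 1 |
| evidence grade | "++": 2, "+": 1, "–": 0 |

The default breakpoints were chosen as the minimal rubric consistent with
a published 45-signal reference scoring (bundled under `inst/extdata/`,
reproduced row-for-row by the test suite); the 20% death-proportion
breakpoint is only constrained by that table to lie in (14.3%, 25%], so
it should be treated as reverse-engineered rather than canonical, and
every breakpoint is configurable through `priority_rubric()`. The
evidence grade is an analyst annotation carried through from input to
output — the package never infers it, because literature evaluation is
judgement, not computation. DME takes precedence when a term is on both
the DME and IME lists. Feature values outside the rubric's domain (e.g.
ROR025 < 1, which cannot occur for a screened signal) raise an error
naming the feature rather than scoring nonsense.

## Weibull time-to-onset

TTO is `event_date − therapy_start_date` in whole days, with the earliest
complete start date used when a case has several therapy records for the
target drug (onset is measured from first exposure). Three exclusion
rules, each counted separately: missing onset date, missing or partial
start date, and onset before start (an input error). Summaries use
linear-interpolation quantiles (`quantile` type 7).

The Weibull fit maximizes the likelihood through the one-dimensional
profile score in the shape β (the scale α has the closed form
$\hat\alpha(\beta) = (\tfrac1n\sum t_i^\beta)^{1/\beta}$). The root is
bracketed and solved to relative tolerance 1e-8 — deterministic, no
starting-value sensitivity, no seeds. Confidence intervals are Wald
intervals on (log α, log β) using the analytic observed information,
exponentiated back; the log scale respects positivity and is the standard
reliability-analysis default. Zero-day onsets (same-day events, common in
spontaneous reports) enter the likelihood shifted to 0.5 days — the
midpoint of a same-day event — while summaries keep the zeros; the shift
is configurable. Degenerate inputs (all samples identical) raise an error
rather than returning an infinite-shape fit, and fits on fewer than 10
samples warn.

Failure type follows the shape CI against 1: entirely below → "early"
(decreasing hazard), entirely above → "wear-out", otherwise "random".
Band-level reporting pools samples over the PTs of each priority band and
fits one Weibull per band — matching the three-row
strong/moderate/weak presentation — with per-PT fitting available by
calling `fit_weibull_tto()` on a subset. There is no censoring model:
spontaneous reports carry no at-risk denominator, so the fitted
distribution describes reported onsets, not a population hazard.

## The synthetic generator

`simulate_faers()` emits a complete bundle (six tables plus a deleted
list) with known ground truth. One primary-suspect drug is drawn per
report; each study PT is an independent Bernoulli whose probability is
odds-scaled for exposed reports,
$p_1 = \mathrm{OR}\,p_0 / (1 - p_0 + \mathrm{OR}\,p_0)$, so the planned
report-level odds ratio is exactly the configured OR and the expected 2×2
has a closed form (`expected_ror()`). A filler reaction from a non-study
vocabulary guarantees every report at least one PT without touching the
study tables. Duplicates are planted as same-caseid rows with a higher
primaryid and perturbed demographics (exercising the keep-highest rule),
deletions as caseids on the deleted list, and date quality is degraded at
configured rates (missing onset, missing/partial start, onset before
start).

Default conditions emulate a GLP-1 receptor agonist gastrointestinal
cohort at simulation scale: 20,000 reports, 5% exposed, 58% female, age
truncated-normal(62, 12) on [18, 90] with 36% missing, log-normal weight
with median 96 kg and 82% missing, 89% US, 40% health-professional
reporters, roughly one-third serious cases, Weibull onset times with
shape < 1, 5% duplicate and 1% deleted cases. The
`preset_mini_semaglutide()` preset swaps in the bundled 45-PT vocabulary
with exposure frequencies scaled from the published report counts and
injected ORs tracking the published ROR lower bounds.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real extracts: free-text drug-name noise beyond
case/whitespace variants (no misspellings, salts, or combination
products), reporting-rate secular trends, correlated PT co-reporting
beyond the shared seriousness mechanism, country-specific reporting
cultures, and the pre-2012 legacy layout. Results on real FAERS data
still depend on careful name curation and dictionary mapping.

## Validation performed by the test suite

All problem sizes were chosen to give the checks statistical teeth at
interactive runtimes: Weibull parameter recovery uses 100 replicates of
n = 500 at true (α = 10, β = 0.5), checking |mean bias of β̂| < 0.02 and
CI coverage within [90%, 98%]; injected-OR recovery uses 100 bundles of
5,000 reports per OR ∈ {2, 5, 20}, requiring ≥ 90% CI coverage of the
truth; null calibration uses 20 bundles × 100 null PTs (2,000 tests),
requiring the ROR025 > 1 rule to fire at 2.5% ± 2 points; the Fisher
implementation is compared against exhaustive hypergeometric enumeration
for every 2×2 table with total n ≤ 30; and the Monte-Carlo mean of
generated 2×2 cells is compared to the closed-form expectation over 200
replicates. Published reference tables (the χ² and Fisher statistics, the
45 priority scores and bands, the test-selection assignment) are
reproduced from their printed component counts exactly.

## Known limitations

Disproportionality measures reporting association, not causation or
incidence: FAERS has no exposure denominator, reporting is voluntary and
biased, and a positive ROR is a hypothesis-generating flag. The Wald ROR
interval is approximate for small cells (the null-calibration test shows
a mild excess over the nominal 2.5% at counts near 25). The severity
tests are per-PT and unadjusted. The priority rubric's death-proportion
breakpoints are reverse-engineered within the published constraints. The
Weibull TTO fit conditions on an event being reported, so "early
failure" describes the timing of reported events, not a patient-level
hazard.
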