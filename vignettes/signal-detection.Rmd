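---
title: "Disproportionality signal detection and method comparison with pvsignals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and method comparison with pvsignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignals)
library(dplyr)
```

## The problem

Hospitals and regulators collect spontaneous adverse drug reaction (ADR)
reports: a clinician suspects that a medicine caused an unintended harmful
reaction and files a report naming the drug(s) and the reaction(s), coded
as MedDRA preferred terms (PT). Such databases have no denominator — we
observe only who reported, not who took the drug safely — so drug–event
associations are screened by *disproportionality*: is the target event
reported for the target drug more often than the database's margins
predict?

The unit of analysis is the **drug–event pair**. A report listing two
suspected drugs and three reactions contributes six pairs. For each
distinct (drug, event) combination the pair universe is collapsed into a
2×2 table:

|               | target event | other events |
|---------------|-------------:|-------------:|
| target drug   | a            | b            |
| other drugs   | c            | d            |

`pvsignals` implements the four screening statistics routinely applied to
such tables, their signal-strength bands, and a framework for comparing
them against a reference method.

## The four methods

**PRR** (proportional reporting ratio): `[a/(a+b)] / [c/(c+d)]`, the
relative reporting proportion of the event for the drug versus all other
drugs. Its 95% interval is the log-scale Wald interval with
`SE = sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))`. A signal requires the CI
lower bound to exceed 1 with at least 3 cases; strength is banded on the
lower bound (weak < 50 ≤ medium < 1000 ≤ high).

**ROR** (reporting odds ratio): `ad/bc` with
`SE = sqrt(1/a + 1/b + 1/c + 1/d)`, same gating and bands. The ROR is
always at least as extreme as the PRR on the disproportionate side.

**MHRA criterion**: a joint rule — PRR ≥ 2, at least 3 cases, and Pearson
`χ² = N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)] ≥ 4` — banded on χ²
(weak < 100 ≤ medium < 1000 ≤ high). A Yates-corrected variant is
available behind the `yates` flag; the plain Pearson form is the default
because neither variant is privileged by published practice and the
uncorrected form is the textbook MHRA rule.

**BCPNN information component**: the Bayesian confidence propagation
neural network scores each cell by `IC = log2[p11/(p1+·p+1)]`, the log2
observed-to-expected ratio under a Bayesian model with Beta priors
(α₁ = β₁ = 1, α = β = 2, γ₁₁ = 1 — the standard hospital-pharmacovigilance
parameterization). The classical closed form (the package default)
computes `IC` and its variance from ratios of posterior means; a signal
requires `IC − 2SD > 0`, with weak ≤ 1.5 < medium ≤ 3.0 < high bands on
the lower limit.

### Exact versus classical BCPNN moments

The classical closed-form `IC` is `log2` of a ratio of posterior *means*,
not the posterior mean of `log2`; the two differ by a Jensen gap of order
`1/(2(a+1)ln 2)` — about 0.16 bits at a = 3, negligible by a ≈ 50.
`bcpnn(..., moments = "exact")` returns the exact posterior mean and SD
of IC under the same independent-Beta posterior, computed with
digamma/trigamma functions. The package's validation suite checks the
exact moments against a 10⁶-draw Monte-Carlo sampler of that posterior
(agreement well inside 0.02 bits) and bounds the classical
approximation's drift against the exact moments at large counts. The
classical form remains the default because it is what deployed screening
systems compute, and because the published strength bands were calibrated
against it.

## Ingest and exclusion rules

`read_line_listing()` accepts both long (one row per report–drug–event)
and wide (multi-valued cells, default delimiter `";"`) dialects, with a
`column_map` for nonstandard headers. Rows with unparseable mandatory
fields are collected in a rejects table, never silently dropped. Drug
names and event terms are case-folded; dates that fail ISO-8601 parsing
become missing (no statistic uses them); ages outside [0, 130] become
missing.

`filter_reports()` applies the conventional exclusions — uncertain
causality, duplicates, and optionally drug-combination reports — logging
one reason per removed report. Two deliberately open choices:

* **Duplicate key.** Reporting systems differ on whether duplicates are
  matched by report number or clinical content. The primary key here is
  `report_id` (first occurrence kept); an off-by-default fuzzy mode also
  matches date + age + sex + sorted drug set + sorted event set. Neither
  is asserted as the only correct key.
* **Combination reports.** "More than one suspected drug" is the working
  definition, and the exclusion is off by default: screens commonly keep
  such reports and scope instead on the first-suspected role, so the flag
  exists for protocols that do exclude them.

## Comparing methods

With one method fixed as the reference (BCPNN by default, the usual
Bayesian reference standard), each other method's binary signal calls are
cross-tabulated against the reference's to give sensitivity, specificity,
predictive values and the Youden index. The comparison is repeated over a
sweep of minimum case counts (default 3, 4, 5, 6, 7, 11), since agreement
between methods improves with case count. Strengths are not graded in the
confusion table — the comparison is of yes/no determinations. Any 0/0
metric in an empty stratum is reported as `NA`, never coerced to 0, which
would silently corrupt the Youden index.

Two ROC constructions are provided and labelled, because sweep-based ROC
summaries are ambiguous: `roc_auc()` anchors the sweep's
(1 − specificity, sensitivity) points at (0,0) and (1,1) and applies the
trapezoid rule, while `roc_scores()` treats the continuous statistic as a
score against the reference labels (via pROC). A method whose specificity
is 1 at every threshold contributes only left-edge points, so its
anchored trapezoid AUC is far below 1 even at perfect specificity —
published AUC values for such sweeps cannot generally be reproduced by
either construction, and the package does not claim to.

## The bundled fluoroquinolone screen

The package ships machine-readable transcriptions of a published
single-hospital fluoroquinolone screen (levofloxacin, moxifloxacin,
ciprofloxacin; 263 reports, 391 drug–event pairs, 31 combinations with
≥ 3 cases) as `load_fixture()` tables: per-drug exposure and incidence,
drug-by-SOC pair counts, the 31 per-combination printed statistics with
per-method determinations, and the published method comparison.

The screen's database-wide denominators were never published, and an
integer search (`inst/scripts/reconstruct-margins.R`) shows the printed
per-row statistics are mutually inconsistent at integer precision — no
single comparator universe reproduces them all. The fixture therefore
carries printed statistics rather than reconstructed margins, and
`screen_from_printed()` turns such a table into a screen object for
classification and comparison. Its `flags` argument matters:
`"classified"` re-applies the stated rules to the printed statistics;
`"printed"` takes the published yes/no columns as-is. The two differ on
exactly two rows of the bundled screen, where the published
determinations contradict the publication's own stated rules (one MHRA
row satisfying PRR ≥ 2, A ≥ 3, χ² ≥ 4 yet marked "No"; one BCPNN row
with a positive printed IC lower limit marked "No"); the test suite pins
both discrepancies.

## The synthetic generator

`simulate_reports()` emulates a multinomial reporting process: each
report draws one suspected drug from configurable marginals and its
event(s) from the event marginals, re-weighted within the drug by the
relative risk of any planted (drug, event) cells and renormalized.
Renormalization attenuates the planted cell's asymptotic PRR to
`rr / (1 + (rr − 1)·p)` for baseline event probability `p`, which the
parameter-recovery tests target explicitly. Defaults chosen for the
validation studies: 5000 reports over 20 drugs × 30 uniform events with
one cell planted at relative risk 10 for power/size runs (the planted
cell's expected count is then ≈ 64, comfortably above the screening
floor, while null cells sit near their 2.5% one-sided false-positive
rate); 2000 reports over 5 drugs × 8 events for interval-coverage runs,
large enough that every combination's Wald interval is in its asymptotic
regime. Reports default to one drug and one event each (matching the
one-drug-per-pair analysis scope); multi-drug, duplicate and uncertain
reports are generated only behind probability flags to exercise the
exclusion rules. The generator does **not** model reporting biases
(Weber effect, stimulated reporting, duplicate clusters with divergent
content), so passing recovery tests demonstrate statistical correctness
of the pipeline, not robustness to real-world reporting artefacts.

Randomness uses R's own seeded generator; every stochastic test and the
acceptance script state their seeds, and a fixed seed reproduces the
generated data byte for byte.

## Numerical choices

* **Zero cells.** A zero in b, c or d makes PRR/ROR or their SEs
  undefined: 0.5 is added to all four cells (Haldane–Anscombe) and the
  result is flagged `corrected`. `a = 0` yields point 0, lower bound 0,
  never a signal. Degenerate margins (an empty row or column) are an
  error for direct calls and a flagged `NA` row in batch screening.
* **Integer overflow.** χ² cross-products are computed in doubles; margin
  products overflow 32-bit integers for universes beyond a few thousand
  pairs.
* **Strict boundaries.** "Lower bound > 1" and "IC − 2SD > 0" are strict;
  the strength-band edges follow the published conventions (50 and 1000
  included upward for PRR/ROR; 4, 100, 1000 for χ²; 1.5 and 3.0 included
  downward for BCPNN).
* **Rounding.** Statistics are kept at full precision; exported display
  tables round to 2 decimals half-up (matching conventional published
  display), with a parallel full-precision CSV.
* **Ordering.** Screens are ordered by drug, descending case count, then
  event; the comparison orders by method then threshold. All operations
  are invariant to input row order.

## Validation problem sizes

The test suite validates against brute-force oracles (row scans, double
loops, quadruple counts, hand formulas, shoelace areas) on small
fixtures; the simulation checks use 100 replicates of 5000 reports for
power/size, 200 replicates of 2000 reports for interval coverage, 60
replicates for margin goodness of fit, and 8 replicates each of 10³–10⁵
reports for parameter recovery — sizes at which the Monte-Carlo error of
each check is an order of magnitude below the tolerance it asserts.

## Known limitations

* No stratification (age, sex, period) and no adjustment for
  multiplicity across combinations — as in routine first-pass screens.
* No EBGM/MGPS, sequence-symmetry or temporal scan methods.
* The comparison framework measures *agreement with a reference method*,
  not accuracy against clinical truth; a method can agree perfectly with
  the reference and still be wrong about causality.
* XLSX input is supported (via readxl); exports are CSV.
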