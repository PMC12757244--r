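---
title: "Methods: case/non-case signal detection and time-to-onset analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/non-case signal detection and time-to-onset analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event databases such as FAERS collect unsolicited
reports of suspected drug reactions. They have no denominator of exposed
patients, so risk cannot be estimated directly; instead, pharmacovigilance
works with *disproportionality*: is the target event reported more often
with the target drug than with everything else in the database? `faersignal`
implements this workflow end to end for the case of a drug (the motivating
application is denosumab, an anti-RANKL antibody) and a severe adverse event
(osteonecrosis of the jaw, ONJ), but every exposure and event is a
parameter: any drug/preferred-term pair, with optional co-drug, regimen, and
demographic refinements, can be analysed.

## Data model and cleaning

A dataset is held relationally, as FAERS distributes it: a demographics
table (one row per report *version*) plus drug, reaction, therapy-date and
outcome tables keyed on `primary_id`. Readers accept both the `$`- and
`|`-delimited quarterly dialects, auto-detected per file; unparseable dates
become missing, child rows with no demographics parent are dropped and
counted as orphans, and rows with a non-numeric `primaryid` are skipped and
counted as malformed, so load quality is always inspectable in `meta$load`.

Cases arrive as multiple versions (follow-ups). `deduplicate()` keeps, per
`CASEID`, the version with the latest FDA receipt date, breaking ties by the
larger `PRIMARYID`. The operation is idempotent and its survivor set equals
a brute-force group-and-argmax, which the test suite verifies on randomized
duplicate sets.

Ages are harmonized from the FAERS unit codes (years, decades, months,
weeks, days, hours) to years, with values outside [0, 130] set to missing.
Dosing regimens are derived from the verbatim dose text: "120 mg" maps to
the every-4-weeks oncology regimen, "60 mg" to the every-6-months
osteoporosis regimen, anything else non-empty to `other`. This is a
deliberate simplification — FAERS dose text is free-form — and the parsing
rule is exposed as `parse_regimen()` so users can audit it.

## Disproportionality

For an exposure E and event Y, the 2×2 table counts a (E, Y),
b (not-E, Y), c (E, not-Y), d (not-E, not-Y) over deduplicated reports;
one report contributes to exactly one cell. The reporting odds ratio is

$$ROR = \frac{a/c}{b/d}, \qquad
95\%\,CI = \exp\left\{\ln ROR \pm 1.96
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right\},$$

and a *signal* is declared when the CI lower bound exceeds 1 with at least
three exposed cases. Tables with an empty cell return an explicit
undefined-ROR result rather than a Haldane–Anscombe 0.5 correction: the
signal rule already requires three cases, and a silent correction would
perturb estimates unpredictably while the sentinel keeps cell totals
conserved through the pipeline.

Two classification contracts coexist, and the distinction matters:

* `classify_reports()` applies a single exposure definition to every
  report: a report failing any observed filter is a comparator
  ("unexposed"), and a report missing a field the filter references is
  *not classifiable* and excluded from that analysis only.
* `stratum_contingency()` builds the table for one stratum of a stratified
  analysis. Here the comparator stays "all other drugs": target-drug
  reports failing a *drug-side* refinement (other regimen, absent co-drug)
  belong to a different stratum and are excluded — putting the 120 mg
  reports of an event-rich drug into the comparator of the 60 mg stratum
  would bias that stratum's ROR toward the null, and simulation with
  planted dose-dependent effects confirms the exclusion design recovers
  the planted values while the naive one cannot. *Demographic* refinements
  describe the patient rather than the drug and therefore restrict both
  sides of the table.

## Case/non-case logistic regression

Within the target-drug cohort (drug as primary suspect), `build_frame()`
derives the binary outcome and covariates — male sex, age ≥ 65, the
high-dose regimen, and one indicator per configured co-drug — and applies
complete-case filtering with a per-field exclusion tally. Fitting is
maximum likelihood via iteratively reweighted least squares
(log-likelihood tolerance 1e-8, 100-iteration cap). The univariate screen
admits variables with likelihood-ratio p < 0.20, plus a configurable
force-include set defaulting to the age indicator, which is retained for
baseline confounding control whether or not it screens in. The multivariate
model reports Wald CIs on the OR scale but likelihood-ratio p-values from
drop-one refits — both are conventional in this literature, and the pair is
reported side by side. Fitted coefficients beyond ±15 on the logit scale
are treated as (quasi-)complete separation — sparse co-drug indicators are
the usual cause — and such variables are flagged and withheld from the
joint model; aliased (collinear) variables are dropped with a warning.
Screened-out variables keep crude-only rows in the output table, so the
published two-column layout is preserved.

## Time-to-onset

Latency is the number of days from the earliest target-drug therapy start
to the event onset date, for exposed cases with both dates observed and a
positive interval; exclusions are tallied by reason. A configuration switch
(`anchor = "any"`) instead anchors on the earliest start across target and
required co-drugs, for sequential-therapy readings of "initiation".

The two-parameter Weibull (scale α in days, shape β) is fitted by maximum
likelihood with `optim` on the log-parameter scale, with moment-based
starting values; 95% CIs come from the observed Fisher information as Wald
intervals on log α and log β, back-transformed. Profile-likelihood
intervals would be a reasonable alternative; the Wald-on-log choice is
documented so users can compare. The hazard trend is read off β: CI
entirely below 1 → decreasing hazard (early failure); CI containing 1 →
constant hazard (random failure); CI entirely above 1 → increasing hazard
(wear-out failure). Exactly one pattern applies to any fit. No censoring
model is used: non-cases and cases without usable dates contribute nothing,
matching standard practice on onset reports and carrying the acknowledged
selection bias of that practice — the package documents rather than
corrects it. Fits are refused below 10 observations or on degenerate
(all-equal) samples. Quartiles use linear interpolation (type 7).
Subgroup comparisons use the two-sided Mann–Whitney U test: exact when both
samples have ≤ 8 tie-free observations, otherwise the normal approximation
with tie and continuity correction.

## The synthetic-data generator

`synth_config()` defines a study with known ground truth; its defaults
emulate the motivating denosumab/ONJ setting at desk scale:

* a mostly female (80%), elderly (mean 71 ± 13 years) reporting
  population, 75% healthcare-professional reporters, US-dominated country
  mix;
* a rare target event in the background (reference rate 0.001) and a
  strong planted exposure association (conditional OR 30), with covariate
  effects male OR 3, age ≥ 65 OR 1.5, high dose OR 7, co-reported
  zoledronic acid OR 10 — magnitudes in the range published risk-factor
  analyses report;
* 15% exposure prevalence with FAERS-like role mixing (85% primary
  suspect), a 40% high-dose share, and a 4% co-drug prevalence;
* regimen-specific Weibull latencies using published denosumab fits
  (60 mg: α 712.83, β 1.06; 120 mg: α 576.47, β 1.33; otherwise α 624.94,
  β 1.21), generated only for cases — matching databases where onset
  exists only for event reports — with 78.5% of case onset dates masked
  (the observed availability of usable dates in the motivating study);
* structured missingness (age 40%, sex 12%, dose 35%, reporter 1%,
  country 3%) applied *after* the latent truth is recorded;
* a 20% duplicate-version rate, each extra version dominated by the
  canonical one in (receipt date, primary id) and differing only in
  mutable fields, so deduplication must recover exactly the recorded
  canonical set.

Event dates are *not* clamped to the calendar window (clamping would
truncate long latencies and bias β downward); only therapy starts are
constrained to it. The event indicator follows a logistic model over the
report's covariates, so the regression stage's estimand is exactly the
planted coefficient vector. One caveat is deliberate: with non-null
covariate effects the *marginal* ROR differs slightly from the planted
conditional odds ratio (non-collapsibility), so parameter-recovery tests
plant either null covariates or compare against the conditional truth.
Latent truth for unexposed cases carries no onset date; the generator makes
no attempt to mimic real FAERS marginals beyond the configured exposures,
and passing tests therefore demonstrate statistical correctness of the
machinery, not realism of any particular FAERS quarter.

## Problem sizes and numerical choices

The test suite exercises the estimators at the scales where their operating
characteristics are meaningful while staying desk-sized: null calibration
of the signal rule uses 200 replicates of 50,000 reports; adjusted-OR
coverage uses 100 replicates of 40,000-row frames; Weibull shape recovery
uses 100 replicates at n = 1,652 (the motivating study's available-onset
count) and classifier behaviour at n = 300. Determinism is enforced
end-to-end: a fixed generator seed yields byte-identical table files and a
byte-identical pipeline manifest.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(
  target_drug = "denosumab",
  event_pt = "Osteonecrosis of jaw",
  synth = synth_config(n_reports = 50000, seed = 1),
  co_drugs = "zoledronic acid",
  out_dir = "faersignal-out"
)
res <- run_pipeline(cfg)
res$ror_table
res$regression$table
res$tto
```

## Known limitations

* Reporting databases carry no exposure denominator; the ROR measures
  reporting disproportionality, not incidence or relative risk.
* The regimen parser reads free-text dose strings; regimens it cannot
  parse are `other`/missing and drop out of dose-stratified analyses.
* The time-to-onset analysis conditions on an observed onset date; if date
  availability correlates with latency, the fitted Weibull is biased, and
  no correction is attempted.
* Drug-name standardization is only as good as the supplied synonym map;
  no structured-product-label resolution is performed, and MedDRA terms
  are treated as opaque strings.
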