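---
title: "Methods: risk-stratified random drug testing, its classifier, and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-stratified random drug testing, its classifier, and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(udtrisk)
```

## The monitoring problem

Patients on chronic opioid analgesic therapy (COAT) are monitored for
compliance by urine (or oral-fluid) toxicology. Testing every visit is
costly; fixed calendar schedules can be anticipated by exactly the patients
one most needs to observe. The policy implemented here removes both problems:
a deterministic stratification of each visit into an ordered risk category,
and a *random* test request at a category-specific pre-set probability. The
provider neither chooses nor can predict who is tested; the expected testing
intensity still tracks presumed risk.

## Dose conversion

Opioid regimens are expressed in morphine milligram equivalents per day
(MME/day): each drug's daily dose times an equianalgesic factor, summed over
drugs. Published equianalgesic sources disagree in detail and clinical
deployments differ; reproducibility, however, requires a pinned table. We
therefore ship a versioned default (`inst/extdata/conversion_table.yaml`)
using the widely adopted CDC-2016-style factors — oxycodone 1.5,
hydrocodone 1, hydromorphone 4, oxymorphone 3, codeine 0.15, tramadol 0.1,
tapentadol 0.4, transdermal fentanyl 2.4 MME per mcg/hr, and a four-tier
methadone schedule (≤20 mg/day ×4, ≤40 ×8, ≤60 ×10, above ×12) — and make
every factor overridable by configuration. Morphine is pinned to exactly 1;
a table violating that, or with non-positive factors or non-increasing tier
bounds, is rejected at load time.

Two conventions matter and are fixed here: doses are mg/day except for
transdermal rate formulations (mcg/hr), flagged per drug; and prescriptions
of the *same* drug are pooled before a tier lookup (tiering reflects
per-drug pharmacology) while different drugs never pool.

## Stratification

The base category comes from the daily dose: `[0, 40)` low, `[40, 100]`
moderate, `(100, ∞)` high. The band edges follow the strict/inclusive
reading of the inequalities "<40, 40–100, >100": 40 and 100 belong to the
middle band. Three binary clinical factors — age under 45 years at the
visit, concomitant benzodiazepine prescription, and a persistent flag set by
any past inconsistent test — escalate the category by exactly one level when
*any* of them holds (one step regardless of how many), saturating at
high+. The base band never emits high+, so escalation applied once is the
only route there, and double escalation cannot occur by construction.
Missing risk-factor values are rejected, not imputed: silently assuming "no
benzodiazepine" in a safety tool is worse than failing loudly.

The test recommendation is one Bernoulli draw per visit at the category's
probability — 0.25, 0.33, 0.50, 0.60 by default. "33%" is implemented as the
literal 0.33 rather than 1/3, since that is the stated frequency; either
choice is configurable. All draws are consumed from an explicitly seeded
stream so a run is exactly reproducible; `recommend_tests(seed=)` isolates
its draws from the caller's RNG state.

## Toxicology classification

A panel is the set of analytes detected at a visit. After removing excluded
analytes (THC by default, following current guidance that a THC finding
should not drive opioid-compliance decisions), the ruling is *consistent*
iff the panel contains at least one analyte expected under the prescribed
opioids (parent or metabolite, via a versioned metabolite map such as
codeine → morphine, oxycodone → oxymorphone/noroxycodone) and contains no
unprescribed opioid analyte and no illicit substance (including the
heroin-specific 6-monoacetylmorphine marker). Each violated condition is a
reason code; all fired reasons are retained, and a single `primary_reason`
is designated by the fixed priority **illicit > unprescribed opioid >
negative for prescribed**. The priority is a design choice: single-label
tabulations of such programmes partition inconsistent tests into exactly one
row each, and ordering by clinical severity is the defensible default when
no ordering is otherwise specified. Benzodiazepine findings never change the
status — the consistency definition names only opioids and illicit
substances — but are carried as annotations. Specimen type (urine vs oral
fluid) is reporting metadata only; detection-window pharmacokinetics are out
of scope.

## The synthetic cohort generator

No patient-level data accompany the reference evaluation, so the package
ships a generator whose defaults *are* the study conditions it emulates:
320 patients, ages normal (57, 12) floored at 18, daily MME log-normal with
mean 70 and SD 66, benzodiazepine prevalence 0.284, visits per patient
truncated negative-binomial with mean 979/320 ≈ 3.06 (dispersion 2, an
assumption — the real visit distribution is unpublished), oral-fluid share
0.114, THC positivity 0.122 independent of everything else, and an entry
history-flag prevalence of 0.

Outcomes follow a patient-random-intercept logistic model:
`logit P(inconsistent) = logit(0.044) + effect(category) + b_i`, with
`b_i ~ N(0, 0.5²)` and category effects `log 2.1` (moderate) and `log 2.0`
(high, high+) against low — the baseline anchored to the low-risk rate and
the effects to the adjusted odds ratios the reference evaluation reported.
The random-intercept SD of 0.5 (latent-scale intraclass correlation ≈ 0.07)
is our choice of a realistic within-patient correlation for repeated
compliance outcomes; the marginal model is the GEE's target, and a
conditional-vs-marginal attenuation of a few percent at this SD is accepted
and visible in the recovery tests' tolerance. Inconsistent panels realise
one of the three mechanisms with weights 31:36:9 (the pooled reason
distribution of the reference counts): an empty panel, the expected set plus
an unprescribed opioid parent, or plus an illicit analyte. Every synthesised
panel is then run through the actual classifier, so simulated verdicts
round-trip by construction *and* by test. The history flag feeds back into
the next visit's category, as in deployment; note this makes escalated
categories slightly enriched in high-intercept patients, a realistic feature
of the adaptive policy rather than a bug.

What the generator does *not* emulate: behavioural adaptation to the
schedule, provider overrides (tests against a "No", 34 of which occurred in
the reference period, are recorded as data in deployment but not modelled),
dropout beyond the fixed visit count, and assay error. Passing recovery
tests therefore show estimator correctness under the stated model, not
robustness to those mechanisms.

## Evaluation

`summarize_visits()` tabulates performed tests per category with half-up
one-decimal percentages (half-up is the convention the reference tables
follow; base R's half-even would, e.g., turn 52/320 = 16.25% into 16.2
rather than the reported 16.3). Reason shares are reported against *both*
denominators — inconsistent tests and all tests — because single-label
tables in this literature mix the two.

Crude odds ratios use the cross-product with a Woolf log-normal interval and
the Haldane–Anscombe +0.5 correction applied to all cells only when some
cell is zero. These visit-level contrasts ignore clustering and are clearly
labelled as such.

The cluster-aware analysis is a logistic GEE, written in-package: Fisher
scoring on the Liang–Zeger estimating equations with moment re-estimation of
the dispersion and, for the exchangeable structure, of the common
within-patient correlation between steps; the exchangeable working inverse
is applied in closed form so all per-cluster sums are `rowsum()` reductions.
Variance is the cluster-robust sandwich without small-sample correction.
Exchangeable is the default working correlation (standard for repeated
binary outcomes; independence is available, and the sandwich keeps inference
valid under either). "Visit" enters as a continuous 1-based index by
default. Convergence is declared at a relative coefficient step below 1e-10
(cap 100 iterations); rank-deficient designs (a THC indicator with no
positive tests, a constant column) have the aliased terms dropped from the
scoring step and reported as `NA` with the fit flagged, and an outcome with
no events is flagged `converged = FALSE` rather than an error. With one
observation per cluster or independence working correlation the estimator
reduces to ordinary logistic maximum likelihood, which the tests verify
against `glm()`, and the sandwich is verified against an independent
implementation (`sandwich::vcovCL`).

`collapse_categories()` applies a total relabelling scheme to visits or to a
statistics table, enabling the two-band (low vs merged high) secondary
analysis; counts are conserved by construction. The 20-MME alternative
cutpoint analysis is the same pipeline with `policy(dose_cutpoints = c(20,
100))`.

## Problem sizes and numerical choices

The shipped tests exercise: the full 24-case stratification truth table
against an independently coded oracle plus the band edges 0, 39.99, 40, 100,
100.01; all 1024 panels over a 10-analyte dictionary for the classifier
invariants (THC neutrality, expected-panel completeness, illicit
monotonicity, reason soundness); calibration of each recommendation
frequency over 10,000 draws within the exact central 99% binomial interval;
all 1296 2×2 tables with cells 0–5 against direct cross-products; and
parameter recovery on 100 replicate cohorts of 5,000 patients, requiring the
cluster-robust 95% intervals to cover the generative odds ratios in at least
93 replicates per term. These sizes give each stochastic check enough
resolution to fail informatively while keeping a full run interactive.

## Known limitations

The equianalgesic factors, metabolite map and substance dictionary are
necessarily opinionated defaults; real deployments must review them.
Quantitative cutoffs, adulteration testing and detection windows are not
modelled, so a "detected" analyte is taken at face value. The GEE
implementation covers the two working structures used here, binomial family
and logit link only. And the reference evaluation's own adjusted odds ratios
cannot be recomputed exactly from published information — the package's
crude contrasts and simulation-based recovery are the honest substitutes.
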