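---
title: "Screening primary-care records for primary antibody deficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening primary-care records for primary antibody deficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padscreen)
```

## The problem

Primary antibody deficiencies (PAD) — common variable immunodeficiency,
IgG subclass deficiency, specific antibody deficiency (SpAD) — are rare
(reported prevalence between 1:1,700 and 1:25,000) and under-diagnosed:
patients typically see their GP for years with recurrent respiratory and
gastro-intestinal infections before anyone measures serum
immunoglobulins. Because the GP record accumulates exactly the coded
breadcrumbs that precede a diagnosis (antibiotic prescriptions, ICPC
infection codes, visit frequency), a weighted-item risk score over those
records can triage a whole practice population and point laboratory
testing at the few patients most likely to be affected.

`padscreen` implements that screening system end to end: the scoring
engine, the exclusion and censoring logic, score refitting on a labelled
high-risk subset, ROC-based cut-off derivation, immunoglobulin flagging
and referral advice, a two-step screening workflow with yield and cost
arithmetic, and a synthetic-population generator that makes all of it
testable without access to a real general-practice database.

## The risk score

Each patient's score is

$$ S = \sum_{c=1}^{8} w_c \sum_{i \in c} w_i \, f_i(\text{record}) $$

where $c$ ranges over eight categories (antibiotic prescriptions,
respiratory tract infections, GI complaints, other infections,
auto-immune symptoms, malignancy/lymphoproliferative and other symptoms,
previously recorded low immunoglobulins, GP-visit frequency), $w_c$ is a
category weight (all 1 in version 1), $w_i$ an item weight, and $f_i$
counts qualifying events under the item's counting rule:
`per_occurrence` ($f_i$ = event count), `once` ($f_i = 1$ if any event),
or `threshold` ($f_i = 1$ if the count reaches a minimum, e.g. six GP
visits in a year). Items may cap their contribution.

Events qualify inside a half-open lookback window
$(\,t_c - L_i,\ t_c\,]$ ending at the patient's *censoring date* $t_c$:
normally the database extraction date, but pulled back to the first
registration of an "ambiguous" diagnosis — one that can cause a
*secondary* antibody deficiency (e.g. lymphoma) — so that contaminated
history never scores. When several ambiguous diagnoses exist we take the
earliest, the most conservative choice. Lookbacks are converted at
365.25 days per year; ages are completed years at the extraction date;
both conventions are fixed and tested because no standard exists for
ICPC-coded exports.

Code matching is exact, or by prefix at a sub-code boundary ("B90"
matches "B90.01"), or by plain prefix for dot-free systems such as ATC
prescription codes ("J01" matches "J01CA04"). Ranking breaks ties by
patient id so a "top 400" selection is a reproducible total order.

The shipped default catalog (`default_scoring_config()`) is a condensed,
deliberately simple stand-in: the category structure, lookbacks and
counting rules follow the validated design, but the per-item weights of
the original 107-item catalog are not public, so ours are a documented
placeholder scheme living entirely in an editable YAML file. Any
deployment against real data should substitute its own calibrated
catalog via `load_scoring_config()`.

## Exclusions

Code-based exclusion rules (HIV, leukaemia, multiple myeloma, cystic
fibrosis, severe addiction, prior immunodeficiency, anorexia/bulimia)
run automatically over the whole population before ranking; rules
without a reliable code (pregnancy, current chemotherapy, cirrhosis,
short life expectancy...) can only fire at the manual-screening stage
through a record's `manual_exclusion_flags`. The screened age window is
12–70 completed years: PAD usually presents in the second to fourth
decade, and paediatric presentations differ enough to need their own
cut-offs.

## Refitting the score (versions 2–4)

Within the high-risk subset that a broad score selects, that same score
discriminates poorly — everyone there is, by construction, high-scoring.
Three refit procedures sharpen it, all penalized logistic regressions of
PAD status with seeded, stratified 10-fold cross-validation over a
100-value penalty path, features standardized to mean 0, SD 1 (ridge and
lasso are scale-sensitive), and coefficients reported on the
standardized scale. Repeated calls with the same seed are bit-identical.

**Version 2** fits a ridge model on the eight category scores at the
one-standard-error penalty and snaps each coefficient to a discrete
weight grid, by default {0.5, 1, 2}. The mapping
(`map_weights_to_grid()`) divides each coefficient by the median
coefficient and takes the nearest grid value, so categories of typical
importance stay at 1 while clearly weaker or stronger ones move down or
up; it is monotone (a larger coefficient never gets a smaller weight).
We chose ratio-to-median rather than a tercile split because a tercile
forces balanced thirds, which cannot express the published pattern of
one demoted, three unchanged and three promoted categories. Categories
constant in the subset carry no information and keep their base weight,
with a warning.

**Version 3** first tames the item count: a principal component analysis
of the centered (unscaled) patient × item matrix retains components with
eigenvalue ≥ 1 (at least one is always kept) and assigns each item to
the component of its largest absolute loading; items absent from the
data fall back to a clinical grouping supplied by the caller. Loadings
are taken on the covariance scale because the inputs are same-scale item
indicators. Stage 1 then ridge-fits group weights on per-group score
sums; stage 2 ridge-fits category weights on the group-reweighted
category scores. Negative fitted weights are clamped to zero in the
resulting config — a score weight cannot be negative — while the raw
coefficients remain in the coefficient table. If stage 1 finds no
informative group at all, category weights stay at base and the fit
warns rather than fabricating structure.

**Version 4** combines the version-3 total score with candidate
covariates that were unavailable or ambiguous at development time
(immunosuppressant use in the past 4 years, a COPD or malignancy code,
≥ 6 GP visits per year, the 10-item Early Warning Signs questionnaire
score) in a lasso. The penalty follows the one-SE rule, falling back to
the minimum-deviance penalty when the 1SE model retains nothing; the
retained variables *are* algorithm version 4.

## Evaluation

`auc_roc()` uses the rank (Mann–Whitney) formulation with ties counted
one half, so it equals exhaustive case–control pair counting exactly.
The default confidence interval is a seeded stratified percentile
bootstrap (2,000 replicates, cases and controls resampled separately);
a DeLong interval is available through pROC. Cut-offs are derived over
the finite candidate set of observed score values plus midpoints of
consecutive values — midpoints are how half-point cut-offs like 15.5
arise — always under the classification rule *score ≥ cutoff*.
`youden_cutoff()` maximizes sensitivity + specificity − 1 with ties
broken toward higher sensitivity, then the lower cutoff;
`full_sensitivity_cutoff()` returns the largest cutoff keeping every
case positive, i.e. the minimum case score. Constant scores produce a
flagged degenerate cutoff rather than an error.

Yield arithmetic (`screening_yield()`) divides stage counts by detected
cases and rounds to the nearest integer, halves away from zero;
`expected_case_range()` turns prevalence bounds expressed as 1:k ratios
into expected case counts the same way.

## Immunoglobulin flagging and referral

`flag_reduced()` compares each measured analyte strictly (<) against
age-banded thresholds (g/L): IgM 0.4 (0.28 up to age 16), IgA 0.7, total
IgG 7 (5.2 up to 16), IgG1 4.9 (3.7 up to 16), IgG2 1.5 (1.06 up to 18),
IgG3 0.20 (0.18 up to 18), IgG4 0.08 (0.035 up to 18), calculated
globulin 18. The bands follow the reference table literally even though
they differ per analyte (12–16 vs 12–18); for ages 17–18 on analytes
with a 12–16 band — a gap in the source table — we apply the adult
threshold, the conservative reading. Unmeasured analytes yield absent
flags, never positive ones. Calculated globulin derives as total protein
minus albumin when not supplied directly.

Referral advice: any reduction other than IgG4 → refer to immunology; an
isolated reduced IgG4 alone never triggers referral (little clinical
relevance); with normal immunoglobulins, a high refined score — at or
above an explicit SpAD cutoff (e.g. 21.5, ≈ 90% specificity) or in the
top decile of tested scores — still refers, because SpAD presents with
normal levels. An internist-consult branch for incidental elevations is
config-gated and off by default, as no thresholds are published.
Outcome labels partition included patients: confirmed PAD; unlikely PAD
(no advice, valid non-referral, or PAD excluded); inconclusive (invalid
non-referral or indeterminate work-up).

## The two-step workflow and costs

`run_two_step()` chains the pieces: code exclusions → version-1 scores →
step-1 cutoff (default ≥ 17) → version-3 scores within the high-risk set
→ step-2 cutoff (default ≥ 15.5) → manual screening (manual-only
exclusions) → invitation → participation, simulated as an independent
seeded coin flip per invitee since no response model is published. Every
decision lands in a per-patient trace. Stage-count propagation is
deterministic given the inputs and seed; we do not attempt the
multiple-imputation projection behind the published expected counts,
whose model is unavailable.

`estimate_costs()` prices manual record screens, immunoglobulin panels
and specialist work-ups by configurable unit costs (the published
breakdown lists counts, not unit prices). Cost per detected patient is
*truncated*, not rounded, to two decimals — the convention that turns a
total of 52,586.68 over 10 cases into 5,258.66 — so a quoted per-patient
cost is never overstated.

## The synthetic generator

`generate_population()` plants cases at a configurable prevalence
(default 1:5,000, inside the reported range) and draws per-category
event counts from a negative-binomial process — overdispersed relative
to Poisson because the published count IQRs are wide relative to their
medians — over category-specific windows, with uniform dates. Default
rates anchor to the published summaries: cases average ~5 antibiotic
prescriptions and ~5–6 RTI codes per 4 years and attend the GP
frequently; controls sit near 1. Immunoglobulins are log-normal around
the published group medians, so ~50% of cases but only ~4% of controls
fall below the 7 g/L total-IgG threshold. A configurable fraction
(default 8.6%) receives a code-based exclusion diagnosis and a small
fraction an ambiguous (censoring) diagnosis. Codes come from a
documented mini-vocabulary matching the default catalog — no attempt at
full ICPC coverage, comorbidity correlation structure, free text, or
real-database marginals; passing tests show the machinery is correct
under the stated generating assumptions, not that the default catalog is
calibrated for any real population.

`make_worked_fixture()` is the 12-patient hand-written anchor: every
score is computed independently by hand and committed beside the
fixture, exercising each counting rule, the censoring logic, window
boundaries and both exclusion paths.

## Numerical choices and problem sizes

Tests verify the closed-form metrics against brute-force enumeration on
instances of n ≤ 50, score totals against an independently coded
double-loop oracle, and the simulation claims at desk scale: populations
of 300–10,000 (10,000 only for rate calibration), refit subsets of
120–400 rows, 50–100 seeded replicates for recovery rates. These sizes
were chosen to make the statistical assertions stable at conventional
tolerances while keeping the default suite quick to run.

Known limitations: the default item weights are placeholders, not the
validated catalog; version-2/3 weights depend on the labelled subset's
composition and should be externally validated before use; the ICPC
dialect is the Dutch sub-code style implied by codes like "B90.01" and
no ICPC↔ICD mapping is attempted.
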