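# padscreen

Case-finding for **primary antibody deficiency (PAD)** in coded
primary-care electronic health records.

PAD (CVID, IgG subclass deficiency, specific antibody deficiency) is
rare — reported prevalence 1:1,700 to 1:25,000 — and typically diagnosed
5–10 years after symptoms begin. The GP record already contains the
warning signs in coded form: antibiotic prescriptions, ICPC codes for
recurrent respiratory and gastro-intestinal infections, high visit
frequency. `padscreen` turns those records into a ranked risk score and
a two-step screening workflow that points serum immunoglobulin testing
at the few patients most likely to be affected.

The package is aimed at clinical epidemiologists and health-informatics
teams who want to run, refit or stress-test this kind of EHR screening
algorithm — on their own ICPC-coded extracts or on the bundled synthetic
populations.

## The score

For each patient,

    S = sum over categories c of  w_c * sum over items i in c of  w_i * f_i(record)

with eight categories (antibiotic prescriptions, RTIs, GI complaints,
other infections, auto-immune symptoms, malignancy/lymphoproliferative
and other symptoms, previously recorded low immunoglobulins, GP-visit
frequency). `f_i` counts qualifying events inside a half-open lookback
window `(censor_date − L_i, censor_date]`; the censoring date moves back
to the first registration of a diagnosis that can cause a *secondary*
antibody deficiency (e.g. lymphoma). Category weights are all 1 in
version 1; versions 2–4 are refits on a labelled high-risk subset
(ridge-adjusted category weights snapped to a {0.5, 1, 2} grid, a
two-stage ridge over PCA-derived item groups, and a lasso adding new
covariates such as the Early Warning Signs score). Classification is
always `score >= cutoff`.

Everything that defines the score — items, codes, weights, lookbacks,
censoring codes, cut-offs — lives in an editable YAML catalog, not in
code. The shipped default is a documented placeholder scheme (the
original 107-item weight table is not public).

## Worked example

```r
library(padscreen)

fx  <- make_worked_fixture()          # 12 hand-scored patients
cfg <- default_scoring_config()
scores <- score_population(fx$population, cfg, default_exclusion_rules())
scores[, c("patient_id", "score_antibiotics", "score_rti",
           "score_gp_visits", "total", "rank", "excluded")]
#>  patient_id score_antibiotics score_rti score_gp_visits total rank excluded
#>       FIX-G               9.0       6.0               3  22.5    1    FALSE
#>       FIX-C               7.5       0.0               0   7.5    2    FALSE
#>       FIX-D               0.0       6.5               0   6.5    3    FALSE
#>       FIX-H               0.0       1.0               0   6.0    4    FALSE
#>       FIX-B               0.0       0.0               3   3.0    5    FALSE
#>       FIX-F               3.0       0.0               0   3.0    6    FALSE
#>       ...
#>       FIX-E               4.5       0.0               0   4.5   NA     TRUE
#>       FIX-K               0.0       0.0               0   0.0   NA     TRUE
```

FIX-G collects points across five categories and ranks first; FIX-F's
history is censored at a 2019 lymphoma code so only two of five
antibiotic prescriptions count; FIX-E scores 4.5 but is excluded (HIV
code), FIX-K by age. Excluded patients are never ranked.

Yield arithmetic for a screening run (400 records screened, 104 tested,
16 referred, 10 PAD diagnoses):

```r
y <- screening_yield(n_screened = 400, n_tested = 104,
                     n_referred = 16, n_cases = 10)
c(y$nns, y$nnt, y$nnr)
#> [1] 40 10  2
```

— screen 40 records, test 10 patients, refer 2 to find one PAD case.

On a synthetic population with planted cases the version-1 score
separates cases from controls:

```r
g  <- generate_population(generator_spec(n_patients = 2000,
                                         prevalence = 0.02, seed = 1,
                                         force_min_cases = TRUE))
sc <- score_population(g$population, cfg, default_exclusion_rules())
ok <- !sc$excluded
auc_roc(sc$total[ok],
        as.integer(g$ground_truth[sc$patient_id[ok]] == "case"),
        n_boot = 500, seed = 1)
#> <roc_result: AUC 0.923 (95% CI 0.877-0.963, bootstrap)>
```

From there, `run_two_step()` executes the full funnel (exclusions →
version-1 cutoff ≥ 17 → version-3 cutoff ≥ 15.5 → manual screen →
invitation → testing → referral advice) and `estimate_costs()` prices
it; `fit_version2()` / `fit_version3()` / `fit_version4()` refit the
score on a labelled subset.

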