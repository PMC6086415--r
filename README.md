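# nccreri

Additive interaction between time-varying drug exposures and comorbidity
profiles in nested case-control analyses of healthcare claims.

## The problem this package addresses

Clinicians and regulators often need to know whether a drug's risk of an
acute outcome is *amplified* in patients with a particular risk profile.
On the public-health scale that question is additive: do drug and
comorbidity together produce more events than the sum of the events each
produces alone? `nccreri` implements the full analysis chain for this
question in longitudinal claims data, with NSAIDs (celecoxib, diclofenac,
ibuprofen, naproxen, rofecoxib, pooled others), cardiovascular risk
profiles (hypertension, coronary heart disease, previous myocardial
infarction, cardioprotective aspirin use) and acute myocardial infarction
in an elderly insured cohort as the running application.

Real provincial claims are confidential, so the package ships a tested
synthetic claims generator whose per-day event model has *analytically
known* marginal odds ratios and interaction structure. Every downstream
stage — cohort, exposure, matching, regression, interaction inference —
is validated against that ground truth.

## The statistic at the core

From a conditional logistic model with drug main effect β₁₀, profile main
effect β₀₁ and binary product term β₁₁ (log-odds scale), the relative
excess risk due to interaction is

    RERI = exp(β₁₀ + β₀₁ + β₁₁) − exp(β₁₀) − exp(β₀₁) + 1
         = OR₁₁ − OR₁₀ − OR₀₁ + 1

with a delta-method 95% CI from the coefficients' covariance block.
RERI = 0 under exactly additive joint effects; β₁₁ = 0 under exact
multiplicativity. A 95% CI entirely below 0 is read as sub-additive,
entirely above 0 as super-additive.

The surrounding machinery: new-user cohort assembly (age ≥ 66, one-year
washout), first acute MI (ICD-9 410.x, ≥ 3-day stay unless
transfer/PCI), dispensing-to-episode exposure construction with
current/recent/past/none classification under four candidate
parametrizations, 1:10 risk-set matched sampling aligned on follow-up
time, conditional logistic regression fitted from the exact conditional
likelihood by Newton–Raphson, and a staged product-term model-building
procedure (p ≤ 0.2 or deviation from both reference scales; pruning;
AIC selection).

## Worked example

```r
library(nccreri)

cfg <- sim_config(
  n_persons = 4000, study_start = as.Date("1993-01-01"),
  study_end = as.Date("1994-12-31"), age_range = c(66, 74),
  baseline_daily_odds = 8e-4, nsaid_spell_rate = 2.5,
  days_supplied = 30, refills_mean = 4,
  market_shares = c(celecoxib = 0.45, diclofenac = 0.1, ibuprofen = 0.05,
                    naproxen = 0.15, rofecoxib = 0.15, other_nsaid = 0.1),
  interactions = list(list(nsaid = "celecoxib", profile = "chd",
                           structure = "custom", or11 = 10)),
  seed = 7)
pop <- simulate_outcomes(generate_population(cfg))
res <- run_analysis(pop, profiles = c("hypertension", "chd"), seed = 11)
print(res)
```

```
Nested case-control interaction analysis
Cohort: 1196 members ( 2804 excluded ); 292 matched sets
Base-model AIC ranking (best -> binary_use.index_day_only , worst -> daily_dose.index_or_7_prior ):
                       model  k      aic rank
   binary_use.index_day_only 34 826.7840    1
   daily_dose.index_day_only 34 828.6324    2
 binary_use.index_or_7_prior 34 829.2179    3
 daily_dose.index_or_7_prior 34 830.7179    4

Interaction findings (pairs in AIC-selected models):
   analysis          pair reri     lo   hi            classification
    primary celecoxib:chd 7.32  0.939 13.7            super_additive
  secondary celecoxib:chd 6.47  1.141 11.8            super_additive
 chd_strict celecoxib:chd 8.66 -0.499 17.8 exact_additive_compatible
```

Reading the output: 4000 simulated persons yield a new-user cohort of
1196 (the 2804 exclusions are the age, washout, and history filters doing
their job) and 292 matched sets. Among the four candidate NSAID-exposure
parametrizations the binary/index-day base model fits best by AIC, so it
drives the primary analysis; the worst-fitting one drives the secondary.
The celecoxib × coronary-heart-disease pair was simulated with joint odds
ratio 10 against marginals 1.2 and 2.6 — a true
RERI = 10 − 1.2 − 2.6 + 1 = 7.2. The procedure retains the product term
in every analysis and estimates RERI = 7.32 (95% CI 0.94, 13.7) in the
primary analysis: correctly classified super-additive, with the truth
well inside the interval. Under the strict CHD definition the profile is
rarer and the interval widens across 0 — an honest display of how
interaction inference loses power as the joint cell thins. Formal CI
calibration (95% coverage at 500 replicates of ~1000-set studies) is
verified in `tests/testthat/test-acceptance.R`.

`write_analysis(res, dir)` emits `aic_table.csv`, `table2_report.csv`,
`decision_log.jsonl` and `manifest.json`. A thin command-line wrapper over
the same function lives at `inst/scripts/run_analysis.R`.

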