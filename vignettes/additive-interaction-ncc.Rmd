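---
title: "Additive interaction in nested case-control claims analyses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive interaction in nested case-control claims analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nccreri)
```

## The scientific problem

Whether a drug's effect on an acute outcome is modified by a patient's
pre-existing risk profile is a public-health question that lives on the
*additive* scale: what matters for counting events is whether the joint
effect of drug and comorbidity exceeds the sum of their separate effects,
not whether it exceeds their product. `nccreri` implements the complete
analysis chain for asking this question of longitudinal healthcare claims
with a nested case-control (NCC) design, using non-steroidal
anti-inflammatory drugs (NSAIDs) and acute myocardial infarction (MI) in an
elderly insured population as the running application: a synthetic claims
generator with analytically known ground truth, new-user cohort assembly,
outcome and exposure ascertainment, risk-set matched sampling, conditional
logistic regression, and inference on the relative excess risk due to
interaction (RERI).

Because real provincial claims databases are not redistributable, the
package is built to be testable end to end without any external data: the
generator is a first-class, tested module whose event model makes every
downstream estimate checkable against known truth.

## The measure: RERI from a conditional logistic model

For a drug exposure D and a profile C entered in a conditional logistic
model with main effects $\beta_{10}$, $\beta_{01}$ and a binary product
term $\beta_{11}$,

$$\mathrm{RERI} = e^{\beta_{10}+\beta_{01}+\beta_{11}}
  - e^{\beta_{10}} - e^{\beta_{01}} + 1
  = \mathrm{OR}_{11} - \mathrm{OR}_{10} - \mathrm{OR}_{01} + 1 .$$

RERI is 0 under exactly additive joint effects and
$\beta_{11} = 0$ under exactly multiplicative ones. The variance of the
RERI point estimate is obtained by the delta method with gradient
$(\mathrm{OR}_{11}-\mathrm{OR}_{10},\,
\mathrm{OR}_{11}-\mathrm{OR}_{01},\, \mathrm{OR}_{11})$ over the 3×3
coefficient covariance block, and a Wald-type interval
$\mathrm{RERI} \pm 1.96\,\widehat{\mathrm{se}}$. An upper bound below 0 is
read as sub-additive, a lower bound above 0 as super-additive, and an
interval containing 0 as compatible with exact additivity
(`classify_joint_effects()`). With odds ratios this reading is an
approximation that inherits the rare-disease interpretation of NCC odds
ratios as rate ratios; only the direction of RERI, not its magnitude, is
interpreted.

When current exposure is modelled as a continuous daily dose, the model
contains no binary current-use main effect, so the package evaluates
$\beta_{10}$ as *dose coefficient × reference dose*, the reference being
the drug's most common dispensed daily dose in the analysis dataset, and
scales the first gradient component accordingly (`scale10` in
`reri_estimate()`). This mirrors reporting odds ratios "at the most common
dose" and keeps the product term binary throughout.

## Design of the analysis chain

**Cohort.** New users: entry at the first dispensing of a single study
NSAID on/after study start, after 365 days of NSAID-free history with at
least 365 days of data coverage, aged at least 66 completed years at
entry. Aspirin never counts as an NSAID. Exit is the earliest of first
qualifying MI on/after entry, death, end of coverage, study end. Persons
with an MI admission *before* entry are retained — their event feeds the
previous-MI covariate, not the outcome — because a history of MI is itself
one of the profiles of interest.

**Outcome.** An admission qualifies as acute MI when any discharge
diagnosis has ICD-9 prefix 410 and the stay is at least 3 days (admission
day = day 0), unless a transfer flag or a percutaneous-intervention
procedure code (configurable, default prefix 480) explains the short stay.

**Exposure.** Dispensings become episodes of continuous use: daily dose =
strength × quantity / days supplied; same-drug supplies that abut or
overlap merge, an overlapping refill being shifted to start the day after
the previous supply ends (stockpiling honoured); a refill gap beyond the
grace period (0 days for NSAIDs, 7 for aspirin, both configurable) ends
the episode, with bridged gap days exposed at the previous dose; a
dispensing of a different study NSAID terminates the active episode the
day before, so no person-day carries two NSAIDs. At an index date each
drug group is exactly one of current / recent (1–30 days ago) / past
(31–180) / none, assessed in that order; four candidate parametrizations
cross the current window (index day only, or index-or-7-prior with recent
then 8–30) with current coded as binary use or daily dose. When the 7-day
window puts two drugs in current range around a switch, the most recently
supplied drug wins and the other falls to recent, preserving the at most
one-current invariant. Cardioprotective aspirin is an episode at 40–650
mg/day (80 mg every other day = 40 mg/day) overlapping the 30-day
pre-index window.

**Covariates.** Comorbidities are recognised through hospital diagnoses
and marker-drug claims. Defaults: first occurrence any time before index;
mediators on the causal pathway (hypertension, congestive heart failure,
renal failure) only before entry, so that nothing dated in (entry, index]
can move them; COPD and gastrointestinal ulcer marker drugs only in the
365 days before index; corticosteroids, clopidogrel and cardioprotective
aspirin in the 30 days before index. Coronary heart disease (CHD) has a
broad definition (any-position 411–414 diagnosis, revascularisation
procedure, or anti-anginal markers) and a strict sensitivity definition
(leading-position 411/413/414, a 480/481 procedure, or markers within 30
days); strict implies broad by construction. The marker-drug class lists
are explicit, configurable stand-ins — claims databases differ in their
drug-algorithm details — and are not a claim about any particular source
system.

**Matching.** Risk-set (incidence-density) sampling: for a case with
follow-up $t$, eligible controls share sex, entry month/year, entry age
within ±1 year, and are still at risk at their own entry + $t$; up to 10
are drawn without replacement and assigned index = entry + $t$, so control
follow-up equals case follow-up exactly. Future cases serve as earlier
controls; sets with 1–9 controls are retained (the conditional likelihood
handles variable set sizes); cases with no eligible control are dropped
and logged.

**Conditional logistic regression.** `cond_logit()` maximises the exact
conditional likelihood (softmax of the case's linear predictor within each
set) by Newton–Raphson with analytic gradient and Hessian, log-sum-exp
stabilisation, step-halving, convergence at gradient max-norm `1e-8`
(Newton is affine covariant, so mixed binary/dose column scales do not
harm convergence), at most 100 iterations, covariance = inverse observed
information. Columns constant within every set are dropped with a warning;
coefficients passing |β| > 15 are flagged as separation, never returned
silently as converged. `survival::clogit` is used in the test suite as an
independent cross-check only.

**Model building.** Candidate drug-by-profile product terms are screened
individually and jointly: a term is kept when its Wald p ≤ 0.2 or when it
(approximately) deviates from exact additivity or exact multiplicativity,
operationalised as the 80% CI for RERI excluding 0 or the 80% CI for
$e^{\beta_{11}}$ excluding 1 — the 80% level deliberately echoes the
p ≤ 0.2 retention spirit, since "approximately deviates" admits no unique
definition. Kept terms whose 95% intervals are compatible with *both*
scales are pruned. The final model minimises AIC over the base model and
subsets of the remaining terms (all subsets up to 4 terms, otherwise full
and leave-one-out), ties broken toward fewer parameters. No
multiple-testing correction is applied; the decision log records every
test so the number of comparisons is visible.

**Pipeline.** `run_analysis()` fits all four base parametrizations, ranks
them by AIC, runs the interaction analysis on the best (primary) and worst
(secondary) parametrizations, and repeats the primary with the strict CHD
definition. On desk-scale synthetic data rare confounder columns can
quasi-separate; the base fit therefore tightens an informativeness filter
(a column must vary within at least 8 sets, then 15, 25, 40) and, as a
last resort, drops separating columns — with hundreds of thousands of
members, as in a real claims cohort, this ladder never triggers.

## The synthetic generator: what it emulates and what it does not

`generate_population()` draws an elderly insured population (default ages
60–90 at study start, admitting under-66 persons so the age filter is
exercised), coverage windows starting up to 3 years before or 1 year after
study start, NSAID treatment spells beginning at a person-specific
first-use date (a new-user initiation pattern) with refills, dose changes,
switches mid-supply, short refill gaps and longer intermittent pauses,
chronic aspirin streams with 0–12 day gaps around the 7-day grace,
comorbidities at prevalences typical of elderly NSAID users (hypertension
42%, CHD 30%, previous MI 6.5%, ...) encoded through both a
hospitalization diagnosis and marker-drug dispensings, and concomitant
corticosteroid/clopidogrel claims.

`simulate_outcomes()` runs a per-day Bernoulli event model: the day's MI
odds are the baseline odds (default 3e-5/day ≈ 1%/year) times the odds
ratio of each current drug exposure (binary, or log-linear in dose
relative to a reference dose, optionally persisting `effect_window_days`
past supply end) and of each comorbidity present, except that for
configured interaction pairs the joint drug-profile multiplier is exactly
the implied OR$_{11}$: OR$_{10}$+OR$_{01}$−1 (exactly additive, ground
truth RERI = 0), OR$_{10}$·OR$_{01}$ (exactly multiplicative, ground-truth
product coefficient 0), or a custom value. First events become 410.x
admissions, a configurable fraction with stays under 3 days of which a
configurable share carries transfer/PCI rescues, exercising the outcome
filter. All randomness flows from one seed with a sub-stream per table, so
outputs are byte-identical across runs.

`simulate_ncc_study()` is a condensed companion for estimator calibration:
time-fixed exposure and profile, geometric event times from the same odds
model, and genuine risk-set sampling. It exists because coverage studies
need a thousand fits, not because the full generator is untrustworthy.

What the generator does *not* emulate: over-the-counter drug use, market
shares of any real jurisdiction, prescription pricing fields, dependence
between comorbidities, seasonal or calendar trends, and out-of-hospital
fatal events. Tests passing on this generator therefore demonstrate the
*machinery* — episode logic, matching, likelihood, RERI calibration — not
robustness to every bias structure of real claims data (confounding by
unrecorded factors, differential misclassification, adherence behaviour).

## Numerical and degenerate-input choices

- Calendar arithmetic is integer days; "one year" is 365 days; ages are
  completed years.
- "At least 3 days" of stay means discharge − admission ≥ 3.
- Day counting: index − last-exposed-day = 0 is the index day; recent
  means 1–30 (or 8–30), past 31–180.
- The conditional likelihood is evaluated with log-sum-exp; the matched
  pair/set likelihood is exact, not approximated.
- Same-day fills of two distinct NSAIDs (undefined under the no-concurrency
  rule) resolve deterministically: the stream is ordered by date, drug
  name, dose and supply, and the switch rule truncates the earlier-sorted
  drug to an empty segment.
- AIC ties break toward fewer parameters; model enumeration order is
  deterministic, so reports are byte-reproducible at fixed seed.
- Empty inputs (no dispensings, no hospitalizations, zero persons) yield
  empty, correctly typed results rather than errors; malformed ICD codes
  fail loudly with row numbers.

## Problem sizes used by the test suite

The suite sizes its simulations for a single CPU: conditional-likelihood
oracle checks use 100 datasets of up to 10 sets; CI-calibration studies
use 500 replicates per interaction structure with about 1000 sets of 11
members each; the exposure fuzzer draws 100 000 random dispensing
streams; the parametrization-ranking study uses 50 replicates of a
2500-person, one-year population with short (7-day) fills, frequent 8–30
day pauses, a strong dose effect (OR 8 at the reference dose) acting for
7 days past supply end — conditions chosen so the one-year window makes
the current-exposure window identifiable at desk scale, where a real
cohort would have two orders of magnitude more sets. Under those
conditions the dose/7-day-window model attains the best AIC in well over
80% of replicates.

## Known limitations

- Dose effects are log-linear by construction in the generator and the
  dose parametrizations; no spline or threshold dose-response is fitted.
- Three-way interactions are out of scope, as is any bias-corrected or
  Bayesian RERI estimation.
- The delta-method CI is symmetric; for very sparse joint cells the
  bootstrap or profile likelihood would be preferable (the test suite
  verifies delta-vs-bootstrap agreement only in well-behaved regimes).
- Marker-drug algorithms and the PCI/CABG code lists are configurable
  defaults, not validated claims algorithms.

## A minimal worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  n_persons = 4000, study_start = as.Date("1993-01-01"),
  study_end = as.Date("1994-12-31"), age_range = c(66, 74),
  baseline_daily_odds = 8e-4, nsaid_spell_rate = 2.5,
  market_shares = c(celecoxib = 0.45, diclofenac = 0.1, ibuprofen = 0.05,
                    naproxen = 0.15, rofecoxib = 0.15, other_nsaid = 0.1),
  interactions = list(list(nsaid = "celecoxib", profile = "chd",
                           structure = "custom", or11 = 10)),
  seed = 7)
pop <- simulate_outcomes(generate_population(cfg))
res <- run_analysis(pop, profiles = c("hypertension", "chd"), seed = 11)
print(res)
write_analysis(res, "analysis_out")
```

The README shows the printed result: the simulated super-additive
celecoxib-by-CHD pair (true RERI 7.2) is retained in every analysis and
correctly classified in the primary and secondary ones, while the strict
CHD sensitivity analysis — where the profile is rarer — returns a wider
interval across 0.
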