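---
title: "Methods: microsimulating national diabetes screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsimulating national diabetes screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabscreen)
```

# The modelling problem

Community-based diabetes screening programs flag "high-risk" adults with a
cheap first-stage test — a risk-scoring questionnaire or a point-of-care
random glucose measurement — and refer them to a confirmatory laboratory
fasting glucose test. `diabscreen` asks what such a program delivers at
national scale: how many undiagnosed cases each instrument finds and misses,
how many false positives it pushes into confirmatory testing, what the
program costs per case found, and how much 20-year complication risk
best-case treatment of the detected cases can remove. Because no nationally
representative cohort exists, the population itself has to be synthesized
from heterogeneous sub-national studies; the package makes that synthesis —
and every downstream claim — a testable computation.

# Stage 1: disease burden from a synthetic evidence base

## Meta-regression

Per-stratum outcome probabilities (total diabetes prevalence, probability of
being undiagnosed given diabetes, hypertension and obesity prevalence) are
estimated by inverse-variance weighted mixed-effects meta-regression of
study-level proportions on the study's moderator composition (share aged
45–65, share male, share urban, income-tertile shares) and calendar year,
with a Normal between-study effect. `fit_meta_regression()` delegates the
fit to `metafor::rma` with REML estimation of the between-study variance.

Design choices that were genuinely open:

* **Scale.** The outcome model can be written on the raw proportion scale,
  but raw-scale stratum predictions can leave [0, 1]. The default therefore
  fits on the **logit scale** with delta-method sampling variances
  (`var[logit p] ≈ var[p] / (p(1−p))²`), which keeps every prediction a
  probability; `scale = "linear"` is retained for fidelity to the raw
  formulation, with out-of-range predictions clamped to [0, 1] and the
  number of clamped cells reported via a message and an attribute — never
  silently.
* **Moderator coding.** Shares are fractions with one reference level
  dropped per family (age 25–44, female, rural, low income) to avoid the
  dummy-variable trap; a singular design aborts with the collinear columns
  named. Main effects only: interactions among moderators are not
  estimable with realistic study counts and are deliberately excluded.
* **Heterogeneity estimator.** REML, with `method = "FE"` exposed so the
  fixed-effect limit can be checked against a hand-rolled weighted
  least-squares oracle (the test suite does this at tolerance 1e-8).
* **Proportions of 0 or 1** in a study receive a 0.5-event continuity
  correction before the logit transform.

Uncertainty propagates by drawing coefficient vectors from the multivariate
Normal defined by the fitted (β, Σ) per outcome (`sample_surface()`), then
mapping each draw to the 24-stratum surface.

## The synthetic evidence base

The published sub-national studies are not machine-readable, so
`simulate_cohort_studies()` generates an evidence base with known ground
truth: each synthetic study draws moderator shares from Beta/Dirichlet
mixing distributions, its true outcome from the logit-linear predictor plus
Normal between-study noise (SD `tau`, per outcome), and its observed
proportion from a binomial sample at the study's size, recording sampling
variance p(1−p)/n. This makes coefficient recovery and credible-interval
coverage directly testable: the suite checks 2-standard-error coverage of
the generator's coefficients across 20 seeds and ≥90% coverage of the
known national prevalence by the 95% credible interval over 50 repeated
synthetic experiments at the default evidence-base size of 58 studies.

The generator's default truth encodes the setting it emulates: national
adult diabetes prevalence near 12% with a strong urban excess (roughly 18%
urban vs 9% rural), about 73% of diabetes undiagnosed — higher among women,
rural and low-income strata — and modest secular trends. These constants
are the study conditions of the package, set once; they are not fitting
targets.

# Stage 2: the microsimulated population

`make_demographics()` splits a national total (default 586 million adults
aged 25–65 in 2015) over 24 strata from per-family shares; the default uses
62% aged 25–44, equal sexes, one-third urban, and income tertiles equal by
construction. `build_population()` allocates `n_persons` simulated
individuals to strata by largest-remainder rounding (low-variance, and no
positive-weight stratum is left empty at reasonable `n_persons`), assigns
diabetes and prior-diagnosis status by per-stratum Bernoulli draws, and
gives every person the weight (stratum millions) / (stratum sample count),
so weighted tallies are national millions and weight is conserved exactly
through every downstream stage.

Risk-factor profiles come from a **Gaussian copula**: one standard
multivariate Normal draw per person (fixed correlation matrix, unit
diagonal, validated positive semi-definite) mapped through status-conditional
marginals — Normal for systolic/diastolic pressure, BMI and waist;
log-Normal for random glucose, fasting glucose, HbA1c and LDL. Waist gets a
±4.5 cm sex offset; age is uniform within the stratum band (no published
within-band density to encode); family history, physical activity, smoking
and CVD history are status-conditional categorical draws, constant across
strata. Diabetic glucose marginals stochastically dominate non-diabetic
ones, so a higher measured glucose genuinely signals disease. The diabetic
random-glucose marginal (median 8.2 mmol/l, log-SD 0.45) was chosen so the
6.1 mmol/l glucometer threshold sits near the ROC-optimal corner on the
national population, as it should for a threshold that was itself derived
by ROC analysis.

Eligibility: previously diagnosed persons are excluded from screening
(`eligible_subset()`), reproducing the "586 million total, ~567 million
eligible" accounting when ~19 million are previously diagnosed.

**Truth definition.** A screening "case" is a person with diabetes, no
prior diagnosis, *and* fasting glucose at or above 7.0 mmol/l — the
confirmatory criterion. Persons diabetic by other criteria but below the
fasting threshold count as non-cases, because the program could never
confirm them.

# Screening instruments

The three questionnaire instruments ship as declarative YAML
(`inst/extdata/instruments/`): each item maps a factor into ordered
categories with integer points; a total at or above the cut point
(Chaturvedi 16/29, Mohan 60/100, Ramachandran 21/42 — the cut is inclusive)
is a positive screen. Encoding decisions:

* Blood pressure (Chaturvedi) scores the worse of the systolic and
  diastolic categories (an `or` across two sub-scales, implemented as a
  max).
* Printed waist bands leave 1-cm gaps between categories; they are encoded
  as contiguous intervals (right-closed for Chaturvedi, left-closed
  elsewhere) so categories are exhaustive over continuous waist. Age bands
  are left-closed for the same reason.
* Ramachandran's "family history, unspecified members" scores any positive
  family history; its two-level activity item maps `neither` (no exercise,
  no strenuous work) to sedentary.

The glucometer screen adds Normal device error (Bland–Altman SD
0.9 mmol/l, additive — the quoted SD is on the measurement scale) to true
random glucose, fresh per encounter, and is positive at ≥ 6.1 mmol/l.
Serial combination requires both tests positive with the second stage
evaluated (and costed) only among first-stage positives; parallel requires
either. Conjunction is classification-symmetric in the order of tests, but
staged test counts — and therefore costs — are not.

# ROC recalibration

`roc_sweep()` computes weighted sensitivity/specificity at every achievable
threshold (each distinct score; a 0.1 mmol/l grid for the glucometer) plus
sentinels beyond the range so both ROC endpoints are present, and
`recalibrate_cutpoint()` picks the threshold maximizing sensitivity ×
specificity. Ties break toward the **higher-specificity** threshold: the
binding constraint in this setting is confirmatory-testing burden, so fewer
referrals is the right tie-break. Weighted (national) persons are used
throughout — recalibration should reflect the population the program
actually faces. Single-class populations are rejected rather than returning
a degenerate curve.

# Costs

Unit costs are **documented placeholders**, not authoritative WHO-CHOICE
values: questionnaire US$0.05, glucometer US$0.15, confirmatory laboratory
test US$1.50 per person, overhead US$0.01 per person screened per year
(2014 US$). They are sized so confirmatory testing dominates, which fixes
the qualitative ordering of strategy costs (glucometer cheapest despite its
dearer first stage); every entry is overridable via `make_unit_costs()`.
The screened population is spread evenly over the 10-year horizon, so the
present value of the program is the undiscounted total times
`discount_factor(h, r) / h`, with `discount_factor()` the geometric sum
Σ(1+r)^−t over t = 0…h−1 (8.7861 at 3% over 10 years). Overhead scales
with persons screened per year rather than per camp, since camp counts are
not modelled.

# Complications and NNST

The 20-year complication stage is a **pluggable interface**
(`risk_equations()`): any per-endpoint risk function of a profile can be
supplied, so externally published outcome-model coefficient sets can be
dropped in. The shipped default is a parametric stand-in — a logistic
function of non-negative-coefficient biomarker deviations (SBP above
120 mm Hg per 10, HbA1c above 5.5%, LDL above 2.6 mmol/l, BMI above 22 per
5, smoking, age above 50 per 10) for five endpoints (heart disease, stroke,
blindness, diabetic ulcer, renal failure) — with baselines giving a typical
untreated screen-detected case roughly a one-in-five 20-year heart-disease
risk and single-digit microvascular risks. Deviations are floored at zero
so treatment to target removes excess risk but never turns protective.

Best-case treatment (`apply_treatment()`) clamps SBP to ≤140 mm Hg, LDL to
≤2.6 mmol/l (≤1.8 with CVD history — profiles carry a `cvd_history` flag
for exactly this rule) and HbA1c to ≤7%, never raising anything. `nnst()`
reports, per endpoint, the weighted-mean absolute risk reduction and its
reciprocal (the NNST), plus the fraction of detected cases avoiding *any*
complication, computed under conditional independence of endpoints given
the profile. The per-endpoint minimum NNST and the any-complication
fraction answer different questions and are both reported; they are not
forced to agree. `cost_per_complication_prevented()` divides total
screening cost by (true positives × fraction avoiding), excluding treatment
costs.

# Uncertainty propagation

`run_pipeline()` runs the full chain per Monte Carlo draw: sample a
coefficient vector per outcome, rebuild the population (so person-level
sampling noise is included alongside parameter uncertainty), evaluate every
configured strategy, cost it, and run the complication stage. Per-draw
seeds are pre-drawn from the master seed, so each draw is reproducible
independently of execution order; draw-level failures are discarded with a
count reported. Outputs aggregate to 95% credible intervals — median point
estimate with 2.5th/97.5th percentile bounds, type-7 interpolation (the
position-(n−1)p+1 rule), mean also emitted. A draw count of 10,000 matches
the production-grade setting; the desk default is 500 draws of 200,000
persons, which completes in roughly 12 minutes on one core and stabilizes
the interval endpoints to well within the Monte Carlo noise of the
quantities reported. The test suite exercises reduced sizes (thousands of
persons, tens of draws) chosen so every property it asserts is comfortably
outside Monte Carlo error at a fixed seed.

# What the synthetic inputs do and do not establish

The generator reproduces the *statistical structure* the analysis assumes:
simplex moderator shares, logit-linear outcome effects with between-study
heterogeneity, binomial sampling error, correlated biomarkers with
status-conditional shifts. Passing tests therefore demonstrate that the
estimation and screening machinery is correct and well-calibrated **under
the stated model**. They do not establish that real Indian cohort studies
follow that model: real evidence bases have non-random study composition
(urban and wealthier areas over-represented), outcome definitions that
drift across decades, and biomarker joint distributions with features a
Gaussian copula cannot express (threshold artefacts, skewed tails,
stratum-varying correlations). National point estimates produced from the
synthetic defaults are illustrative of the setting, not estimates for any
real year.

# Known limitations

* The complication stage's default equations are a documented stand-in, not
  a validated outcome model; absolute NNST levels should be read as
  order-of-magnitude under the default parameters.
* No longitudinal dynamics: prevalence, diagnosis and biomarkers are a 2015
  cross-section; screening is evaluated as a one-shot program.
* Family history and physical activity are status-conditional but
  stratum-constant, which understates geographic clustering of behaviour.
* Costs exclude treatment and are linear in throughput; camp-level fixed
  costs and congestion effects are out of scope.
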