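# diabscreen

Microsimulation of large-scale community-based diabetes screening strategies,
built for health-policy modellers and biostatisticians studying screening
programs in India and similar settings.

Mass screening for type 2 diabetes is typically run through health camps that
apply either a short risk-scoring questionnaire or a point-of-care random
glucose test, referring everyone flagged "high risk" to a confirmatory
laboratory fasting glucose test. Whether that is a good use of a health
system depends on quantities no single cohort study can give you: national
sensitivity and specificity across very heterogeneous urban/rural and income
strata, the confirmatory-testing burden created by false positives, the cost
per case found, and how much complication risk early treatment can actually
remove. `diabscreen` estimates all of these by simulation.

## The model

The pipeline has three stages:

1. **Disease burden.** A synthetic national adult population (25–65 y) is
   stratified by age band × sex × urban/rural × income tertile (24 strata).
   Per-stratum probabilities of diabetes, and of being undiagnosed given
   diabetes, come from an inverse-variance weighted mixed-effects
   meta-regression of study-level outcome proportions *y<sub>j</sub>* on
   study moderator shares and calendar year,

   *y<sub>j</sub>* = β₀ + β₁x₁ⱼ + … + βₙxₙⱼ + β<sub>y</sub>·year + u<sub>j</sub> + ε<sub>j</sub>,

   fitted by REML on the logit scale with delta-method sampling variances
   (`metafor` under the hood). A synthetic cohort-study generator with known
   ground truth stands in for the published evidence base, so coefficient
   recovery and interval coverage are testable end to end.

2. **Screening.** Each simulated person carries a correlated risk-factor
   profile (Gaussian copula over blood pressure, BMI, waist, glucose
   measures, HbA1c, LDL; status-conditional categorical factors) and a
   national sampling weight. Three questionnaire instruments — Chaturvedi,
   Mohan (Indian Diabetes Risk Score) and Ramachandran, encoded as
   declarative YAML scoring rules — plus random glucometer testing
   (threshold ≥ 6.1 mmol/l, additive device error SD 0.9 mmol/l) are applied
   singly, serially, or in parallel; positives receive the confirmatory
   fasting test (≥ 7.0 mmol/l). Weighted confusion counts give sensitivity,
   specificity, predictive values, the number needed to screen (NNS =
   eligible screened per undiagnosed case found), and the false:true
   positive ratio. ROC sweeps recalibrate each instrument's cut point by
   maximizing sensitivity × specificity.

3. **Consequences.** Discounted program costs (10-year horizon, 3% annual
   rate, 2014 US$) are charged per stage — serial second-stage tests only
   among first-stage positives — and complication yield among detected cases
   is assessed with pluggable 20-year risk equations under best-case
   treatment targets (SBP ≤ 140 mm Hg, LDL ≤ 2.6/1.8 mmol/l, HbA1c ≤ 7%),
   giving the number needed to screen and treat (NNST) per complication
   prevented. A Monte Carlo wrapper redraws model coefficients and the
   population each iteration and reports 95% credible intervals for every
   output.

## Worked example

```r
library(diabscreen)

chat <- load_instrument("chaturvedi")
score_instrument(chat, data.frame(
  age = 45, sbp = 125, dbp = 70, sex = "male", waist = 85,
  family_history = "one_parent_or_sibling"))
#>   score positive
#> 1    22     TRUE

truth   <- default_truth()
studies <- simulate_cohort_studies(truth, 58, seed = 11)
fits    <- sapply(names(truth$coefficients), function(oc)
  fit_meta_regression(studies, oc), simplify = FALSE)
surface <- predict_surface(fits, 2015)
pop <- build_population(make_demographics(586), surface,
                        truth$risk_factors, 50000, seed = 3)
pop
#> Microsimulated population: 50000 persons representing 586 million
#>   diabetes: 78.16 million; previously diagnosed: 20.23 million; eligible: 565.77 million

evaluate_strategy(pop, strategy_instrument(chat), seed = 5)
#> Screening evaluation: Chaturvedi risk score
#>   eligible 565.8M; referred 264.1M | TP 40.4M FP 223.7M TN 290.2M FN 11.5M
#>   sens 77.9%  spec 56.5%  PPV 15.3%  NPV 96.2%  NNS 14.0  FP:TP 5.5
```

A 45-year-old man with mildly raised blood pressure, a family history and a
waist of 85 cm scores 22 of 29 points — above the cut point of 16, so he
would be referred. At the national scale this instrument would refer about
264 million of 566 million eligible adults, finding roughly 40 million
undiagnosed cases while sending about 224 million people without diabetes to
confirmatory testing (5.5 false positives per case found, about 14 people
screened per case). `cost_strategy()` prices the program,
`roc_sweep()`/`recalibrate_cutpoint()` re-derive the optimal cut point on
the national population, and `run_pipeline(run_config(...))` wraps the whole
chain in Monte Carlo draws with credible intervals (see the vignette).

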