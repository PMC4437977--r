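# shared fixtures, built in code; populations are memoized so several test
# files can reuse the same draw without repaying the simulation cost

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# constant per-stratum surface
flat_surface <- function(prevalence = 0.12, undiagnosed = 0.733, ...) {
  s <- stratum_grid()
  s$prevalence <- prevalence
  s$undiagnosed <- undiagnosed
  extra <- list(...)
  for (nm in names(extra)) s[[nm]] <- extra[[nm]]
  class(s) <- c("prevalence_surface", "data.frame")
  s
}

# hand-built meta_fit (for prediction/sampling tests with known coefficients)
fake_fit <- function(beta, vcov = NULL, scale = "logit", outcome = "prevalence",
                     year_ref = 2005) {
  if (is.null(vcov))
    vcov <- matrix(0, length(beta), length(beta),
                   dimnames = list(names(beta), names(beta)))
  structure(list(beta = beta, vcov = vcov, tau2 = 0, scale = scale,
                 outcome = outcome, year_ref = year_ref, n_studies = NA),
            class = "meta_fit")
}

full_beta <- function(intercept = 0, age_45_65 = 0, male = 0, urban = 0,
                      income_mid = 0, income_high = 0, year = 0) {
  c(intercept = intercept, age_45_65 = age_45_65, male = male, urban = urban,
    income_mid = income_mid, income_high = income_high, year = year)
}

# default microsimulated population, 12% prevalence, 73.3% undiagnosed
std_pop <- function(n = 20000, seed = 42) {
  memo(paste0("pop_", n, "_", seed), {
    build_population(make_demographics(586), flat_surface(),
                     default_risk_factor_params(), n, seed = seed)
  })
}

# risk-factor params where fasting glucose is deterministic per status, so
# every diabetic is fasting-confirmed and every non-diabetic is not
crisp_params <- function() {
  p <- default_risk_factor_params()
  p$diabetic$scale[["fpg"]] <- 0
  p$diabetic$location[["fpg"]] <- log(9)
  p$nondiabetic$scale[["fpg"]] <- 0
  p$nondiabetic$location[["fpg"]] <- log(5)
  p
}

# populations where everyone / no one is an undiagnosed confirmed case
all_case_pop <- function(n = 20000, seed = 7) {
  memo(paste0("case_", n, "_", seed), {
    build_population(make_demographics(586),
                     flat_surface(prevalence = 1, undiagnosed = 1),
                     crisp_params(), n, seed = seed)
  })
}

no_case_pop <- function(n = 20000, seed = 7) {
  memo(paste0("ctrl_", n, "_", seed), {
    build_population(make_demographics(586),
                     flat_surface(prevalence = 0, undiagnosed = 1),
                     crisp_params(), n, seed = seed)
  })
}

# fitted meta-regressions from a default synthetic evidence base
std_fits <- function(seed = 11, n_studies = 58) {
  memo(paste0("fits_", seed, "_", n_studies), {
    truth <- default_truth()
    studies <- simulate_cohort_studies(truth, n_studies, seed = seed)
    fits <- lapply(names(truth$coefficients), function(oc)
      fit_meta_regression(studies, oc))
    names(fits) <- names(truth$coefficients)
    fits
  })
}
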