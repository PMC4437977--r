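#' Ground truth for the synthetic evidence base
#'
#' Returns the default "true" parameter set that drives every synthetic input:
#' logit-scale coefficient vectors for each modelled outcome (total diabetes
#' prevalence, probability of being undiagnosed given diabetes, hypertension
#' and obesity prevalence), between-study heterogeneity SDs, and the
#' status-conditional joint risk-factor distribution. Defaults emulate the
#' Indian adult (25-65 y) setting: overall diabetes prevalence near 12%,
#' markedly higher in urban than rural strata, and about 73% of diabetes
#' undiagnosed, with higher undiagnosed fractions among women, rural and
#' low-income groups.
#'
#' Coefficients are ordered (intercept, age_45_65, male, urban, income_mid,
#' income_high, year); reference categories are age 25-44, female, rural, low
#' income; `year` is centred at `year_ref`.
#'
#' @param scale `"logit"` (default) or `"linear"`: scale on which the
#'   outcome model is linear.
#' @return A list of class `ground_truth` with elements `scale`, `year_ref`,
#'   `coefficients` (list of named vectors), `tau` (between-study SDs) and
#'   `risk_factors` (see [default_risk_factor_params()]).
#' @export
default_truth <- function(scale = c("logit", "linear")) {
  scale <- match.arg(scale)
  co <- list(
    prevalence = c(intercept = stats::qlogis(0.04), age_45_65 = 0.75,
                   male = 0.05, urban = 0.87, income_mid = 0.25,
                   income_high = 0.50, year = 0.020),
    undiagnosed = c(intercept = 3.1, age_45_65 = -0.20,
                    male = -1.00, urban = -0.98, income_mid = -0.60,
                    income_high = -1.30, year = -0.010),
    hypertension = c(intercept = stats::qlogis(0.16), age_45_65 = 0.85,
                     male = 0.15, urban = 0.35, income_mid = 0.10,
                     income_high = 0.20, year = 0.010),
    obesity = c(intercept = stats::qlogis(0.035), age_45_65 = 0.30,
                male = -0.20, urban = 0.90, income_mid = 0.30,
                income_high = 0.60, year = 0.020)
  )
  if (scale == "linear") {
    # same qualitative structure, expressed directly on the proportion scale
    co <- list(
      prevalence  = c(intercept = 0.08, age_45_65 = 0.06, male = 0.005,
                      urban = 0.08, income_mid = 0.02, income_high = 0.04,
                      year = 0.002),
      undiagnosed = c(intercept = 0.88, age_45_65 = -0.03, male = -0.16,
                      urban = -0.15, income_mid = -0.08, income_high = -0.18,
                      year = -0.002),
      hypertension = c(intercept = 0.15, age_45_65 = 0.12, male = 0.02,
                       urban = 0.06, income_mid = 0.01, income_high = 0.03,
                       year = 0.001),
      obesity = c(intercept = 0.03, age_45_65 = 0.01, male = -0.005,
                  urban = 0.05, income_mid = 0.01, income_high = 0.02,
                  year = 0.001)
    )
  }
  truth <- list(
    scale = scale,
    year_ref = 2005,
    coefficients = co,
    tau = c(prevalence = 0.20, undiagnosed = 0.20,
            hypertension = 0.18, obesity = 0.22),
    risk_factors = default_risk_factor_params()
  )
  class(truth) <- "ground_truth"
  truth
}

#' Default status-conditional risk-factor distribution parameters
#'
#' A Gaussian copula over eight continuous biomarkers: blood pressures, BMI
#' and waist circumference are Normal on the natural scale; random plasma
#' glucose, fasting plasma glucose, HbA1c and LDL are log-Normal (location =
#' log median, scale = SD on the log scale). Parameters are conditional on
#' diabetes status; waist circumference receives an additive sex offset.
#' Categorical factors (family history, physical activity, smoking, prior
#' cardiovascular disease) have status-conditional level probabilities.
#'
#' @return A list of class `risk_factor_params`.
#' @export
default_risk_factor_params <- function() {
  factors <- c("sbp", "dbp", "bmi", "waist", "rpg", "fpg", "hba1c", "ldl")
  dist <- c(sbp = "normal", dbp = "normal", bmi = "normal", waist = "normal",
            rpg = "lognormal", fpg = "lognormal", hba1c = "lognormal",
            ldl = "lognormal")
  corr <- diag(8)
  dimnames(corr) <- list(factors, factors)
  set_r <- function(a, b, r) {
    corr[a, b] <<- r
    corr[b, a] <<- r
  }
  set_r("sbp", "dbp", 0.70); set_r("bmi", "waist", 0.80)
  set_r("sbp", "bmi", 0.25); set_r("sbp", "waist", 0.20)
  set_r("dbp", "bmi", 0.20); set_r("dbp", "waist", 0.16)
  set_r("rpg", "fpg", 0.60); set_r("fpg", "hba1c", 0.65)
  set_r("rpg", "hba1c", 0.50)
  set_r("bmi", "rpg", 0.15); set_r("bmi", "fpg", 0.15)
  set_r("waist", "rpg", 0.12); set_r("waist", "fpg", 0.12)
  set_r("sbp", "rpg", 0.10); set_r("sbp", "fpg", 0.10)
  set_r("sbp", "hba1c", 0.10); set_r("bmi", "ldl", 0.15)
  p <- list(
    factors = factors,
    dist = dist,
    corr = corr,
    # location/scale: mean/SD for normal marginals, log-median/log-SD for
    # log-normal marginals
    nondiabetic = list(
      location = c(sbp = 122, dbp = 78, bmi = 22.8, waist = 81.5,
                   rpg = log(5.4), fpg = log(5.1), hba1c = log(5.5),
                   ldl = log(2.9)),
      scale = c(sbp = 14, dbp = 9, bmi = 3.6, waist = 9.5,
                rpg = 0.18, fpg = 0.11, hba1c = 0.06, ldl = 0.27),
      categorical = list(
        family_history = c(none = 0.80, one_parent_or_sibling = 0.17,
                           both_parents = 0.03),
        physical_activity = c(regular_exercise_and_strenuous_work = 0.25,
                              one_of_the_two = 0.45, neither = 0.30),
        smoker = 0.15, cvd_history = 0.02
      )
    ),
    diabetic = list(
      location = c(sbp = 132, dbp = 82, bmi = 25.5, waist = 89,
                   rpg = log(8.2), fpg = log(9.0), hba1c = log(7.8),
                   ldl = log(3.1)),
      scale = c(sbp = 15, dbp = 9.5, bmi = 4.0, waist = 9.5,
                rpg = 0.45, fpg = 0.20, hba1c = 0.15, ldl = 0.27),
      categorical = list(
        family_history = c(none = 0.60, one_parent_or_sibling = 0.32,
                           both_parents = 0.08),
        physical_activity = c(regular_exercise_and_strenuous_work = 0.15,
                              one_of_the_two = 0.40, neither = 0.45),
        smoker = 0.18, cvd_history = 0.08
      )
    ),
    waist_sex_offset = c(male = 4.5, female = -4.5)
  )
  class(p) <- "risk_factor_params"
  validate_risk_factor_params(p)
  p
}

validate_risk_factor_params <- function(p) {
  stopifnot(is.list(p), !is.null(p$corr))
  R <- p$corr
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12))
    stop("correlation matrix must be symmetric with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("correlation matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  for (st in c("nondiabetic", "diabetic")) {
    for (fam in c("family_history", "physical_activity")) {
      pr <- p[[st]]$categorical[[fam]]
      if (abs(sum(pr) - 1) > 1e-9 || any(pr < 0))
        stop(st, " ", fam, " probabilities must be a simplex")
    }
  }
  invisible(p)
}

# linear predictor of an outcome for given moderator values (vector or matrix
# with columns age_45_65, male, urban, income_mid, income_high) and year
outcome_linpred <- function(beta, mods, year, year_ref) {
  mods <- as.matrix(mods)
  drop(beta["intercept"] +
         mods %*% beta[c("age_45_65", "male", "urban",
                         "income_mid", "income_high")] +
         beta["year"] * (year - year_ref))
}

link_inv <- function(x, scale) {
  if (scale == "logit") stats::plogis(x) else x
}

#' Simulate a synthetic set of cohort-study summaries
#'
#' Emulates the published evidence base that drives the prevalence model: each
#' synthetic study draws its demographic composition (moderator shares) from a
#' mixing distribution, its true outcome proportions from the ground-truth
#' linear predictor plus Normal between-study noise, and its observed
#' proportions from binomial sampling at the study's size. The recorded
#' sampling variance is p(1-p)/n.
#'
#' @param truth A `ground_truth` object, see [default_truth()].
#' @param n_studies Number of studies (>= 2).
#' @param seed Integer RNG seed.
#' @param n_range Length-2 integer range for per-study sample sizes.
#' @param between_sd Optional named override of `truth$tau` (use 0 for the
#'   noise-free limit).
#' @param outcomes Which outcomes to record; defaults to all in `truth`.
#' @param year_range Calendar-year range studies are drawn from.
#' @return A data.frame of class `cohort_studies`, one row per study, with
#'   share columns per stratification level, one `p_<outcome>` and
#'   `var_<outcome>` column pair per outcome, `year` and `n`. An attribute
#'   `n_clamped` counts truth proportions clamped into (0, 1).
#' @export
simulate_cohort_studies <- function(truth, n_studies, seed,
                                    n_range = c(500L, 20000L),
                                    between_sd = NULL,
                                    outcomes = names(truth$coefficients),
                                    year_range = c(1995L, 2014L)) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_studies < 2) stop("`n_studies` must be at least 2")
  tau <- truth$tau
  if (!is.null(between_sd)) {
    if (length(between_sd) == 1L && is.null(names(between_sd)))
      between_sd <- stats::setNames(rep(between_sd, length(outcomes)), outcomes)
    tau[names(between_sd)] <- between_sd
  }
  set.seed(seed)
  age_45 <- stats::rbeta(n_studies, 2.5, 3.5)
  male <- stats::rbeta(n_studies, 6, 6)
  urban <- stats::rbeta(n_studies, 2, 2)
  inc <- matrix(stats::rgamma(3L * n_studies, shape = 2), ncol = 3L)
  inc <- inc / rowSums(inc)
  sample_range <- function(r, k) {
    v <- seq(r[1], r[2])
    if (length(v) == 1L) rep(v, k) else sample(v, k, replace = TRUE)
  }
  year <- sample_range(year_range, n_studies)
  n <- sample_range(n_range, n_studies)
  out <- data.frame(
    study_id = sprintf("S%03d", seq_len(n_studies)),
    year = year, n = n,
    share_age_25_44 = 1 - age_45, share_age_45_65 = age_45,
    share_female = 1 - male, share_male = male,
    share_rural = 1 - urban, share_urban = urban,
    share_income_low = inc[, 1], share_income_mid = inc[, 2],
    share_income_high = inc[, 3]
  )
  mods <- cbind(age_45_65 = age_45, male = male, urban = urban,
                income_mid = inc[, 2], income_high = inc[, 3])
  n_clamped <- 0L
  for (oc in outcomes) {
    lp <- outcome_linpred(truth$coefficients[[oc]], mods, year, truth$year_ref)
    lp <- lp + stats::rnorm(n_studies, 0, tau[[oc]])
    p_true <- link_inv(lp, truth$scale)
    bad <- p_true < 1e-6 | p_true > 1 - 1e-6
    if (any(bad)) {
      n_clamped <- n_clamped + sum(bad)
      p_true <- pmin(pmax(p_true, 1e-6), 1 - 1e-6)
    }
    events <- stats::rbinom(n_studies, n, p_true)
    p_hat <- ifelse(events == 0L | events == n,
                    (events + 0.5) / (n + 1), events / n)
    out[[paste0("p_", oc)]] <- p_hat
    out[[paste0("var_", oc)]] <- p_hat * (1 - p_hat) / n
  }
  if (n_clamped > 0L)
    message("simulate_cohort_studies: clamped ", n_clamped,
            " true proportions into (0, 1)")
  attr(out, "n_clamped") <- n_clamped
  attr(out, "scale") <- truth$scale
  class(out) <- c("cohort_studies", "data.frame")
  out
}

#' Unit-cost inputs for the cost model
#'
#' Per-person unit costs (2014 US dollars) for each program activity. The
#' defaults are documented placeholders sized so that confirmatory laboratory
#' testing dominates program cost, as in typical low- and middle-income
#' screening settings; they are not authoritative WHO-CHOICE values and any
#' entry can be overridden.
#'
#' @param overrides Named list/vector overriding any of `questionnaire`,
#'   `glucometer`, `confirmatory`, `overhead_per_person_year`.
#' @return Named numeric vector of class `unit_costs`.
#' @examples
#' make_unit_costs(list(confirmatory = 2))
#' @export
make_unit_costs <- function(overrides = list()) {
  costs <- c(questionnaire = 0.05, glucometer = 0.15, confirmatory = 1.50,
             overhead_per_person_year = 0.01)
  if (length(overrides)) {
    overrides <- unlist(overrides)
    unknown <- setdiff(names(overrides), names(costs))
    if (length(unknown))
      stop("unknown cost item(s): ", paste(unknown, collapse = ", "))
    costs[names(overrides)] <- overrides
  }
  if (any(!is.finite(costs)) || any(costs < 0))
    stop("all unit costs must be finite and non-negative")
  class(costs) <- "unit_costs"
  costs
}

#' Read or write cohort-study summaries as CSV
#'
#' @param x A `cohort_studies` data.frame.
#' @param path File path.
#' @return `read_cohort_studies()` returns a `cohort_studies` data.frame.
#' @export
write_cohort_studies <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_studies
#' @param scale Outcome scale the studies were generated on.
#' @export
read_cohort_studies <- function(path, scale = "logit") {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(x, "scale") <- scale
  class(x) <- c("cohort_studies", "data.frame")
  x
}
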