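#' Pluggable 20-year complication risk equations
#'
#' The complication stage is a pluggable interface: any set of per-endpoint
#' risk functions of a risk-factor profile can be supplied (e.g. externally
#' published outcome-model equations). The shipped default is a documented
#' parametric stand-in: for each endpoint the 20-year risk is a logistic
#' function of biomarker deviations from reference values, with non-negative
#' coefficients so risk is monotone non-decreasing in each hazard-raising
#' biomarker.
#'
#' Default endpoints: heart disease (`ihd`, including myocardial infarction
#' and heart failure), `stroke`, `blindness`, diabetic `ulcer`, and `renal`
#' failure. Baselines are sized so a typical untreated screen-detected case
#' carries roughly a 20% 20-year heart-disease risk and single-digit risks
#' for the microvascular endpoints.
#'
#' @param params Optional named list overriding per-endpoint parameter lists
#'   (`baseline` log-odds plus coefficient list `coef`).
#' @return Object of class `risk_equations`.
#' @export
risk_equations <- function(params = NULL) {
  default <- list(
    ihd = list(baseline = -1.5,
               coef = c(sbp10 = 0.08, hba1c = 0.06, ldl = 0.12,
                        bmi5 = 0.04, smoker = 0.20, age10 = 0.18)),
    stroke = list(baseline = -2.5,
                  coef = c(sbp10 = 0.12, hba1c = 0.05, ldl = 0.05,
                           bmi5 = 0.02, smoker = 0.15, age10 = 0.20)),
    blindness = list(baseline = -3.2,
                     coef = c(sbp10 = 0.03, hba1c = 0.15, ldl = 0,
                              bmi5 = 0, smoker = 0.05, age10 = 0.08)),
    ulcer = list(baseline = -3.0,
                 coef = c(sbp10 = 0.02, hba1c = 0.13, ldl = 0.02,
                          bmi5 = 0.04, smoker = 0.10, age10 = 0.08)),
    renal = list(baseline = -3.6,
                 coef = c(sbp10 = 0.10, hba1c = 0.12, ldl = 0.02,
                          bmi5 = 0.02, smoker = 0.06, age10 = 0.10))
  )
  if (!is.null(params)) default[names(params)] <- params
  for (ep in names(default)) {
    if (any(default[[ep]]$coef < 0))
      stop("risk-equation coefficients must be non-negative (endpoint ",
           ep, ")")
  }
  structure(default, class = "risk_equations")
}

#' American Diabetes Association best-case treatment targets
#'
#' Systolic blood pressure lowered to at most 140 mm Hg, LDL to at most
#' 2.6 mmol/l (1.8 mmol/l with a cardiovascular disease history), and HbA1c
#' to at most 7%. Treatment never raises a biomarker.
#'
#' @param sbp_target,ldl_target,ldl_target_cvd,hba1c_target Numeric targets.
#' @return List of class `treatment_targets`.
#' @export
treatment_targets <- function(sbp_target = 140, ldl_target = 2.6,
                              ldl_target_cvd = 1.8, hba1c_target = 7) {
  stopifnot(sbp_target > 0, ldl_target > 0, ldl_target_cvd > 0,
            hba1c_target > 0)
  structure(list(sbp_target = sbp_target, ldl_target = ldl_target,
                 ldl_target_cvd = ldl_target_cvd,
                 hba1c_target = hba1c_target),
            class = "treatment_targets")
}

#' Apply best-case treatment to profiles
#'
#' Clamps each targeted biomarker to `min(current, target)`; everything else
#' is unchanged (full adherence, full risk reversal — the most optimistic
#' scenario).
#'
#' @param profiles data.frame with `sbp`, `ldl`, `hba1c` and logical
#'   `cvd_history`.
#' @param targets A `treatment_targets` object.
#' @return The treated profiles data.frame.
#' @export
apply_treatment <- function(profiles, targets = treatment_targets()) {
  stopifnot(inherits(targets, "treatment_targets"))
  profiles$sbp <- pmin(profiles$sbp, targets$sbp_target)
  ldl_t <- ifelse(isTRUE_vec(profiles$cvd_history),
                  targets$ldl_target_cvd, targets$ldl_target)
  profiles$ldl <- pmin(profiles$ldl, ldl_t)
  profiles$hba1c <- pmin(profiles$hba1c, targets$hba1c_target)
  profiles
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else as.logical(x)

#' Per-endpoint 20-year complication risks
#'
#' @param eqs A `risk_equations` set.
#' @param profiles data.frame with `sbp`, `hba1c`, `ldl`, `bmi`, `smoker`,
#'   `age`.
#' @return Matrix (persons x endpoints) of risks in [0, 1].
#' @export
complication_risk <- function(eqs, profiles) {
  stopifnot(inherits(eqs, "risk_equations"))
  need <- c("sbp", "hba1c", "ldl", "bmi", "smoker", "age")
  missing <- setdiff(need, names(profiles))
  if (length(missing))
    stop("profiles lack biomarker(s): ", paste(missing, collapse = ", "))
  # deviations from reference values (floored at 0 so treatment to target
  # removes the excess risk, never goes protective)
  dev <- cbind(
    sbp10 = pmax(profiles$sbp - 120, 0) / 10,
    hba1c = pmax(profiles$hba1c - 5.5, 0),
    ldl = pmax(profiles$ldl - 2.6, 0),
    bmi5 = pmax(profiles$bmi - 22, 0) / 5,
    smoker = as.numeric(profiles$smoker),
    age10 = pmax(profiles$age - 50, 0) / 10
  )
  risks <- vapply(names(eqs), function(ep) {
    e <- eqs[[ep]]
    stats::plogis(e$baseline + drop(dev[, names(e$coef), drop = FALSE] %*%
                                      e$coef))
  }, numeric(nrow(profiles)))
  if (nrow(profiles) == 1L) risks <- matrix(risks, nrow = 1L,
                                            dimnames = list(NULL, names(eqs)))
  risks
}

# probability of at least one complication assuming conditional independence
# of endpoints given the profile
any_complication <- function(risks) 1 - apply(1 - risks, 1, prod)

#' Number needed to screen and treat (NNST)
#'
#' Among screen-detected cases, compares per-endpoint 20-year complication
#' risks before and after best-case treatment. The absolute risk reduction
#' (ARR) is the weighted mean risk difference; NNST is its reciprocal. The
#' overall "fraction avoiding any complication" uses the per-person
#' any-complication probability difference under conditional independence of
#' endpoints.
#'
#' @param cases data.frame of screen-detected cases with profile columns and
#'   a `weight` column (equal weights assumed when absent).
#' @param eqs A `risk_equations` set.
#' @param targets A `treatment_targets` object.
#' @return Object of class `nnst_result`: per-endpoint data.frame (`arr`,
#'   `nnst`), `fraction_avoiding` any complication, `nnst_any` and
#'   `min_nnst` (the smallest per-endpoint NNST).
#' @export
nnst <- function(cases, eqs = risk_equations(), targets = treatment_targets()) {
  if (!nrow(cases)) stop("need at least one detected case")
  w <- cases$weight
  if (is.null(w)) w <- rep(1, nrow(cases))
  w <- w / sum(w)
  r0 <- complication_risk(eqs, cases)
  r1 <- complication_risk(eqs, apply_treatment(cases, targets))
  arr <- colSums(w * (r0 - r1))
  nnst_ep <- ifelse(arr > 0, 1 / arr, NA_real_)
  frac <- sum(w * (any_complication(r0) - any_complication(r1)))
  structure(list(
    endpoints = data.frame(endpoint = colnames(r0), arr = arr,
                           nnst = nnst_ep, row.names = NULL),
    fraction_avoiding = frac,
    nnst_any = if (frac > 0) 1 / frac else NA_real_,
    min_nnst = if (any(arr > 0)) min(nnst_ep, na.rm = TRUE) else NA_real_
  ), class = "nnst_result")
}

#' @export
print.nnst_result <- function(x, ...) {
  cat("Best-case treatment effect among screen-detected cases\n")
  print(transform(x$endpoints, arr = signif(arr, 4), nnst = round(nnst, 1)))
  cat(sprintf(
    "  fraction avoiding any complication: %.2f%%  (NNST any: %.1f; min per-endpoint NNST: %.1f)\n",
    100 * x$fraction_avoiding, x$nnst_any, x$min_nnst))
  invisible(x)
}

#' Screening cost per complication prevented
#'
#' Total screening-program cost divided by the number of detected cases
#' expected to avoid a complication (true positives times the fraction
#' avoiding any complication under best-case treatment). Treatment costs are
#' excluded.
#'
#' @param cost A `cost_summary`.
#' @param nnst_res An `nnst_result`.
#' @param tp True-positive cases found (millions), from the matching
#'   `confusion_counts`.
#' @return Cost per person with a complication prevented (same currency as
#'   `cost`), or `NA` when the avoided fraction is zero.
#' @export
cost_per_complication_prevented <- function(cost, nnst_res, tp) {
  stopifnot(inherits(cost, "cost_summary"), inherits(nnst_res, "nnst_result"))
  if (!is.finite(nnst_res$fraction_avoiding) ||
      nnst_res$fraction_avoiding <= 0 || tp <= 0)
    return(NA_real_)
  cost$total_cost / (tp * nnst_res$fraction_avoiding)
}
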