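#' Build the microsimulated national population
#'
#' Allocates `n_persons` simulated individuals to the 24 demographic strata in
#' proportion to the demographic weights (largest-remainder rounding, so every
#' stratum with positive weight receives at least its proportional share),
#' assigns diabetes status and prior-diagnosis status from the per-stratum
#' surface probabilities, and draws a correlated risk-factor profile
#' conditional on diabetes status. Each person carries a sampling weight
#' (stratum millions / stratum sample count) so that weighted tallies are on
#' the national scale in millions.
#'
#' @param demo A `demographic_table` from [make_demographics()].
#' @param surface A `prevalence_surface` carrying at least columns
#'   `prevalence` and `undiagnosed` (probability undiagnosed given diabetes).
#' @param dist_params A `risk_factor_params` object.
#' @param n_persons Number of simulated individuals (>= 24).
#' @param seed Integer RNG seed.
#' @return A data.frame of class `population_sample`: stratum columns,
#'   `has_diabetes`, `previously_diagnosed`, `eligible`, `weight` (millions
#'   represented) and the risk-factor profile columns.
#' @export
build_population <- function(demo, surface, dist_params, n_persons, seed) {
  stopifnot(inherits(demo, "demographic_table"))
  if (n_persons < 24) stop("`n_persons` must be at least 24")
  need <- c("prevalence", "undiagnosed")
  if (!all(need %in% names(surface)))
    stop("surface must provide columns: ", paste(need, collapse = ", "))
  validate_risk_factor_params(dist_params)
  set.seed(seed)

  total <- attr(demo, "total_millions")
  # largest-remainder allocation of persons to strata
  exact <- n_persons * demo$weight / total
  n_k <- floor(exact)
  rem <- n_persons - sum(n_k)
  if (rem > 0) {
    ord <- order(exact - n_k, decreasing = TRUE)
    n_k[ord[seq_len(rem)]] <- n_k[ord[seq_len(rem)]] + 1L
  }
  if (any(n_k == 0 & demo$weight > 0))
    stop("stratum with positive weight received no persons; increase n_persons")

  idx <- rep.int(seq_len(nrow(demo)), n_k)
  s <- match(demo$stratum[idx], surface$stratum)
  if (anyNA(s)) stop("surface does not cover all strata")
  pop <- demo[idx, c("age_band", "sex", "location", "income", "stratum")]
  rownames(pop) <- NULL
  pop$weight <- (demo$weight / pmax(n_k, 1L))[idx]

  prev <- surface$prevalence[s]
  p_undiag <- surface$undiagnosed[s]
  pop$has_diabetes <- stats::runif(nrow(pop)) < prev
  pop$previously_diagnosed <- pop$has_diabetes &
    (stats::runif(nrow(pop)) >= p_undiag)
  pop$eligible <- !pop$previously_diagnosed

  prof <- draw_profiles(pop$has_diabetes, pop$sex, pop$age_band, dist_params)
  pop <- cbind(pop, prof)
  attr(pop, "total_millions") <- total
  class(pop) <- c("population_sample", "data.frame")
  pop
}

#' Draw correlated risk-factor profiles
#'
#' Continuous biomarkers come from a Gaussian copula: a standard multivariate
#' Normal draw (correlation from `dist_params$corr`) is mapped through each
#' factor's marginal (Normal, or log-Normal for the glucose measures, HbA1c
#' and LDL), conditional on diabetes status. Waist circumference receives a
#' sex offset; age is drawn uniformly within the stratum's band. Categorical
#' factors use status-conditional probabilities.
#'
#' @param has_diabetes Logical vector.
#' @param sex Character vector (`"male"`/`"female"`).
#' @param age_band Character vector (`"25-44"`/`"45-65"`).
#' @param dist_params A `risk_factor_params` object.
#' @return data.frame with columns `age`, `sbp`, `dbp`, `bmi`, `waist`,
#'   `rpg`, `fpg`, `hba1c`, `ldl` (continuous), `family_history`,
#'   `physical_activity` (character), `smoker`, `cvd_history` (logical).
#' @export
draw_profiles <- function(has_diabetes, sex, age_band, dist_params) {
  validate_risk_factor_params(dist_params)
  n <- length(has_diabetes)
  fac <- dist_params$factors
  k <- length(fac)
  L <- chol_psd(dist_params$corr)
  Z <- matrix(stats::rnorm(n * k), nrow = n) %*% L
  colnames(Z) <- fac
  X <- matrix(NA_real_, n, k, dimnames = list(NULL, fac))
  for (st in c(FALSE, TRUE)) {
    i <- which(has_diabetes == st)
    if (!length(i)) next
    par <- dist_params[[if (st) "diabetic" else "nondiabetic"]]
    for (f in fac) {
      if (dist_params$dist[[f]] == "normal") {
        X[i, f] <- par$location[[f]] + par$scale[[f]] * Z[i, f]
      } else {
        X[i, f] <- exp(par$location[[f]] + par$scale[[f]] * Z[i, f])
      }
    }
  }
  X[, "waist"] <- X[, "waist"] + dist_params$waist_sex_offset[sex]
  # continuous biomarkers are physically positive; truncate extreme deviates
  X[X <= 0.1] <- 0.1
  age_lo <- ifelse(age_band == "45-65", 45, 25)
  age_hi <- ifelse(age_band == "45-65", 65, 45)
  out <- data.frame(age = stats::runif(n, age_lo, age_hi))
  out <- cbind(out, as.data.frame(X))
  out$family_history <- draw_categorical(has_diabetes, dist_params,
                                         "family_history")
  out$physical_activity <- draw_categorical(has_diabetes, dist_params,
                                            "physical_activity")
  p_smoke <- ifelse(has_diabetes, dist_params$diabetic$categorical$smoker,
                    dist_params$nondiabetic$categorical$smoker)
  out$smoker <- stats::runif(n) < p_smoke
  p_cvd <- ifelse(has_diabetes, dist_params$diabetic$categorical$cvd_history,
                  dist_params$nondiabetic$categorical$cvd_history)
  out$cvd_history <- stats::runif(n) < p_cvd
  out
}

draw_categorical <- function(has_diabetes, dist_params, fam) {
  n <- length(has_diabetes)
  out <- character(n)
  for (st in c(FALSE, TRUE)) {
    i <- which(has_diabetes == st)
    if (!length(i)) next
    pr <- dist_params[[if (st) "diabetic" else "nondiabetic"]]$categorical[[fam]]
    out[i] <- sample(names(pr), length(i), replace = TRUE, prob = pr)
  }
  out
}

# Cholesky factor tolerant of a semi-definite matrix (e.g. perfectly
# correlated or zero-variance blocks): falls back to an eigen square root.
chol_psd <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("matrix is not positive semi-definite")
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors))
}

#' Restrict a population to those eligible for screening
#'
#' Screening targets people without a prior diabetes diagnosis; previously
#' diagnosed persons are removed, weights are unchanged.
#'
#' @param pop A `population_sample`.
#' @return The eligible `population_sample` subset.
#' @export
eligible_subset <- function(pop) {
  stopifnot(inherits(pop, "population_sample"))
  out <- pop[!pop$previously_diagnosed, , drop = FALSE]
  attr(out, "total_millions") <- attr(pop, "total_millions")
  class(out) <- class(pop)
  out
}

#' @export
print.population_sample <- function(x, ...) {
  w <- sum(x$weight)
  cat("Microsimulated population:", nrow(x), "persons representing",
      format(round(w, 3)), "million\n")
  cat("  diabetes:",
      format(round(sum(x$weight[x$has_diabetes]), 2)), "million;",
      "previously diagnosed:",
      format(round(sum(x$weight[x$previously_diagnosed]), 2)), "million;",
      "eligible:", format(round(sum(x$weight[x$eligible]), 2)), "million\n")
  invisible(x)
}

#' Weighted summary totals of a population sample
#'
#' @param object A `population_sample`.
#' @param ... Unused.
#' @return Named numeric vector of national totals in millions.
#' @export
summary.population_sample <- function(object, ...) {
  w <- object$weight
  c(total = sum(w),
    diabetes = sum(w[object$has_diabetes]),
    previously_diagnosed = sum(w[object$previously_diagnosed]),
    eligible = sum(w[object$eligible]),
    undiagnosed = sum(w[object$has_diabetes & !object$previously_diagnosed]))
}
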