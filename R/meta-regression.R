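#' Inverse-variance mixed-effects meta-regression of study outcomes
#'
#' Regresses study-level outcome proportions on the study's moderator shares
#' (age, sex, location, income composition; one reference level dropped per
#' family) and calendar year, weighting each study by the inverse of its
#' sampling variance and allowing Normal between-study heterogeneity
#' (restricted maximum likelihood). The default fits on the logit scale with
#' delta-method sampling variances, which guarantees predicted probabilities
#' stay in [0, 1]; a linear (raw proportion) scale is available for fidelity
#' to the raw-outcome formulation.
#'
#' @param studies A `cohort_studies` data.frame (see
#'   [simulate_cohort_studies()]).
#' @param outcome Outcome name, e.g. `"prevalence"`; columns
#'   `p_<outcome>` and `var_<outcome>` must exist.
#' @param scale `"logit"` (default) or `"linear"`.
#' @param intercept_only If `TRUE`, fit a pooled intercept with no moderators.
#' @param method Between-study variance estimator: `"REML"` (default) or
#'   `"FE"` to fix tau2 at 0 (the fixed-effect / pure inverse-variance
#'   weighted least-squares limit).
#' @param year_ref Year centring constant (must match downstream prediction).
#' @return An object of class `meta_fit`: list with `beta` (named coefficient
#'   vector), `vcov`, `tau2`, `scale`, `outcome`, `year_ref`, `n_studies`, and
#'   the underlying `metafor::rma` fit as `rma`.
#' @export
fit_meta_regression <- function(studies, outcome, scale = c("logit", "linear"),
                                intercept_only = FALSE,
                                method = c("REML", "FE"), year_ref = 2005) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  pcol <- paste0("p_", outcome)
  vcol <- paste0("var_", outcome)
  if (!all(c(pcol, vcol) %in% names(studies)))
    stop("studies lack columns for outcome '", outcome, "'")
  p <- studies[[pcol]]
  v <- studies[[vcol]]
  if (any(v <= 0)) stop("all sampling variances must be positive")
  if (scale == "logit") {
    eps <- 1e-6
    p_adj <- pmin(pmax(p, eps), 1 - eps)
    yi <- stats::qlogis(p_adj)
    vi <- v / (p_adj * (1 - p_adj))^2   # delta method for the logit transform
  } else {
    yi <- p
    vi <- v
  }
  if (intercept_only) {
    X <- NULL
    k_par <- 1L
  } else {
    X <- data.frame(
      age_45_65   = studies$share_age_45_65,
      male        = studies$share_male,
      urban       = studies$share_urban,
      income_mid  = studies$share_income_mid,
      income_high = studies$share_income_high,
      year        = studies$year - year_ref
    )
    k_par <- ncol(X) + 1L
    qrX <- qr(cbind(1, as.matrix(X)))
    if (qrX$rank < k_par) {
      keep <- qrX$pivot[seq_len(qrX$rank)]
      dropped <- setdiff(seq_len(k_par), keep) - 1L
      stop("singular moderator design; collinear column(s): ",
           paste(names(X)[dropped], collapse = ", "))
    }
  }
  if (nrow(studies) < k_par)
    stop("need at least ", k_par, " studies to fit ", k_par,
         " coefficients; got ", nrow(studies))
  if (nrow(studies) == 1L) method <- "FE"
  fit <- if (intercept_only) {
    metafor::rma(yi = yi, vi = vi, method = method)
  } else {
    metafor::rma(yi = yi, vi = vi, mods = as.matrix(X), method = method)
  }
  beta <- as.numeric(fit$beta)
  names(beta) <- if (intercept_only) "intercept" else c("intercept", names(X))
  out <- list(beta = beta, vcov = stats::vcov(fit),
              tau2 = max(0, fit$tau2), scale = scale, outcome = outcome,
              year_ref = year_ref, n_studies = nrow(studies), rma = fit)
  class(out) <- "meta_fit"
  out
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("Inverse-variance mixed-effects meta-regression (", x$scale,
      " scale)\n", sep = "")
  cat("Outcome:", x$outcome, " Studies:", x$n_studies,
      " tau^2:", format(x$tau2, digits = 4), "\n")
  print(round(cbind(beta = x$beta, se = sqrt(diag(x$vcov))), 4))
  invisible(x)
}

#' @export
coef.meta_fit <- function(object, ...) object$beta

#' @export
vcov.meta_fit <- function(object, ...) object$vcov

#' @export
summary.meta_fit <- function(object, ...) summary(object$rma, ...)

# moderator row for each of the 24 strata (0/1 indicators + centred year)
surface_design <- function(year, year_ref) {
  g <- stratum_grid()
  X <- as.matrix(cbind(stratum_moderators(g), year = year - year_ref))
  list(grid = g, X = cbind(intercept = 1, X))
}

surface_from_beta <- function(betas, year, year_ref, scale) {
  d <- surface_design(year, year_ref)
  out <- d$grid
  n_clamped <- 0L
  for (oc in names(betas)) {
    beta <- betas[[oc]]
    lp <- drop(d$X[, names(beta), drop = FALSE] %*% beta)
    p <- if (scale == "logit") stats::plogis(lp) else lp
    bad <- p < 0 | p > 1
    if (any(bad)) {
      n_clamped <- n_clamped + sum(bad)
      p <- pmin(pmax(p, 0), 1)
    }
    out[[oc]] <- p
  }
  attr(out, "year") <- year
  attr(out, "n_clamped") <- n_clamped
  class(out) <- c("prevalence_surface", "data.frame")
  out
}

#' Predict the per-stratum prevalence surface
#'
#' Maps a set of fitted meta-regressions to point predictions for all 24
#' strata at a given calendar year. Predictions on the linear scale falling
#' outside [0, 1] are clamped, with the number of clamped cells reported via
#' a message and stored in the `n_clamped` attribute.
#'
#' @param fits Named list of `meta_fit` objects (one per outcome).
#' @param year Calendar year of prediction.
#' @return A data.frame of class `prevalence_surface`: stratum columns plus
#'   one probability column per outcome.
#' @export
predict_surface <- function(fits, year) {
  if (!length(fits) || !all(vapply(fits, inherits, TRUE, "meta_fit")))
    stop("`fits` must be a non-empty named list of meta_fit objects")
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("`fits` must be named by outcome")
  scales <- unique(vapply(fits, `[[`, "", "scale"))
  refs <- unique(vapply(fits, `[[`, 0, "year_ref"))
  if (length(scales) != 1L || length(refs) != 1L)
    stop("all fits must share one scale and year_ref")
  betas <- lapply(fits, `[[`, "beta")
  s <- surface_from_beta(betas, year, refs, scales)
  if (attr(s, "n_clamped") > 0L)
    message("predict_surface: clamped ", attr(s, "n_clamped"),
            " predictions into [0, 1]")
  s
}

#' True prevalence surface implied by a ground-truth parameter set
#'
#' @param truth A `ground_truth` object.
#' @param year Calendar year.
#' @return A `prevalence_surface` data.frame.
#' @export
true_surface <- function(truth, year) {
  surface_from_beta(truth$coefficients, year, truth$year_ref, truth$scale)
}

#' Draw prevalence surfaces from the coefficient distribution
#'
#' Propagates estimation uncertainty: draws coefficient vectors from the
#' multivariate Normal defined by each fit's (beta, vcov) and maps each draw
#' to a full per-stratum surface.
#'
#' @inheritParams predict_surface
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed Integer RNG seed.
#' @return List of `prevalence_surface` objects, length `n_draws`.
#' @export
sample_surface <- function(fits, year, n_draws, seed) {
  if (n_draws < 1) stop("`n_draws` must be >= 1")
  scales <- unique(vapply(fits, `[[`, "", "scale"))
  refs <- unique(vapply(fits, `[[`, 0, "year_ref"))
  if (length(scales) != 1L || length(refs) != 1L)
    stop("all fits must share one scale and year_ref")
  set.seed(seed)
  draws <- lapply(fits, function(f) {
    V <- (f$vcov + t(f$vcov)) / 2
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("coefficient covariance for outcome '", f$outcome,
           "' is not positive semi-definite")
    b <- MASS::mvrnorm(n_draws, mu = f$beta, Sigma = V)
    if (n_draws == 1L) b <- matrix(b, nrow = 1L,
                                   dimnames = list(NULL, names(f$beta)))
    b
  })
  lapply(seq_len(n_draws), function(i) {
    betas <- lapply(draws, function(b) b[i, ])
    surface_from_beta(betas, year, refs, scales)
  })
}
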