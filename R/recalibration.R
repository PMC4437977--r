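#' Weighted ROC sweep over instrument thresholds
#'
#' Computes sensitivity and specificity at every achievable positivity
#' threshold of an instrument (each distinct score, plus a sentinel beyond
#' the range so both ROC endpoints are present) on the eligible national
#' population, using person weights. For the glucometer the measured value
#' (true glucose plus device error) is swept on a 0.1 mmol/l grid.
#'
#' Truth is previously undiagnosed diabetes confirmed by the fasting
#' criterion, as in [evaluate_strategy()].
#'
#' @param pop A `population_sample`.
#' @param spec An `instrument_spec` or `glucometer_spec`.
#' @param seed Seed for the glucometer measurement error.
#' @param grid_step Glucometer threshold grid step, mmol/l.
#' @return Object of class `roc_curve`: data.frame of `threshold`,
#'   `sensitivity`, `specificity` (positive means value >= threshold) with
#'   attribute `auc` (trapezoidal area under the curve).
#' @export
roc_sweep <- function(pop, spec, seed = 1L, grid_step = 0.1) {
  stopifnot(inherits(pop, "population_sample"))
  pop <- eligible_subset(pop)
  truth <- pop$has_diabetes & !pop$previously_diagnosed &
    confirmatory_test(pop)
  if (!any(truth) || all(truth))
    stop("ROC requires both cases and non-cases in the population")
  if (inherits(spec, "instrument_spec")) {
    value <- score_instrument(spec, pop)$score
    thresholds <- sort(unique(value))
  } else if (inherits(spec, "glucometer_spec")) {
    set.seed(seed)
    value <- glucometer_screen(spec, pop)$value
    thresholds <- seq(floor(min(value) / grid_step) * grid_step,
                      ceiling(max(value) / grid_step) * grid_step,
                      by = grid_step)
  } else stop("spec must be an instrument_spec or glucometer_spec")
  # sentinel above the range: nobody positive (sens 0, spec 1); the lowest
  # achievable threshold classifies everyone positive for scores, giving the
  # (sens 1, spec 0) endpoint
  thresholds <- c(thresholds, max(thresholds) + max(grid_step, 1))
  if (min(value) >= min(thresholds))
    thresholds <- c(min(thresholds) - max(grid_step, 1), thresholds)
  w <- pop$weight
  w_case <- sum(w[truth]); w_ctrl <- sum(w[!truth])
  sens <- spec_ <- numeric(length(thresholds))
  ord <- order(value)
  v_s <- value[ord]; t_s <- truth[ord]; w_s <- w[ord]
  cum_case <- cumsum(w_s * t_s); cum_ctrl <- cumsum(w_s * !t_s)
  for (i in seq_along(thresholds)) {
    j <- findInterval(thresholds[i], v_s, left.open = TRUE)  # last value < t
    below_case <- if (j > 0) cum_case[j] else 0
    below_ctrl <- if (j > 0) cum_ctrl[j] else 0
    sens[i] <- (w_case - below_case) / w_case
    spec_[i] <- below_ctrl / w_ctrl
  }
  curve <- data.frame(threshold = thresholds, sensitivity = sens,
                      specificity = spec_)
  curve <- curve[order(curve$threshold), ]
  rownames(curve) <- NULL
  fpr <- 1 - curve$specificity
  o <- order(fpr, curve$sensitivity)
  auc <- sum(diff(fpr[o]) * (utils::head(curve$sensitivity[o], -1) +
                               utils::tail(curve$sensitivity[o], -1)) / 2)
  attr(curve, "auc") <- auc
  class(curve) <- c("roc_curve", "data.frame")
  curve
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve:", nrow(x), "thresholds, AUC =",
      format(attr(x, "auc"), digits = 4), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(1 - x$specificity, x$sensitivity, type = "b",
       xlab = "1 - specificity", ylab = "Sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Recalibrate an instrument cut point on the national population
#'
#' Chooses the threshold maximizing the product of sensitivity and
#' specificity (the top-left-most ROC corner). Ties are broken toward the
#' higher-specificity (fewer-referral) threshold.
#'
#' @param curve A `roc_curve`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `product`.
#' @export
recalibrate_cutpoint <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"), nrow(curve) >= 1)
  prod <- curve$sensitivity * curve$specificity
  best <- max(prod)
  cand <- which(prod >= best - 1e-12)
  pick <- cand[which.max(curve$specificity[cand])]
  list(threshold = curve$threshold[pick],
       sensitivity = curve$sensitivity[pick],
       specificity = curve$specificity[pick],
       product = prod[pick])
}
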