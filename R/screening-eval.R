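#' Weighted confusion counts on the national scale
#'
#' Construct confusion counts (millions of persons) directly; the screening
#' evaluator produces these, and the constructor also lets printed national
#' tallies be fed through the same aggregation arithmetic.
#'
#' @param tp,fp,tn,fn Weighted counts in millions (all >= 0).
#' @param eligible_total Total eligible; defaults to the sum of the four
#'   cells.
#' @return List of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`,
#'   `eligible_total` and `referred_total` (tp + fp).
#' @export
confusion_counts <- function(tp, fp, tn, fn, eligible_total = tp + fp + tn + fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(v)) || any(v < 0))
    stop("confusion counts must be finite and non-negative")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 eligible_total = eligible_total,
                 referred_total = tp + fp),
            class = "confusion_counts")
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity, specificity, positive and negative predictive values, and the
#' number needed to screen (NNS) to detect one previously undiagnosed
#' diabetes case, defined as eligible persons screened per true positive.
#'
#' @param counts A `confusion_counts` object.
#' @return Named numeric vector with `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `nns`; `nns` is `NA` when no true positives exist.
#' @export
screening_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, c(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    nns = if (tp > 0) eligible_total / tp else NA_real_
  ))
}

#' Ratio of false-positive to true-positive screens
#'
#' @param counts A `confusion_counts` object.
#' @return `fp / tp`, or `NA` when there are no true positives.
#' @export
false_true_ratio <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp <= 0) return(NA_real_)
  counts$fp / counts$tp
}

# weighted confusion tallies: truth is undiagnosed diabetes confirmed by the
# fasting criterion; persons diabetic by other criteria but fasting < 7 count
# as non-cases
weighted_confusion <- function(pop, positive, fasting_threshold = 7.0) {
  truth <- pop$has_diabetes & !pop$previously_diagnosed &
    confirmatory_test(pop, fasting_threshold)
  w <- pop$weight
  confusion_counts(
    tp = sum(w[truth & positive]),
    fp = sum(w[!truth & positive]),
    tn = sum(w[!truth & !positive]),
    fn = sum(w[truth & !positive]),
    eligible_total = sum(w)
  )
}

#' Evaluate a screening strategy on the eligible population
#'
#' Applies the strategy's first-stage tests to every eligible person, crosses
#' the screen result with true undiagnosed-diabetes status (diabetes present,
#' no prior diagnosis, and confirmed by the fasting >= 7.0 mmol/l criterion),
#' and accumulates weighted counts on the national scale (millions).
#'
#' @param pop A `population_sample` (the eligible subset is taken
#'   automatically).
#' @param strategy A `screen_strategy`.
#' @param seed Integer seed for stochastic screen components.
#' @return Object of class `screen_eval`: `counts` (`confusion_counts`),
#'   `metrics` (see [screening_metrics()]), `fp_tp_ratio`, `stage_tested`
#'   (weighted millions tested per stage, named by cost activity), `strategy`
#'   label.
#' @export
evaluate_strategy <- function(pop, strategy, seed = 1L) {
  stopifnot(inherits(pop, "population_sample"))
  pop <- eligible_subset(pop)
  if (!nrow(pop)) stop("no eligible persons in population")
  set.seed(seed)
  res <- apply_strategy(strategy, pop)
  counts <- weighted_confusion(pop, res$positive)
  stage_tested <- vapply(res$stages,
                         function(st) sum(pop$weight[st$tested]), 0)
  names(stage_tested) <- vapply(res$stages, `[[`, "", "kind")
  out <- list(counts = counts, metrics = screening_metrics(counts),
              fp_tp_ratio = false_true_ratio(counts),
              stage_tested = stage_tested,
              strategy = strategy$label,
              positive = res$positive)
  class(out) <- "screen_eval"
  out
}

#' @export
print.screen_eval <- function(x, ...) {
  cat("Screening evaluation:", x$strategy, "\n")
  with(x$counts, cat(sprintf(
    "  eligible %.1fM; referred %.1fM | TP %.1fM FP %.1fM TN %.1fM FN %.1fM\n",
    eligible_total, referred_total, tp, fp, tn, fn)))
  m <- x$metrics
  cat(sprintf(
    "  sens %.1f%%  spec %.1f%%  PPV %.1f%%  NPV %.1f%%  NNS %.1f  FP:TP %.1f\n",
    100 * m["sensitivity"], 100 * m["specificity"], 100 * m["ppv"],
    100 * m["npv"], m["nns"], x$fp_tp_ratio))
  invisible(x)
}

#' Direct fasting-test comparator
#'
#' Bypasses first-stage screening: every eligible person receives the
#' laboratory fasting test, so the NNS equals eligible persons per confirmed
#' undiagnosed case.
#'
#' @inheritParams evaluate_strategy
#' @return A `screen_eval` object.
#' @export
direct_fasting_comparator <- function(pop, seed = 1L) {
  evaluate_strategy(pop, strategy_fasting(), seed = seed)
}

#' Screening restricted to demographic subgroups
#'
#' Applies a strategy only within strata matched by a predicate on the
#' stratum descriptors, emulating targeted programs (e.g. urban-only or
#' older-age screening).
#'
#' @inheritParams evaluate_strategy
#' @param subgroup Function taking the population data.frame and returning a
#'   logical vector (it may use `age_band`, `sex`, `location`, `income`).
#' @return A `screen_eval` for the subgroup, or `NULL` (with a message) when
#'   the subgroup is empty.
#' @export
targeted_screening <- function(pop, strategy, subgroup, seed = 1L) {
  stopifnot(inherits(pop, "population_sample"))
  keep <- subgroup(pop)
  if (!any(keep)) {
    message("targeted_screening: empty subgroup, skipped")
    return(NULL)
  }
  sub <- pop[keep, , drop = FALSE]
  attr(sub, "total_millions") <- sum(sub$weight)
  class(sub) <- class(pop)
  evaluate_strategy(sub, strategy, seed = seed)
}

#' Co-morbidity detection among screen positives
#'
#' Weighted fraction of screen-positive persons who also meet the
#' hypertension (SBP >= 140 or DBP >= 90 mm Hg) and obesity (BMI >= 30)
#' definitions — the conditions a diabetes screening program would co-detect.
#'
#' @inheritParams evaluate_strategy
#' @return Named numeric vector `hypertension`, `obesity` (fractions of
#'   screen positives), plus the marginal eligible-population fractions as
#'   `hypertension_marginal`, `obesity_marginal`.
#' @export
comorbidity_codetection <- function(pop, strategy, seed = 1L) {
  stopifnot(inherits(pop, "population_sample"))
  pop <- eligible_subset(pop)
  set.seed(seed)
  res <- apply_strategy(strategy, pop)
  htn <- pop$sbp >= 140 | pop$dbp >= 90
  obe <- pop$bmi >= 30
  w <- pop$weight
  wpos <- sum(w[res$positive])
  c(hypertension = if (wpos > 0) sum(w[res$positive & htn]) / wpos else NA_real_,
    obesity = if (wpos > 0) sum(w[res$positive & obe]) / wpos else NA_real_,
    hypertension_marginal = sum(w[htn]) / sum(w),
    obesity_marginal = sum(w[obe]) / sum(w))
}
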