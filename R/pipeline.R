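#' Run configuration for the end-to-end microsimulation
#'
#' @param seed Master integer seed; every random stage derives from it.
#' @param n_persons Simulated individuals per draw (default 200000).
#' @param n_draws Monte Carlo draws over input-parameter uncertainty
#'   (default 500; 10000 for production-grade intervals).
#' @param strategies Named list of `screen_strategy` objects; default is the
#'   three questionnaire instruments plus random glucometer testing.
#' @param year Calendar year the surface is predicted for.
#' @param total_millions National population total, millions.
#' @param truth `ground_truth` driving the synthetic evidence base.
#' @param n_studies Synthetic cohort studies to generate and fit.
#' @param costs A `cost_model`.
#' @param run_complications Whether to run the complication/NNST stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_persons = 200000L, n_draws = 500L,
                       strategies = default_strategies(), year = 2015,
                       total_millions = 586, truth = default_truth(),
                       n_studies = 58L, costs = cost_model(),
                       run_complications = TRUE) {
  if (n_draws < 1) stop("`n_draws` must be >= 1")
  if (!length(strategies)) stop("`strategies` must be non-empty")
  if (is.null(names(strategies)) || any(names(strategies) == ""))
    stop("`strategies` must be a named list")
  structure(list(seed = as.integer(seed), n_persons = as.integer(n_persons),
                 n_draws = as.integer(n_draws), strategies = strategies,
                 year = year, total_millions = total_millions, truth = truth,
                 n_studies = as.integer(n_studies), costs = costs,
                 run_complications = run_complications),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_strategies <- function() {
  list(chaturvedi = strategy_instrument("chaturvedi"),
       mohan = strategy_instrument("mohan"),
       ramachandran = strategy_instrument("ramachandran"),
       glucometer = strategy_glucometer())
}

#' Empirical 95% credible interval
#'
#' Summarizes Monte Carlo draws as the median point estimate with 2.5th and
#' 97.5th percentile bounds (type-7 interpolation, the R default: the p-th
#' quantile interpolates between order statistics at position
#' `(n - 1) * p + 1`). The mean is also reported.
#'
#' @param draws Numeric vector of per-draw values (NAs dropped).
#' @param name Optional quantity name.
#' @return Object of class `credible_interval`: `point` (median), `lower`,
#'   `upper`, `mean`, `n_draws`.
#' @export
summarize_draws <- function(draws, name = NULL) {
  draws <- draws[is.finite(draws)]
  if (!length(draws)) {
    out <- list(point = NA_real_, lower = NA_real_, upper = NA_real_,
                mean = NA_real_, n_draws = 0L, name = name)
    class(out) <- "credible_interval"
    return(out)
  }
  q <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  out <- list(point = q[2], lower = q[1], upper = q[3],
              mean = mean(draws), n_draws = length(draws), name = name)
  class(out) <- "credible_interval"
  out
}

#' @export
print.credible_interval <- function(x, ...) {
  cat(sprintf("%s%.4g (95%% CrI %.4g-%.4g; mean %.4g; %d draws)\n",
              if (!is.null(x$name)) paste0(x$name, ": ") else "",
              x$point, x$lower, x$upper, x$mean, x$n_draws))
  invisible(x)
}

#' @export
as.data.frame.credible_interval <- function(x, ...) {
  data.frame(quantity = x$name %||% NA_character_, point = x$point,
             lower = x$lower, upper = x$upper, mean = x$mean,
             n_draws = x$n_draws)
}

# one complete model evaluation at a given surface and seed; returns a named
# numeric vector of outputs
run_one_draw <- function(config, surface, seed) {
  demo <- make_demographics(config$total_millions)
  pop <- build_population(demo, surface, config$truth$risk_factors,
                          config$n_persons, seed = seed)
  elig <- eligible_subset(pop)
  out <- c(eligible_millions = sum(elig$weight),
           diabetes_millions = sum(pop$weight[pop$has_diabetes]),
           undiagnosed_millions = sum(pop$weight[pop$has_diabetes &
                                                   !pop$previously_diagnosed]))
  fast <- direct_fasting_comparator(pop, seed = seed + 1L)
  out["fasting_nns"] <- fast$metrics[["nns"]]
  for (nm in names(config$strategies)) {
    ev <- evaluate_strategy(pop, config$strategies[[nm]], seed = seed + 2L)
    cs <- cost_strategy(ev, config$costs)
    vals <- c(ev$metrics,
              tp = ev$counts$tp, fp = ev$counts$fp, tn = ev$counts$tn,
              fn = ev$counts$fn, referred = ev$counts$referred_total,
              fp_tp_ratio = ev$fp_tp_ratio,
              total_cost = cs$total_cost, cost_per_case = cs$cost_per_case)
    if (config$run_complications) {
      cases <- elig[ev$positive & elig$has_diabetes &
                      confirmatory_test(elig), , drop = FALSE]
      if (nrow(cases)) {
        nr <- nnst(cases)
        vals <- c(vals, fraction_avoiding = nr$fraction_avoiding,
                  min_nnst = nr$min_nnst,
                  cost_per_complication_prevented =
                    cost_per_complication_prevented(cs, nr, ev$counts$tp))
      }
    }
    names(vals) <- paste(nm, names(vals), sep = ".")
    out <- c(out, vals)
  }
  out
}

#' Run the full uncertainty pipeline
#'
#' End-to-end probabilistic run: generates the synthetic cohort-study
#' evidence base, fits the meta-regressions, then for each Monte Carlo draw
#' samples a coefficient vector (propagating estimation uncertainty),
#' rebuilds the microsimulated population (so person-level sampling noise is
#' included), evaluates every configured screening strategy, costs it, and
#' (optionally) runs the complication/NNST stage. Outputs are aggregated to
#' 95% credible intervals. Per-draw seeds are pre-drawn from the master seed
#' so each draw is reproducible independently of execution order.
#'
#' @param config A `run_config`.
#' @return Object of class `screen_sim`: `summary` data.frame (one row per
#'   quantity: point/lower/upper/mean), `draws` matrix (draw x quantity),
#'   `fits` (the fitted meta-regressions), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  draw_seeds <- sample.int(.Machine$integer.max - 10L, config$n_draws)
  studies <- simulate_cohort_studies(config$truth, config$n_studies,
                                     seed = config$seed + 1L)
  outcomes <- names(config$truth$coefficients)
  fits <- lapply(outcomes, function(oc)
    fit_meta_regression(studies, oc, scale = config$truth$scale,
                        year_ref = config$truth$year_ref))
  names(fits) <- outcomes
  surfaces <- sample_surface(fits, config$year, config$n_draws,
                             seed = config$seed + 2L)
  rows <- vector("list", config$n_draws)
  failed <- 0L
  for (i in seq_len(config$n_draws)) {
    rows[[i]] <- tryCatch(
      run_one_draw(config, surfaces[[i]], seed = draw_seeds[i]),
      error = function(e) {
        warning("draw ", i, " failed and was discarded: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(rows[[i]])) failed <- failed + 1L
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("all draws failed")
  qty <- unique(unlist(lapply(rows, names)))
  draws <- t(vapply(rows, function(r) r[qty], numeric(length(qty))))
  colnames(draws) <- qty
  summ <- do.call(rbind, lapply(qty, function(q)
    as.data.frame(summarize_draws(draws[, q], name = q))))
  structure(list(summary = summ, draws = draws, fits = fits,
                 config = config, n_failed = failed),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Diabetes-screening microsimulation:",
      nrow(x$draws), "draws x", x$config$n_persons, "persons;",
      length(x$config$strategies), "strategies\n")
  if (x$n_failed) cat("  (", x$n_failed, "draws failed and were discarded)\n")
  key <- x$summary[grepl(
    "millions$|\\.(sensitivity|specificity|nns|tp|fp|cost_per_case)$",
    x$summary$quantity), ]
  print(transform(key, point = signif(point, 4), lower = signif(lower, 4),
                  upper = signif(upper, 4), mean = NULL), row.names = FALSE)
  invisible(x)
}

#' @export
summary.screen_sim <- function(object, ...) object$summary

#' Write pipeline report tables
#'
#' Emits a metrics table (one row per strategy: sensitivity, specificity,
#' predictive values, NNS with credible intervals), a burden table (weighted
#' confusion counts and costs in millions), and a JSON summary of every
#' aggregated quantity.
#'
#' @param sim A `screen_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(sim, dir) {
  stopifnot(inherits(sim, "screen_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- sim$summary
  get_ci <- function(strategy, metric) {
    r <- s[s$quantity == paste(strategy, metric, sep = "."), ]
    if (!nrow(r)) return("")
    sprintf("%.3g (%.3g-%.3g)", r$point, r$lower, r$upper)
  }
  strategies <- names(sim$config$strategies)
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "nns")
  perf <- data.frame(strategy = strategies)
  for (m in metrics)
    perf[[m]] <- vapply(strategies, get_ci, "", metric = m)
  burden_rows <- c("tp", "fn", "tn", "fp", "referred", "total_cost",
                   "cost_per_case")
  burden <- data.frame(quantity = burden_rows)
  for (st in strategies)
    burden[[st]] <- vapply(burden_rows, function(m) get_ci(st, m), "")
  p1 <- file.path(dir, "performance.csv")
  p2 <- file.path(dir, "burden.csv")
  p3 <- file.path(dir, "summary.json")
  utils::write.csv(perf, p1, row.names = FALSE)
  utils::write.csv(burden, p2, row.names = FALSE)
  jsonlite::write_json(
    stats::setNames(
      lapply(seq_len(nrow(s)), function(i)
        list(point = s$point[i], lower = s$lower[i], upper = s$upper[i],
             mean = s$mean[i])),
      s$quantity),
    p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
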