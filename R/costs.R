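#' Program cost model
#'
#' Unit costs plus the implementation horizon and annual discount rate.
#' Costs are tabulated in 2014 US dollars over a 10-year horizon at a 3%
#' annual discount rate by default; the screened population is spread evenly
#' over the horizon (uniform annual throughput) for discounting.
#'
#' @param unit_costs A `unit_costs` vector from [make_unit_costs()].
#' @param horizon_years Implementation horizon (>= 1).
#' @param discount_rate Annual discount rate in [0, 1).
#' @param currency Currency label.
#' @return List of class `cost_model`.
#' @export
cost_model <- function(unit_costs = make_unit_costs(), horizon_years = 10,
                       discount_rate = 0.03, currency = "2014 US$") {
  if (horizon_years < 1) stop("`horizon_years` must be >= 1")
  if (discount_rate < 0 || discount_rate >= 1)
    stop("`discount_rate` must be in [0, 1)")
  structure(list(unit_costs = unit_costs, horizon_years = horizon_years,
                 discount_rate = discount_rate, currency = currency),
            class = "cost_model")
}

#' Discount factor for a uniform annual stream
#'
#' Sum over years t = 0 ... horizon-1 of (1 + rate)^-t; multiplying an
#' annual flow by this factor gives its present value over the horizon.
#'
#' @param horizon_years Number of years (>= 1).
#' @param rate Annual discount rate.
#' @return The discount factor (equals `horizon_years` when `rate` is 0).
#' @examples
#' discount_factor(10, 0.03)  # 8.7861
#' @export
discount_factor <- function(horizon_years, rate) {
  if (horizon_years < 1) stop("`horizon_years` must be >= 1")
  if (rate == 0) return(as.numeric(horizon_years))
  (1 - (1 + rate)^(-horizon_years)) / (1 - (1 + rate)^-1)
}

#' Discounted cost of a screening strategy
#'
#' Charges each first-stage test to the weighted persons it was applied to
#' (serial second stages only among first-stage positives), the confirmatory
#' laboratory test to everyone referred, and annual overhead proportional to
#' persons screened per year. Throughput is uniform over the horizon, so the
#' present value is the undiscounted total scaled by
#' `discount_factor(h, r) / h`.
#'
#' @param eval A `screen_eval` from [evaluate_strategy()] (or a list with
#'   `counts` and `stage_tested` in millions).
#' @param model A `cost_model`.
#' @return Object of class `cost_summary`: `total_cost` (millions),
#'   `cost_per_case` (dollars per true positive), component breakdown
#'   `screening`, `confirmatory`, `overhead` (discounted millions).
#' @export
cost_strategy <- function(eval, model = cost_model()) {
  stopifnot(inherits(model, "cost_model"))
  uc <- model$unit_costs
  stage_kinds <- names(eval$stage_tested)
  stage_cost_per <- vapply(stage_kinds, function(k)
    switch(k, questionnaire = uc[["questionnaire"]],
           glucometer = uc[["glucometer"]],
           confirmatory = uc[["confirmatory"]],
           none = 0, stop("unknown stage kind '", k, "'")), 0)
  screening_undisc <- sum(stage_cost_per * eval$stage_tested)
  confirmatory_undisc <- uc[["confirmatory"]] * eval$counts$referred_total
  # overhead scales with persons entering screening each year
  overhead_annual <- uc[["overhead_per_person_year"]] *
    eval$counts$eligible_total / model$horizon_years
  df <- discount_factor(model$horizon_years, model$discount_rate)
  scale <- df / model$horizon_years
  screening <- screening_undisc * scale
  confirmatory <- confirmatory_undisc * scale
  overhead <- overhead_annual * df
  total <- screening + confirmatory + overhead
  tp <- eval$counts$tp
  structure(list(
    total_cost = total,
    cost_per_case = if (tp > 0) total / tp else NA_real_,
    screening = screening, confirmatory = confirmatory, overhead = overhead,
    currency = model$currency, strategy = eval$strategy %||% ""
  ), class = "cost_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf(
    "Cost (%s): total %.2fM = screening %.2fM + confirmatory %.2fM + overhead %.2fM\n",
    x$currency, x$total_cost, x$screening, x$confirmatory, x$overhead))
  cat(sprintf("  per true-positive case found: %.2f\n", x$cost_per_case))
  invisible(x)
}
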