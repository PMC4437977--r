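#' Load a questionnaire screening instrument definition
#'
#' Instrument definitions are declarative YAML files (items, category
#' predicates, points, cut point). The three encoded survey instruments ship
#' with the package: `"chaturvedi"`, `"mohan"` (Indian Diabetes Risk Score)
#' and `"ramachandran"`. A score greater than or equal to the cut point is a
#' positive screen.
#'
#' @param name Instrument name, or a path to a YAML file following the same
#'   schema.
#' @return A list of class `instrument_spec` with elements `name`, `label`,
#'   `cut_point`, `items` and `max_score` (sum of per-item maxima, validated
#'   against exhaustive enumeration).
#' @examples
#' chat <- load_instrument("chaturvedi")
#' chat$max_score  # 29
#' @export
load_instrument <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "instruments", paste0(name, ".yaml"),
                package = "diabscreen")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown instrument '", name, "'")
  spec <- yaml::read_yaml(path)
  validate_instrument(spec)
  spec$max_score <- sum(vapply(spec$items, item_max_points, 0))
  class(spec) <- "instrument_spec"
  spec
}

item_points_set <- function(item) {
  switch(item$type,
    numeric = as.numeric(item$points),
    categorical = as.numeric(unlist(item$points)),
    max_of = sort(unique(unlist(lapply(item$components, item_points_set)))),
    stop("unknown item type '", item$type, "'")
  )
}

item_max_points <- function(item) max(item_points_set(item))

validate_instrument <- function(spec) {
  stopifnot(is.character(spec$name), is.numeric(spec$cut_point),
            length(spec$items) >= 1)
  for (item in spec$items) {
    pts <- item_points_set(item)
    if (any(pts < 0) || any(pts != round(pts)))
      stop("points for item '", item$factor,
           "' must be non-negative integers")
    if (item$type == "numeric") {
      br <- if (!is.null(item$sex_breaks)) item$sex_breaks else
        list(item$breaks)
      for (b in br) {
        if (is.unsorted(b, strictly = TRUE))
          stop("breaks for '", item$factor, "' must be strictly increasing")
        if (length(item$points) != length(b) + 1L)
          stop("item '", item$factor, "': need one more point value than breaks")
      }
    }
  }
  invisible(spec)
}

#' Maximum achievable instrument score by exhaustive enumeration
#'
#' Enumerates every combination of one category per item (the full Cartesian
#' product of category point values) and returns the maximum total score.
#'
#' @param spec An `instrument_spec`.
#' @return List with `max_score` and `n_combinations` enumerated.
#' @export
instrument_max_score <- function(spec) {
  sets <- lapply(spec$items, item_points_set)
  grid <- do.call(expand.grid, sets)
  totals <- rowSums(as.matrix(grid))
  list(max_score = max(totals), n_combinations = nrow(grid))
}

score_item <- function(item, profiles) {
  if (item$type == "max_of") {
    comp <- lapply(item$components, score_item, profiles = profiles)
    return(do.call(pmax, comp))
  }
  x <- profiles[[item$factor]]
  if (is.null(x))
    stop("profiles lack factor '", item$factor, "' required by the instrument")
  if (item$type == "categorical") {
    pts <- unlist(item$points)
    s <- pts[match(x, names(pts))]
    if (anyNA(s))
      stop("unmatched category for factor '", item$factor, "': ",
           paste(unique(x[is.na(s)]), collapse = ", "))
    return(as.numeric(s))
  }
  # numeric item: interval membership via breaks; left-closed [b, b') or
  # right-closed (b, b'] intervals
  left_open <- identical(item$closed, "right")
  pts <- as.numeric(item$points)
  if (!is.null(item$sex_breaks)) {
    sex <- profiles$sex
    if (is.null(sex)) stop("profiles lack 'sex' needed for factor '",
                           item$factor, "'")
    s <- numeric(length(x))
    for (sx in names(item$sex_breaks)) {
      i <- which(sex == sx)
      if (!length(i)) next
      bin <- findInterval(x[i], as.numeric(item$sex_breaks[[sx]]),
                          left.open = left_open)
      s[i] <- pts[bin + 1L]
    }
    if (!all(sex %in% names(item$sex_breaks)))
      stop("unmatched sex level for factor '", item$factor, "'")
    return(s)
  }
  bin <- findInterval(x, as.numeric(item$breaks), left.open = left_open)
  pts[bin + 1L]
}

#' Score a questionnaire instrument on risk-factor profiles
#'
#' @param spec An `instrument_spec`.
#' @param profiles data.frame of risk-factor profiles (must include `sex`
#'   where the instrument uses sex-specific waist bands).
#' @return data.frame with integer `score` and logical `positive`
#'   (score >= cut point).
#' @examples
#' chat <- load_instrument("chaturvedi")
#' p <- data.frame(age = 45, sbp = 125, dbp = 70, sex = "male", waist = 85,
#'                 family_history = "one_parent_or_sibling")
#' score_instrument(chat, p)  # 22 points, positive
#' @export
score_instrument <- function(spec, profiles) {
  stopifnot(inherits(spec, "instrument_spec"))
  s <- Reduce(`+`, lapply(spec$items, score_item, profiles = profiles))
  data.frame(score = s, positive = s >= spec$cut_point)
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(x$label, "\n  items:",
      paste(vapply(x$items, `[[`, "", "factor"), collapse = ", "),
      "\n  cut point:", x$cut_point, " max score:", x$max_score, "\n")
  invisible(x)
}

#' Random capillary glucometer screen specification
#'
#' Point-of-care random (non-fasting) glucose screening. The measured value
#' is the person's true random plasma glucose plus additive Normal device
#' error (Bland-Altman SD); the screen is positive at or above the threshold.
#'
#' @param threshold Positivity threshold in mmol/l (inclusive; default 6.1).
#' @param meter_error_sd Device error SD in mmol/l (default 0.9).
#' @return List of class `glucometer_spec`.
#' @export
glucometer_spec <- function(threshold = 6.1, meter_error_sd = 0.9) {
  if (threshold <= 0) stop("`threshold` must be positive")
  if (meter_error_sd < 0) stop("`meter_error_sd` must be >= 0")
  structure(list(name = "glucometer", label = "Random glucometer testing",
                 threshold = threshold, meter_error_sd = meter_error_sd),
            class = "glucometer_spec")
}

#' Apply the glucometer screen
#'
#' @param spec A `glucometer_spec`.
#' @param profiles data.frame with column `rpg` (true random plasma glucose,
#'   mmol/l).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return data.frame with `value` (measured mmol/l) and logical `positive`.
#' @export
glucometer_screen <- function(spec, profiles, seed = NULL) {
  stopifnot(inherits(spec, "glucometer_spec"))
  if (is.null(profiles$rpg)) stop("profiles lack 'rpg'")
  if (!is.null(seed)) set.seed(seed)
  measured <- profiles$rpg +
    stats::rnorm(nrow(profiles), 0, spec$meter_error_sd)
  data.frame(value = measured, positive = measured >= spec$threshold)
}

#' Confirmatory laboratory diagnosis
#'
#' Laboratory fasting plasma glucose; diabetes is confirmed at
#' >= 7.0 mmol/l.
#'
#' @param profiles data.frame with column `fpg` (true fasting plasma
#'   glucose, mmol/l).
#' @param threshold Diagnostic threshold (default 7.0, inclusive).
#' @return Logical vector: diabetes confirmed.
#' @export
confirmatory_test <- function(profiles, threshold = 7.0) {
  if (is.null(profiles$fpg)) stop("profiles lack 'fpg'")
  profiles$fpg >= threshold
}

# ---- screening strategies (first-stage test compositions) -----------------

new_strategy <- function(kind, label, ...) {
  structure(list(kind = kind, label = label, ...),
            class = "screen_strategy")
}

#' Screening strategies
#'
#' A strategy is the first-stage test (or composition of tests) that decides
#' referral to confirmatory laboratory testing. Constructors wrap a
#' questionnaire instrument, the glucometer screen, the coin-flip comparator,
#' or direct fasting laboratory testing; [combine_serial()] and
#' [combine_parallel()] compose any two strategies.
#'
#' @param spec An `instrument_spec` or `glucometer_spec`.
#' @return A `screen_strategy` object.
#' @name strategies
NULL

#' @rdname strategies
#' @export
strategy_instrument <- function(spec) {
  if (is.character(spec)) spec <- load_instrument(spec)
  stopifnot(inherits(spec, "instrument_spec"))
  new_strategy("instrument", spec$label, spec = spec)
}

#' @rdname strategies
#' @export
strategy_glucometer <- function(spec = glucometer_spec()) {
  stopifnot(inherits(spec, "glucometer_spec"))
  new_strategy("glucometer", spec$label, spec = spec)
}

#' @rdname strategies
#' @param p Referral probability of the coin-flip comparator.
#' @export
strategy_coinflip <- function(p = 0.5) {
  stopifnot(p >= 0, p <= 1)
  new_strategy("coinflip", sprintf("Coin flip (p = %g)", p), p = p)
}

#' @rdname strategies
#' @param threshold Diagnostic fasting threshold (mmol/l).
#' @export
strategy_fasting <- function(threshold = 7.0) {
  new_strategy("fasting", "Direct fasting laboratory testing",
               threshold = threshold)
}

#' Serial combination of two screening strategies
#'
#' The second test is applied only to persons positive on the first; referral
#' requires both to be positive (conjunction). The staging is recorded so
#' costs can charge the second test only among first-stage positives.
#'
#' @param first,second `screen_strategy` objects.
#' @return A composite `screen_strategy`.
#' @export
combine_serial <- function(first, second) {
  stopifnot(inherits(first, "screen_strategy"),
            inherits(second, "screen_strategy"))
  new_strategy("serial", paste(first$label, "then", second$label),
               first = first, second = second)
}

#' Parallel combination of two screening strategies
#'
#' Both tests are performed on everyone; referral requires either to be
#' positive (disjunction).
#'
#' @param a,b `screen_strategy` objects.
#' @return A composite `screen_strategy`.
#' @export
combine_parallel <- function(a, b) {
  stopifnot(inherits(a, "screen_strategy"), inherits(b, "screen_strategy"))
  new_strategy("parallel", paste(a$label, "and", b$label, "(parallel)"),
               first = a, second = b)
}

#' @export
print.screen_strategy <- function(x, ...) {
  cat("Screening strategy:", x$label, "\n")
  invisible(x)
}

#' Apply a screening strategy to profiles
#'
#' Evaluates the first-stage test composition on every profile. Uses the
#' current RNG stream for stochastic components (glucometer error, coin
#' flip); set a seed beforehand for reproducibility.
#'
#' @param strategy A `screen_strategy`.
#' @param profiles data.frame of risk-factor profiles.
#' @return List with `positive` (logical vector) and `stages` (list of
#'   per-stage records: `kind` — the unit-cost activity — and `tested`,
#'   the logical vector marking whom the stage was applied to).
#' @export
apply_strategy <- function(strategy, profiles) {
  stopifnot(inherits(strategy, "screen_strategy"))
  n <- nrow(profiles)
  all_tested <- rep(TRUE, n)
  switch(strategy$kind,
    instrument = {
      pos <- score_instrument(strategy$spec, profiles)$positive
      list(positive = pos,
           stages = list(list(kind = "questionnaire", tested = all_tested)))
    },
    glucometer = {
      pos <- glucometer_screen(strategy$spec, profiles)$positive
      list(positive = pos,
           stages = list(list(kind = "glucometer", tested = all_tested)))
    },
    coinflip = {
      pos <- stats::runif(n) < strategy$p
      list(positive = pos,
           stages = list(list(kind = "none", tested = all_tested)))
    },
    fasting = {
      pos <- confirmatory_test(profiles, strategy$threshold)
      list(positive = pos,
           stages = list(list(kind = "confirmatory", tested = all_tested)))
    },
    serial = {
      r1 <- apply_strategy(strategy$first, profiles)
      r2 <- apply_strategy(strategy$second, profiles)
      stages2 <- lapply(r2$stages, function(st) {
        st$tested <- st$tested & r1$positive
        st
      })
      list(positive = r1$positive & r2$positive,
           stages = c(r1$stages, stages2))
    },
    parallel = {
      r1 <- apply_strategy(strategy$first, profiles)
      r2 <- apply_strategy(strategy$second, profiles)
      list(positive = r1$positive | r2$positive,
           stages = c(r1$stages, r2$stages))
    },
    stop("unknown strategy kind '", strategy$kind, "'")
  )
}
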