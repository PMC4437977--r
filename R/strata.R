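#' Enumerate the demographic strata
#'
#' The national population is stratified by age band (25-44 / 45-65 years),
#' sex, urban/rural location, and income tertile of the standard of living
#' index, giving 2 x 2 x 2 x 3 = 24 cells.
#'
#' @return A data.frame with 24 rows and columns `age_band`, `sex`,
#'   `location`, `income`, plus a unique `stratum` id string.
#' @export
stratum_grid <- function() {
  g <- expand.grid(
    age_band = c("25-44", "45-65"),
    sex      = c("male", "female"),
    location = c("urban", "rural"),
    income   = c("low", "mid", "high"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g$stratum <- with(g, paste(age_band, sex, location, income, sep = "/"))
  g
}

#' Build the per-stratum demographic weights table
#'
#' Splits a national population total (in millions of persons) across the 24
#' strata. Shares are specified per factor family and combined independently;
#' the default emulates India's 2015 adult age structure: a young population
#' (62% aged 25-44), equal sexes, about one third urban, and income tertiles
#' equal by construction.
#'
#' @param total_millions Positive total population, millions of persons.
#' @param stratum_shares Either the string `"default"` or a named list with
#'   entries `age_band`, `sex`, `location`, `income`, each a named numeric
#'   vector of shares summing to 1.
#' @return A data.frame (class `demographic_table`): the stratum grid plus a
#'   `weight` column in millions, with attribute `total_millions`.
#' @examples
#' d <- make_demographics(586)
#' sum(d$weight)
#' @export
make_demographics <- function(total_millions, stratum_shares = "default") {
  if (!is.numeric(total_millions) || length(total_millions) != 1L ||
      !is.finite(total_millions) || total_millions <= 0)
    stop("`total_millions` must be a single positive number")
  if (identical(stratum_shares, "default")) {
    stratum_shares <- list(
      age_band = c("25-44" = 0.62, "45-65" = 0.38),
      sex      = c(male = 0.5, female = 0.5),
      location = c(urban = 1 / 3, rural = 2 / 3),
      income   = c(low = 1 / 3, mid = 1 / 3, high = 1 / 3)
    )
  } else if (identical(stratum_shares, "uniform")) {
    stratum_shares <- list(
      age_band = c("25-44" = 0.5, "45-65" = 0.5),
      sex      = c(male = 0.5, female = 0.5),
      location = c(urban = 0.5, rural = 0.5),
      income   = c(low = 1 / 3, mid = 1 / 3, high = 1 / 3)
    )
  }
  g <- stratum_grid()
  for (fam in c("age_band", "sex", "location", "income")) {
    sh <- stratum_shares[[fam]]
    if (is.null(sh)) stop("missing shares for family '", fam, "'")
    if (abs(sum(sh) - 1) > 1e-9)
      stop("shares for '", fam, "' sum to ", sum(sh), ", not 1")
    if (any(sh < 0)) stop("negative share in family '", fam, "'")
    lev <- unique(g[[fam]])
    if (!all(lev %in% names(sh)))
      stop("shares for '", fam, "' must name levels: ",
           paste(lev, collapse = ", "))
  }
  w <- with(stratum_shares,
            age_band[g$age_band] * sex[g$sex] *
              location[g$location] * income[g$income])
  g$weight <- as.numeric(w) * total_millions
  stopifnot(abs(sum(g$weight) - total_millions) <= 1e-9 * total_millions)
  attr(g, "total_millions") <- total_millions
  class(g) <- c("demographic_table", "data.frame")
  g
}

#' @export
print.demographic_table <- function(x, ...) {
  cat("Demographic weights table: 24 strata,",
      format(attr(x, "total_millions")), "million persons total\n")
  print.data.frame(x, ...)
  invisible(x)
}

# 0/1 moderator coding of a stratum row: reference categories are
# age 25-44, female, rural, low income (one dropped level per family).
stratum_moderators <- function(strata) {
  data.frame(
    age_45_65   = as.numeric(strata$age_band == "45-65"),
    male        = as.numeric(strata$sex == "male"),
    urban       = as.numeric(strata$location == "urban"),
    income_mid  = as.numeric(strata$income == "mid"),
    income_high = as.numeric(strata$income == "high")
  )
}
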