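# brute-force oracle: recompute sensitivity/specificity at a threshold by
# direct weighted comparison
brute_point <- function(pop, value, threshold) {
  truth <- pop$has_diabetes & !pop$previously_diagnosed &
    confirmatory_test(pop)
  w <- pop$weight
  pos <- value >= threshold
  c(sens = sum(w[truth & pos]) / sum(w[truth]),
    spec = sum(w[!truth & !pos]) / sum(w[!truth]))
}

test_that("ROC sweep equals the brute-force per-threshold oracle", {
  pop <- eligible_subset(std_pop())
  chat <- load_instrument("chaturvedi")
  curve <- roc_sweep(std_pop(), chat)
  value <- score_instrument(chat, pop)$score
  for (i in seq_len(nrow(curve))) {
    bp <- brute_point(pop, value, curve$threshold[i])
    expect_equal(curve$sensitivity[i], unname(bp["sens"]))
    expect_equal(curve$specificity[i], unname(bp["spec"]))
  }
})

test_that("ROC endpoints and monotonicity hold", {
  curve <- roc_sweep(std_pop(), load_instrument("mohan"))
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 0))
  expect_true(any(curve$sensitivity == 0 & curve$specificity == 1))
  o <- order(curve$threshold)
  expect_true(all(diff(curve$sensitivity[o]) <= 1e-12))
  expect_true(all(diff(curve$specificity[o]) >= -1e-12))
})

test_that("a perfectly separating value yields the (1, 1) corner and AUC 1", {
  p <- crisp_params()
  p$diabetic$location[["rpg"]] <- log(12)
  p$diabetic$scale[["rpg"]] <- 0
  p$nondiabetic$location[["rpg"]] <- log(5)
  p$nondiabetic$scale[["rpg"]] <- 0
  pop <- build_population(make_demographics(10), flat_surface(0.3, 1),
                          p, 2400, seed = 4)
  curve <- roc_sweep(pop, glucometer_spec(meter_error_sd = 0))
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 1))
  expect_equal(attr(curve, "auc"), 1, tolerance = 1e-9)
  best <- recalibrate_cutpoint(curve)
  expect_equal(best$product, 1, tolerance = 1e-12)
})

test_that("an uninformative score gives AUC near one half", {
  # age is independent of diabetes status in the generator, so an age-only
  # score carries no information about undiagnosed diabetes
  age_only <- tempfile(fileext = ".yaml")
  writeLines(c("name: age_only", "label: age only", "cut_point: 1", "items:",
               "  - {factor: age, type: numeric, closed: left, breaks: [30, 35, 40, 45, 50, 55, 60], points: [0, 1, 2, 3, 4, 5, 6, 7]}"),
             age_only)
  spec <- load_instrument(age_only)
  pop <- build_population(make_demographics(10), flat_surface(0.3, 1),
                          crisp_params(), 20000, seed = 9)
  # single age band so the score is pure noise with respect to status
  curve <- roc_sweep(pop, spec)
  expect_equal(attr(curve, "auc"), 0.5, tolerance = 0.1)
  unlink(age_only)
})

test_that("AUC is invariant under monotone transformation of the value", {
  p <- crisp_params()
  pop <- build_population(make_demographics(10), flat_surface(0.3, 1),
                          p, 10000, seed = 14)
  c1 <- roc_sweep(pop, glucometer_spec(meter_error_sd = 0), grid_step = 0.01)
  pop2 <- pop
  pop2$rpg <- pop$rpg^2 / 10    # strictly increasing on positive glucose
  c2 <- roc_sweep(pop2, glucometer_spec(meter_error_sd = 0), grid_step = 0.01)
  expect_equal(attr(c1, "auc"), attr(c2, "auc"), tolerance = 0.01)
})

test_that("cut-point recalibration matches exhaustive grid search on random curves", {
  set.seed(27)
  for (i in 1:200) {
    k <- sample(3:30, 1)
    sens <- sort(runif(k), decreasing = TRUE)
    spec <- sort(runif(k))
    curve <- data.frame(threshold = seq_len(k), sensitivity = sens,
                        specificity = spec)
    class(curve) <- c("roc_curve", "data.frame")
    best <- recalibrate_cutpoint(curve)
    prods <- sens * spec
    expect_equal(best$product, max(prods), tolerance = 1e-12)
    ties <- which(prods >= max(prods) - 1e-12)
    expect_equal(best$threshold, ties[which.max(spec[ties])])
  }
})

test_that("product ties break toward higher specificity", {
  curve <- data.frame(threshold = 1:3,
                      sensitivity = c(0.8, 0.4, 0.2),
                      specificity = c(0.1, 0.2, 0.4))
  curve$sensitivity <- c(0.8, 0.4, 0.2)
  curve$specificity <- c(0.1, 0.2, 0.4)  # products 0.08, 0.08, 0.08
  class(curve) <- c("roc_curve", "data.frame")
  best <- recalibrate_cutpoint(curve)
  expect_equal(best$threshold, 3)
})

test_that("the recalibrated product is at least the published cut point's", {
  pop <- std_pop()
  for (nm in c("chaturvedi", "mohan", "ramachandran")) {
    spec <- load_instrument(nm)
    curve <- roc_sweep(pop, spec)
    best <- recalibrate_cutpoint(curve)
    at_pub <- curve[which.min(abs(curve$threshold - spec$cut_point)), ]
    expect_gte(best$product, at_pub$sensitivity * at_pub$specificity)
  }
})

test_that("single-class populations are rejected", {
  expect_error(roc_sweep(no_case_pop(), load_instrument("mohan")),
               "cases and non-cases")
})

test_that("unweighted ROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  p <- crisp_params()
  pop <- build_population(make_demographics(10), flat_surface(0.3, 1),
                          p, 2400, seed = 8)
  pop$weight <- rep(1, nrow(pop))   # equal weights for comparability
  attr(pop, "total_millions") <- nrow(pop)
  chat <- load_instrument("chaturvedi")
  curve <- roc_sweep(pop, chat)
  elig <- eligible_subset(pop)
  truth <- elig$has_diabetes & confirmatory_test(elig)
  score <- score_instrument(chat, elig)$score
  ref <- pROC::roc(response = truth, predictor = score, quiet = TRUE,
                   direction = "<")
  expect_equal(attr(curve, "auc"), as.numeric(pROC::auc(ref)),
               tolerance = 1e-9)
})
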