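# hand-built two-study summary set on the raw proportion scale
mini_studies <- function(p, v, year = 2005) {
  k <- length(p)
  s <- data.frame(
    study_id = paste0("S", seq_len(k)), year = rep(year, k),
    n = rep(1000L, k),
    share_age_25_44 = 0.5, share_age_45_65 = 0.5,
    share_female = 0.5, share_male = 0.5,
    share_rural = 0.5, share_urban = 0.5,
    share_income_low = 1 / 3, share_income_mid = 1 / 3,
    share_income_high = 1 / 3,
    p_prevalence = p, var_prevalence = v
  )
  class(s) <- c("cohort_studies", "data.frame")
  s
}

test_that("equal-variance intercept-only pooling is the arithmetic mean", {
  s <- mini_studies(c(0.10, 0.30), c(0.001, 0.001))
  fit <- fit_meta_regression(s, "prevalence", scale = "linear",
                             intercept_only = TRUE)
  expect_equal(unname(fit$beta["intercept"]), 0.20, tolerance = 1e-10)
})

test_that("a single study is returned as-is with zero heterogeneity", {
  s <- mini_studies(0.17, 0.002)
  fit <- fit_meta_regression(s, "prevalence", scale = "linear",
                             intercept_only = TRUE)
  expect_equal(unname(fit$beta["intercept"]), 0.17, tolerance = 1e-12)
  expect_equal(fit$tau2, 0)
})

test_that("fixed-effect fit equals the brute-force weighted least-squares oracle", {
  truth <- default_truth()
  studies <- simulate_cohort_studies(truth, 40, seed = 21)
  fit <- fit_meta_regression(studies, "prevalence", method = "FE")
  # independent WLS: beta = (X'WX)^-1 X'Wy with W = 1/vi on the logit scale
  eps <- 1e-6
  p <- pmin(pmax(studies$p_prevalence, eps), 1 - eps)
  y <- qlogis(p)
  vi <- studies$var_prevalence / (p * (1 - p))^2
  X <- cbind(1, studies$share_age_45_65, studies$share_male,
             studies$share_urban, studies$share_income_mid,
             studies$share_income_high, studies$year - 2005)
  W <- diag(1 / vi)
  beta_wls <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  expect_equal(unname(fit$beta), drop(beta_wls), tolerance = 1e-8)
  expect_equal(fit$tau2, 0)
})

test_that("duplicating a study at half the variance pulls the pooled estimate toward it", {
  base <- mini_studies(c(0.10, 0.30), c(0.001, 0.001))
  fit0 <- fit_meta_regression(base, "prevalence", scale = "linear",
                              intercept_only = TRUE, method = "FE")
  dup <- mini_studies(c(0.10, 0.30, 0.30), c(0.001, 0.001, 0.0005))
  fit1 <- fit_meta_regression(dup, "prevalence", scale = "linear",
                              intercept_only = TRUE, method = "FE")
  expect_gt(fit1$beta["intercept"], fit0$beta["intercept"])
})

test_that("degenerate designs fail loudly", {
  s <- mini_studies(c(0.1, 0.2, 0.3), rep(0.001, 3))
  expect_error(fit_meta_regression(s, "prevalence"), "at least|singular")
  s2 <- mini_studies(c(0.1, 0.2), c(0.001, -0.001))
  expect_error(fit_meta_regression(s2, "prevalence", intercept_only = TRUE),
               "positive")
  expect_error(fit_meta_regression(s, "nonexistent"), "lack columns")
})

test_that("coefficients are recovered from a simulated evidence base", {
  truth <- default_truth()
  studies <- simulate_cohort_studies(truth, 60, seed = 7)
  fit <- fit_meta_regression(studies, "prevalence")
  se <- sqrt(diag(fit$vcov))
  expect_equal(names(fit$beta), names(truth$coefficients$prevalence))
  # every coefficient within 3 SE for this single seed (2-SE coverage over
  # many seeds is exercised in the acceptance suite)
  expect_true(all(abs(fit$beta - truth$coefficients$prevalence) < 3 * se))
})

test_that("recovery bias shrinks as the evidence base grows", {
  truth <- default_truth()
  err <- vapply(c(20, 60, 200), function(k) {
    n_rng <- c(5000L, 50000L)
    bias <- rowMeans(vapply(1:5, function(s) {
      st <- simulate_cohort_studies(truth, k, seed = 100 + s,
                                    n_range = n_rng,
                                    between_sd = 0.05,
                                    outcomes = "prevalence")
      fit_meta_regression(st, "prevalence")$beta -
        truth$coefficients$prevalence
    }, numeric(7)))
    sqrt(mean(bias^2))
  }, 0)
  expect_lt(err[3], err[1])
})

test_that("surface prediction reproduces flat, monotone and time-invariant cases", {
  flat <- list(prevalence = fake_fit(full_beta(intercept = qlogis(0.12))))
  s <- predict_surface(flat, 2015)
  expect_equal(s$prevalence, rep(0.12, 24), tolerance = 1e-12)

  urb <- list(prevalence = fake_fit(full_beta(intercept = qlogis(0.10),
                                              urban = 0.5)))
  su <- predict_surface(urb, 2015)
  m <- match(paste(su$age_band, su$sex, su$income)[su$location == "urban"],
             paste(su$age_band, su$sex, su$income)[su$location == "rural"])
  expect_true(all(su$prevalence[su$location == "urban"] >
                    su$prevalence[su$location == "rural"][m]))

  s1 <- predict_surface(flat, 2000)
  s2 <- predict_surface(flat, 2015)
  expect_equal(s1$prevalence, s2$prevalence)
})

test_that("linear-scale predictions outside [0,1] are clamped with a message", {
  f <- list(prevalence = fake_fit(full_beta(intercept = 1.2),
                                  scale = "linear"))
  expect_message(s <- predict_surface(f, 2005), "clamped")
  expect_true(all(s$prevalence <= 1))
})

test_that("surface sampling is seeded, degenerate at zero variance, and matches the SE", {
  flat <- list(prevalence = fake_fit(full_beta(intercept = qlogis(0.12))))
  draws <- sample_surface(flat, 2015, 5, seed = 1)
  for (d in draws) expect_equal(d$prevalence, rep(0.12, 24))

  a <- sample_surface(std_fits(), 2015, 3, seed = 123)
  b <- sample_surface(std_fits(), 2015, 3, seed = 123)
  expect_identical(a, b)

  # 1-parameter fit on the linear scale: the surface value is the coefficient
  # draw itself, so the empirical SD must match the coefficient SE
  se <- 0.05
  one <- list(prevalence = fake_fit(c(intercept = 0.5),
                                    vcov = matrix(se^2, 1, 1),
                                    scale = "linear"))
  ds <- sample_surface(one, 2005, 10000, seed = 99)
  vals <- vapply(ds, function(d) d$prevalence[1], 0)
  expect_equal(sd(vals) / se, 1, tolerance = 0.05)
})
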