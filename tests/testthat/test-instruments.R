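base_profile <- function(...) {
  p <- data.frame(age = 30, sex = "male", sbp = 110, dbp = 70, bmi = 22,
                  waist = 70, family_history = "none",
                  physical_activity = "regular_exercise_and_strenuous_work",
                  rpg = 5, fpg = 5, hba1c = 5.5, ldl = 2.5, smoker = FALSE,
                  cvd_history = FALSE, stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) p[[nm]] <- args[[nm]]
  p
}

test_that("the three encoded instruments reach their published maximum scores", {
  expected <- c(chaturvedi = 29, mohan = 100, ramachandran = 42)
  for (nm in names(expected)) {
    spec <- load_instrument(nm)
    enum <- instrument_max_score(spec)
    expect_equal(enum$max_score, unname(expected[nm]), info = nm)
    expect_equal(spec$max_score, unname(expected[nm]), info = nm)
    expect_gt(enum$n_combinations, 1)
  }
})

test_that("worked scoring examples match the published point values", {
  chat <- load_instrument("chaturvedi")
  # all base categories
  r0 <- score_instrument(chat, base_profile())
  expect_equal(r0$score, 0)
  expect_false(r0$positive)
  # age 45 (+4), SBP 125 (+5), sibling history (+4), male waist 85 (+9)
  r22 <- score_instrument(chat, base_profile(
    age = 45, sbp = 125, family_history = "one_parent_or_sibling",
    waist = 85))
  expect_equal(r22$score, 22)
  expect_true(r22$positive)
  # every maximal category
  rmax <- score_instrument(chat, base_profile(
    age = 55, sbp = 150, dbp = 95, family_history = "both_parents",
    waist = 95))
  expect_equal(rmax$score, 29)
})

test_that("a score equal to the cut point screens positive", {
  chat <- load_instrument("chaturvedi")
  # BP >= 140 (+7) and male waist 85 (+9) = 16 = cut point
  r <- score_instrument(chat, base_profile(sbp = 140, waist = 85))
  expect_equal(r$score, 16)
  expect_true(r$positive)
  r15 <- score_instrument(chat, base_profile(sbp = 125, waist = 85,
                                             age = 30))
  expect_equal(r15$score, 14)
  expect_false(r15$positive)
})

test_that("blood pressure scores the worse of systolic and diastolic", {
  chat <- load_instrument("chaturvedi")
  expect_equal(score_instrument(chat, base_profile(sbp = 110, dbp = 92))$score, 7)
  expect_equal(score_instrument(chat, base_profile(sbp = 125, dbp = 70))$score, 5)
  expect_equal(score_instrument(chat, base_profile(sbp = 145, dbp = 85))$score, 7)
})

test_that("scores are integers in range and monotone in risk categories", {
  specs <- lapply(c("chaturvedi", "mohan", "ramachandran"), load_instrument)
  set.seed(99)
  prof <- data.frame(
    age = runif(500, 25, 65), sex = sample(c("male", "female"), 500, TRUE),
    sbp = runif(500, 90, 180), dbp = runif(500, 60, 110),
    bmi = runif(500, 16, 40), waist = runif(500, 60, 120),
    family_history = sample(c("none", "one_parent_or_sibling",
                              "both_parents"), 500, TRUE),
    physical_activity = sample(c("regular_exercise_and_strenuous_work",
                                 "one_of_the_two", "neither"), 500, TRUE),
    stringsAsFactors = FALSE
  )
  worse <- prof
  worse$age <- worse$age + 5
  worse$sbp <- worse$sbp + 20
  worse$dbp <- worse$dbp + 10
  worse$bmi <- worse$bmi + 5
  worse$waist <- worse$waist + 15
  worse$family_history <- "both_parents"
  worse$physical_activity <- "neither"
  for (spec in specs) {
    s <- score_instrument(spec, prof)$score
    expect_true(all(s == round(s)))
    expect_true(all(s >= 0 & s <= spec$max_score))
    expect_true(all(score_instrument(spec, worse)$score >= s))
  }
})

test_that("an unmatched category names the offending factor", {
  chat <- load_instrument("chaturvedi")
  expect_error(score_instrument(chat, base_profile(family_history = "cousin")),
               "family_history")
  p <- base_profile(); p$waist <- NULL
  expect_error(score_instrument(chat, p), "waist")
})

test_that("glucometer screen applies the inclusive threshold and additive error", {
  noerr <- glucometer_spec(meter_error_sd = 0)
  expect_true(glucometer_screen(noerr, base_profile(rpg = 10))$positive)
  expect_true(glucometer_screen(noerr, base_profile(rpg = 6.1))$positive)
  expect_false(glucometer_screen(noerr, base_profile(rpg = 6.09))$positive)

  spec <- glucometer_spec()   # SD 0.9, threshold 6.1
  prof <- base_profile(rpg = 6.1)[rep(1, 10000), ]
  res <- glucometer_screen(spec, prof, seed = 4)
  expect_equal(mean(res$positive), 0.5, tolerance = 0.02)
  expect_equal(sd(res$value), 0.9, tolerance = 0.03)
})

test_that("confirmatory fasting test is strict below 7.0 mmol/l", {
  expect_true(confirmatory_test(base_profile(fpg = 7.0)))
  expect_false(confirmatory_test(base_profile(fpg = 6.99)))
  expect_false(confirmatory_test(base_profile(fpg = 5.0)))
})

test_that("serial self-combination of a deterministic test is idempotent", {
  chat <- strategy_instrument("chaturvedi")
  pop <- std_pop()
  single <- evaluate_strategy(pop, chat, seed = 1)
  twice <- evaluate_strategy(pop, combine_serial(chat, chat), seed = 1)
  expect_equal(twice$counts$tp, single$counts$tp)
  expect_equal(twice$counts$fp, single$counts$fp)
})

test_that("serial conjunction is order-symmetric in classification", {
  a <- strategy_instrument("chaturvedi")
  b <- strategy_instrument("mohan")
  pop <- std_pop()
  ab <- evaluate_strategy(pop, combine_serial(a, b), seed = 1)
  ba <- evaluate_strategy(pop, combine_serial(b, a), seed = 1)
  expect_equal(ab$counts$tp, ba$counts$tp)
  expect_equal(ab$counts$fp, ba$counts$fp)
  # staged test counts differ: second stage only sees first-stage positives
  expect_false(isTRUE(all.equal(ab$stage_tested, ba$stage_tested,
                                check.attributes = FALSE)))
})

test_that("independent serial sensitivities multiply and parallel specificities multiply", {
  cases <- all_case_pop()
  serial <- combine_serial(strategy_coinflip(0.7), strategy_coinflip(0.6))
  ev <- evaluate_strategy(cases, serial, seed = 12)
  expect_equal(unname(ev$metrics["sensitivity"]), 0.42, tolerance = 0.03)

  ctrls <- no_case_pop()
  par <- combine_parallel(strategy_coinflip(0.2), strategy_coinflip(0.2))
  evp <- evaluate_strategy(ctrls, par, seed = 12)
  expect_equal(unname(evp$metrics["specificity"]), 0.64, tolerance = 0.03)
})

test_that("parallel combination with an always-negative test is the identity", {
  pop <- std_pop()
  chat <- strategy_instrument("chaturvedi")
  alone <- evaluate_strategy(pop, chat, seed = 3)
  with_null <- evaluate_strategy(pop, combine_parallel(chat,
                                                       strategy_coinflip(0)),
                                 seed = 3)
  expect_equal(with_null$counts$tp, alone$counts$tp)
  expect_equal(with_null$counts$fp, alone$counts$fp)
})

test_that("instrument specs validate their schema", {
  expect_error(load_instrument("no_such_instrument"), "unknown")
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("name: bad", "cut_point: 1", "items:",
               "  - factor: age", "    type: numeric", "    closed: left",
               "    breaks: [40]", "    points: [0, -2]"), bad)
  expect_error(load_instrument(bad), "non-negative")
  unlink(bad)
})
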