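test_that("eligibility cascade reproduces the published arithmetic", {
  led <- apply_eligibility_filters(c(
    total_surgical = 766, amputation = 4, under_18 = 33, deceased = 74,
    unknown_address = 12, insufficient_postop_images = 6, responders = 362))
  expect_equal(led$eligible, 637)
  expect_equal(response_rate(led), 57)
})

test_that("eligibility works on patient-level records", {
  n <- 10
  rec <- data.frame(amputation = FALSE, under_18 = FALSE, deceased = FALSE,
                    unknown_address = FALSE,
                    insufficient_postop_images = FALSE,
                    responded = TRUE)[rep(1, n), ]
  led <- apply_eligibility_filters(rec)
  expect_equal(led$eligible, 10)
  expect_equal(response_rate(led), 100)
  rec$deceased <- TRUE
  led2 <- apply_eligibility_filters(rec)
  expect_equal(led2$eligible, 0)
  expect_error(response_rate(led2), "no eligible")
  led3 <- led; led3$responders <- 0L
  expect_equal(response_rate(led3), 0)
})

test_that("one-way ANOVA matches hand computation and handles degenerate input", {
  res <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  # between SS 54 on 2 df, within SS 6 on 6 df -> F = 27 (verified with aov)
  expect_equal(res$F, 27, tolerance = 1e-12)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p_value, anova(lm(v ~ g, data.frame(
    v = c(1:3, 4:6, 7:9), g = rep(letters[1:3], each = 3))))$`Pr(>F)`[1],
    tolerance = 1e-12)
  # identical constant groups: no between-group variation
  expect_equal(one_way_anova(list(a = c(2, 2), b = c(2, 2)))$F, 0)
  expect_error(one_way_anova(list(a = 1:5)), "at least 2")
})

test_that("group summaries report per-group means and handle empty groups", {
  co <- data.frame(initial_gap_mm2 = c(100, 120, 300), symptoms = 80,
                   pain = 80, adl = 80, sport = 80, qol = 80)
  gs <- group_summary(co)
  ex <- gs[gs$group == "excellent" & gs$subscale == "symptoms", ]
  expect_equal(ex$n, 2)
  expect_equal(ex$mean, 80)
  expect_equal(ex$sd, 0)
  poor <- gs[gs$group == "poor" & gs$subscale == "symptoms", ]
  expect_equal(poor$n, 0)
  expect_true(is.na(poor$mean))
})

test_that("group means of simulated cohorts match the configured model", {
  spec <- cohort_spec(n = 3000, seed = 11, p_tka = 0)
  co <- simulate_cohort(spec)
  gs <- group_summary(co)
  grp <- assign_prognostic_group(co$initial_gap_mm2)
  m <- spec$models$symptoms
  for (g in levels(grp)) {
    mu_true <- mean(m$intercept + m$b_gap * co$initial_gap_mm2[grp == g] / 100)
    row <- gs[gs$group == g & gs$subscale == "symptoms", ]
    expect_lt(abs(row$mean - mu_true), 2 * 18 / sqrt(row$n) + 0.5)
  }
})

test_that("zero-noise cohorts are fit exactly by the adjusted model", {
  spec <- cohort_spec(n = 150, seed = 3, p_tka = 0, outcome = list(
    symptoms = list(sd = 0, b_gap = -0.9,
                    effects = list(age = -0.05, female = 2, bmi = -0.1,
                                   smoking = -1, complication = -3,
                                   inadequate_reduction = -4,
                                   follow_up = 0.2))))
  co <- simulate_cohort(spec)
  stopifnot(all(co$symptoms > 0 & co$symptoms < 100))  # clamp inactive
  fit <- suppressWarnings(fit_ols(co, "symptoms"))  # lm flags the perfect fit
  expect_equal(unname(gap_coefficient(fit)["estimate"]), -0.9,
               tolerance = 1e-8)
  est <- fit$terms
  expect_equal(est$estimate[est$term == "age"], -0.05, tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "sexfemale"], 2, tolerance = 1e-8)
  # AO/OTA carries no configured effect: all dummies ~ 0
  expect_true(all(abs(est$estimate[grepl("^ao_ota", est$term)]) < 1e-8))
})

test_that("the residual-displacement model omits the reduction confounder", {
  co <- simulate_cohort(cohort_spec(n = 120, seed = 5, p_tka = 0,
                                    gap_source = "residual"))
  fit_i <- fit_ols(co, "symptoms", "initial_gap_mm2")
  fit_r <- fit_ols(co, "symptoms", "residual_gap_mm2")
  expect_true("inadequate_reductionTRUE" %in% fit_i$terms$term)
  expect_false(any(grepl("inadequate_reduction", fit_r$terms$term)))
})

test_that("a constant predictor raises a rank-deficiency error naming the term", {
  co <- simulate_cohort(cohort_spec(n = 80, seed = 9, p_tka = 0))
  co$initial_gap_mm2 <- 500
  expect_error(fit_ols(co, "symptoms"), "gap_per_100mm2")
})

test_that("OLS residuals are orthogonal to the standardized design", {
  co <- simulate_cohort(cohort_spec(n = 250, seed = 13, p_tka = 0))
  fit <- fit_ols(co, "qol")$fit
  X <- model.matrix(fit)
  Xs <- scale(X[, -1])
  r <- residuals(fit)
  expect_lt(max(abs(crossprod(Xs, r))) / nrow(X), 1e-6)
})

test_that("confidence intervals bracket the estimate with t-based width", {
  co <- simulate_cohort(cohort_spec(n = 200, seed = 17, p_tka = 0))
  fit <- fit_ols(co, "sport")
  g <- gap_coefficient(fit)
  expect_lt(g["conf_low"], g["estimate"])
  expect_gt(g["conf_high"], g["estimate"])
  expect_true(g["p_value"] >= 0 && g["p_value"] <= 1)
})

test_that("nonresponse comparisons follow the Welch and chi-square formulas", {
  r <- nonresponse_tests(list(n = 50, age_mean = 5, age_sd = 1, n_female = 25),
                         list(n = 50, age_mean = 6, age_sd = 1, n_female = 25))
  expect_equal(r$age$t, -5, tolerance = 1e-12)
  expect_equal(r$sex$chisq, 0, tolerance = 1e-12)
  same <- list(n = 40, age_mean = 50, age_sd = 10, n_female = 20)
  r2 <- nonresponse_tests(same, same)
  expect_equal(r2$age$p_value, 1)
  expect_equal(r2$sex$p_value, 1)
  # published summaries: responders vs nonresponders
  r3 <- nonresponse_tests(
    list(n = 362, age_mean = 52.7, age_sd = 14.0, n_female = 252),
    list(n = 275, age_mean = 48.9, age_sd = 16.9, n_female = 164))
  expect_lt(r3$age$p_value, 0.05)
  expect_gt(r3$age$p_value, 0)
})
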