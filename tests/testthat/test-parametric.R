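test_that("intercept-only pooled logistic equals the occurrence/exposure ratio", {
  # simple unweighted case: 1 event in 10 person-days
  pd <- data.frame(arm = "treated", day = rep(1:5, 2), at_risk = 1L,
                   death = c(rep(0L, 9), 1L), discharge = 0L, weight = 1,
                   admission_month = "Mar")
  fit <- fit_pooled_logistic(pd, "treated", "death")
  expect_equal(fit$hazard, 0.1, tolerance = 1e-8)

  # zero events
  pd$death <- 0L
  expect_equal(fit_pooled_logistic(pd, "treated", "death")$hazard, 0)

  # random weighted tables against the direct ratio, glm optimiser route
  set.seed(99)
  for (i in 1:10) {
    n <- 200
    pd <- data.frame(
      arm = sample(c("treated", "untreated"), n, TRUE),
      day = sample(1:20, n, TRUE), at_risk = 1L,
      death = rbinom(n, 1, 0.05), discharge = 0L,
      weight = rexp(n, 1) + 0.1, admission_month = "Mar"
    )
    pd$discharge <- ifelse(pd$death == 0L, rbinom(n, 1, 0.1), 0L)
    for (arm in c("treated", "untreated")) {
      sub <- pd[pd$arm == arm, ]
      oracle <- sum(sub$weight * sub$death) / sum(sub$weight)
      fit <- fit_pooled_logistic(pd, arm, "death", method = "glm")
      expect_equal(fit$hazard, oracle, tolerance = 1e-8)
    }
  }
})

test_that("hazard estimates are invariant to rescaling all weights", {
  co <- simulate_cohort(recovery_config(500), seed = 3)
  cloned <- attach_weights(apply_grace_censoring(clone_cohort(co)))
  pd <- person_day_table(cloned)
  h1 <- hazard_estimates(pd)
  pd$weight <- pd$weight * 7
  h2 <- hazard_estimates(pd)
  expect_equal(h1$lambda_02, h2$lambda_02)
  expect_equal(h1$lambda_13, h2$lambda_13)
})

test_that("glm, ratio and clone-direct routes agree", {
  co <- simulate_cohort(confounded_config(600), seed = 7)
  cloned <- attach_weights(apply_grace_censoring(clone_cohort(co)))
  pd <- person_day_table(cloned)
  h_glm <- hazard_estimates(pd, method = "glm")
  h_ratio <- hazard_estimates(pd, method = "ratio")
  h_clone <- hazard_estimates(cloned, method = "ratio")
  for (f in c("lambda_02", "lambda_03", "lambda_12", "lambda_13")) {
    expect_equal(h_glm[[f]], h_ratio[[f]], tolerance = 1e-7)
    expect_equal(h_ratio[[f]], h_clone[[f]], tolerance = 1e-12)
  }
  expect_error(fit_pooled_logistic(pd, "treated", "death",
                                   adjustment = "admission_month",
                                   method = "ratio"), "ratio")
})

test_that("month adjustment marginalises back to the crude hazard when months are exchangeable", {
  co <- simulate_cohort(recovery_config(800), seed = 17)
  cloned <- attach_weights(apply_grace_censoring(clone_cohort(co)))
  pd <- person_day_table(cloned)
  crude <- hazard_estimates(pd)
  adj <- hazard_estimates(pd, adjustment = "admission_month")
  # months carry no information in this generator: standardised and crude
  # marginal hazards agree closely
  expect_equal(adj$lambda_03, crude$lambda_03, tolerance = 0.02)
  expect_equal(adj$lambda_02, crude$lambda_02, tolerance = 0.2)
})

test_that("an arm without person-time raises an informative error", {
  pd <- data.frame(arm = "untreated", day = 1, at_risk = 1L, death = 0L,
                   discharge = 1L, weight = 1, admission_month = "Mar")
  expect_error(fit_pooled_logistic(pd, "treated", "death"), "no person-days")
})

test_that("cif_constant matches its closed form, limits and quadrature", {
  expect_equal(cif_constant(0.01, 0.125, 0), 0)
  expect_equal(cif_constant(0, 0, 10), 0)
  # eventual cause fraction: lambda_cause = lambda_total / 2
  expect_equal(cif_constant(0.05, 0.1, 1e9), 0.5)
  # quadrature oracle
  q <- integrate(function(s) 0.01 * exp(-0.125 * s), 0, 30)$value
  expect_equal(cif_constant(0.01, 0.125, 30), q, tolerance = 1e-9)
  expect_error(cif_constant(0.2, 0.1, 5), "lambda_cause")
  expect_error(cif_constant(0.01, 0.1, -1), "nonnegative")
})

test_that("death and discharge incidences share the all-cause envelope", {
  set.seed(11)
  for (i in 1:250) {
    lt <- runif(1, 0, 0.5)
    lc <- runif(1, 0, lt)
    t <- runif(1, 0, 80)
    expect_equal(cif_constant(lc, lt, t) + cif_constant(lt - lc, lt, t),
                 1 - exp(-lt * t), tolerance = 1e-12)
  }
})

test_that("effect_measures reproduces every catalogue entry", {
  h <- list(lambda_02 = 0.00925, lambda_03 = 0.11575,
            lambda_12 = 0.00725, lambda_13 = 0.11775)
  ef <- effect_measures(h, tau = 60)
  expect_equal(ef$mortality_risk_untreated, 0.074)
  expect_equal(ef$mortality_risk_treated, 0.058)
  expect_equal(ef$mortality_difference, -0.016)
  expect_equal(ef$discharge_difference, 0.016)
  expect_equal(round(ef$discharge_risk_ratio, 2), 1.02)
  expect_equal(ef$hr_death, 0.00725 / 0.00925)
  expect_equal(ef$los_untreated, 8)
  expect_equal(ef$los_treated, 8)
  expect_equal(ef$curves$time, 0:60)
  expect_true(all(diff(ef$curves$cif_death_treated) >= 0))

  # finite-time identity: RD2(t) + RD3(t) equals the difference of envelopes
  t <- ef$curves$time
  env <- (1 - exp(-(0.00725 + 0.11775) * t)) - (1 - exp(-0.125 * t))
  expect_equal(ef$curves$rd_death + ef$curves$rd_discharge, env,
               tolerance = 1e-12)
})

test_that("identical arms give null effects and zero denominators give NA", {
  h <- list(lambda_02 = 0.01, lambda_03 = 0.115,
            lambda_12 = 0.01, lambda_13 = 0.115)
  ef <- effect_measures(h)
  expect_equal(ef$mortality_difference, 0)
  expect_equal(ef$hr_death, 1)
  expect_equal(ef$hr_discharge, 1)
  expect_equal(ef$los_difference, 0)
  expect_true(all(abs(ef$curves$rd_death) < 1e-15))
  expect_true(all(ef$curves$rr_death[-1] == 1))

  h0 <- list(lambda_02 = 0, lambda_03 = 0.1, lambda_12 = 0.01,
             lambda_13 = 0.1)
  ef0 <- effect_measures(h0)
  expect_true(is.na(ef0$hr_death))
  expect_false(is.na(ef0$los_untreated))
})

test_that("odds ratios approximate rate ratios for small daily hazards", {
  # intercept-contrast odds ratio vs the plain rate ratio over a grid of
  # daily hazards up to 0.15: relative error stays under 20%
  grid <- expand.grid(h0 = seq(0.005, 0.15, by = 0.005),
                      h1 = seq(0.005, 0.15, by = 0.005))
  or <- (grid$h1 / (1 - grid$h1)) / (grid$h0 / (1 - grid$h0))
  rr <- grid$h1 / grid$h0
  expect_true(all(abs(or / rr - 1) < 0.2))
})

test_that("hazard_ratio_ci returns point estimates and bootstrap bounds", {
  h <- list(lambda_02 = 0.01, lambda_03 = 0.1, lambda_12 = 0.008,
            lambda_13 = 0.1)
  out <- hazard_ratio_ci(h)
  expect_equal(out$estimate, c(0.8, 1.0))

  co <- simulate_cohort(recovery_config(400), seed = 29)
  out <- hazard_ratio_ci(h, cohort = co, B = 40, seed = 2)
  expect_true(all(out$ci_low <= out$estimate | is.na(out$ci_low) |
                    out$ci_low <= out$ci_high))
  expect_true(all(out$ci_low <= out$ci_high))
})
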