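test_that("censoring covariate effects are near zero when initiation is random", {
  co <- simulate_cohort(recovery_config(4000), seed = 31)
  cloned <- apply_grace_censoring(clone_cohort(co))
  for (arm in c("treated", "untreated")) {
    m <- fit_censoring_model(cloned, arm)
    # rough Wald-style bound: coefficients scaled by covariate spread
    sds <- vapply(co$records[m$covariate_list], sd, numeric(1))
    expect_true(all(abs(m$coefficients * sds) < 0.2),
                label = paste("standardised coefficients near 0 in", arm))
  }
})

test_that("an arm with no artificial censorings yields a degenerate model", {
  co <- make_cohort(treatment_day = c(1L, 1L, 1L), event_day = c(5L, 7L, 9L),
                    event_type = c("death", "discharge", "discharge"))
  cloned <- apply_grace_censoring(clone_cohort(co))
  expect_warning(m <- fit_censoring_model(cloned, "treated"), "no artificial")
  expect_true(m$degenerate)
  expect_equal(prob_uncensored(m, co$records), rep(1, 3))
})

test_that("with no covariates the censoring survival is the product-limit estimate", {
  co <- simulate_cohort(simulation_config(n = 500), seed = 13)
  cloned <- apply_grace_censoring(clone_cohort(co))
  m <- fit_censoring_model(cloned, "untreated", covariates = character(0))

  # oracle: empirical per-day censoring hazards over the same risk sets
  cl <- cloned$clones[cloned$clones$arm == "untreated", ]
  time <- pmin(cl$end_day, 2)
  cen <- cl$end_reason == "artificial_censor"
  km <- prod(vapply(1:2, function(s) {
    1 - sum(cen & time == s) / sum(time >= s)
  }, numeric(1)))
  p <- prob_uncensored(m, co$records[1, ])
  expect_equal(unname(p), km, tolerance = 1e-10)
})

test_that("discrete and cox engines agree on who gets up-weighted most", {
  co <- simulate_cohort(confounded_config(1500), seed = 19)
  cloned <- apply_grace_censoring(clone_cohort(co))
  md <- fit_censoring_model(cloned, "untreated", engine = "discrete")
  mc <- fit_censoring_model(cloned, "untreated", engine = "cox")
  pd <- prob_uncensored(md, co$records)
  pc <- prob_uncensored(mc, co$records)
  # same direction of confounding: strong rank agreement between engines
  expect_gt(cor(pd, pc, method = "spearman"), 0.95)
  # both detect that low oxygen saturation raises censoring (treatment)
  expect_lt(md$coefficients[["spo2"]], 0)
  expect_lt(mc$coefficients[["spo2"]], 0)
})

test_that("the exponential form obeys its closed-form identities", {
  m <- structure(
    list(arm = "untreated", engine = "cox", covariate_list = "age",
         grace_period_days = 2L, degenerate = FALSE,
         coefficients = c(age = log(2)), centers = c(age = 0),
         day_intercepts = NULL,
         baseline_cumhaz = data.frame(day = 1:2, increment = c(log(2), 0),
                                      hazard = c(log(2), log(2)))),
    class = "ccw_censoring_model"
  )
  # Lambda0(g) = log 2, zero covariate effect (age at centre) -> exp(-log 2)
  expect_equal(
    prob_uncensored(m, data.frame(age = 0), form = "exponential"), 0.5)
  # doubling exp(x beta) squares the probability
  p1 <- prob_uncensored(m, data.frame(age = 1), form = "exponential")
  p2 <- prob_uncensored(m, data.frame(age = 2), form = "exponential")
  expect_equal(p2, p1^2)
  # Lambda0 = 0 -> probability 1
  m0 <- m
  m0$baseline_cumhaz$increment <- 0
  m0$baseline_cumhaz$hazard <- 0
  expect_equal(
    prob_uncensored(m0, data.frame(age = 5), form = "exponential"), 1)
})

test_that("weights are inverse probabilities and at least 1", {
  co <- simulate_cohort(confounded_config(800), seed = 23)
  cloned <- attach_weights(apply_grace_censoring(clone_cohort(co)))
  cl <- cloned$clones
  g <- cloned$protocol$grace_period_days
  expect_true(all(cl$weight >= 1))
  expect_true(all(cl$weight[cl$end_day <= g] == 1))
  # spot-check the inverse relation in the treated arm
  m <- cloned$censoring_models$treated
  sel <- cl$arm == "treated" & cl$end_day > g
  expect_equal(cl$weight[sel], unname(1 / prob_uncensored(m, cl[sel, ])))
})

test_that("weighting restores covariate balance broken by selective censoring", {
  co <- simulate_cohort(confounded_config(4000), seed = 41)
  cloned <- attach_weights(apply_grace_censoring(clone_cohort(co)))
  cl <- cloned$clones
  g <- cloned$protocol$grace_period_days
  target <- mean(co$records$spo2)
  for (a in c("treated", "untreated")) {
    post <- cl[cl$arm == a & cl$end_day > g, ]
    raw <- mean(post$spo2)
    wtd <- weighted.mean(post$spo2, post$weight)
    expect_gt(abs(raw - target), abs(wtd - target))
    expect_lt(abs(wtd - target), 0.75)   # Monte-Carlo slack on an sd-5 scale
  }
})

test_that("weighted survivors conserve the pseudo-population size", {
  co <- simulate_cohort(recovery_config(4000), seed = 53)
  cloned <- attach_weights(apply_grace_censoring(clone_cohort(co)))
  cl <- cloned$clones
  g <- cloned$protocol$grace_period_days
  for (a in c("treated", "untreated")) {
    post <- cl$arm == a & cl$end_day > g
    # patients still in hospital at the end of the grace period, either arm
    at_risk <- sum(co$records$event_day > g)
    expect_lt(abs(sum(cl$weight[post]) - at_risk) / at_risk, 0.1)
  }
})

test_that("covariate-free censoring models give equal weights within an arm", {
  co <- simulate_cohort(confounded_config(400), seed = 71)
  cloned <- apply_grace_censoring(clone_cohort(co))
  models <- list(
    treated = fit_censoring_model(cloned, "treated", covariates = character(0)),
    untreated = fit_censoring_model(cloned, "untreated",
                                    covariates = character(0))
  )
  cl <- attach_weights(cloned, models)$clones
  g <- cloned$protocol$grace_period_days
  for (a in c("treated", "untreated")) {
    w <- cl$weight[cl$arm == a & cl$end_day > g]
    expect_lt(diff(range(w)), 1e-12)
  }
})

test_that("weight truncation caps the extreme tail on request", {
  co <- simulate_cohort(confounded_config(1200), seed = 61)
  cloned <- apply_grace_censoring(clone_cohort(co))
  models <- list(treated = fit_censoring_model(cloned, "treated"),
                 untreated = fit_censoring_model(cloned, "untreated"))
  free <- attach_weights(cloned, models)
  expect_message(capped <- attach_weights(cloned, models, cap = 0.95),
                 "truncating")
  expect_lt(max(capped$clones$weight), max(free$clones$weight))
  expect_equal(max(capped$clones$weight),
               unname(quantile(free$clones$weight, 0.95)))
})
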