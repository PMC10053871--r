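test_that("protocol_config validates the grace period and horizon", {
  p <- protocol_config()
  expect_equal(p$grace_period_days, 2L)
  expect_equal(p$max_followup_days, 60L)
  expect_error(protocol_config(0), "positive")
  expect_error(protocol_config(5, 5), "exceed")
})

test_that("cloning duplicates every patient into both arms unchanged", {
  co <- fig_ten_cohort()
  cloned <- clone_cohort(co)
  expect_equal(nrow(cloned$clones), 2L * nrow(co$records))
  for (a in c("treated", "untreated")) {
    sub <- cloned$clones[cloned$clones$arm == a, ]
    expect_equal(nrow(sub), nrow(co$records))
    expect_equal(sub$end_day, pmin(co$records$event_day, 60L))
  }
  # no censoring yet; all ends are events here (every event day < 60)
  expect_true(all(cloned$clones$end_reason == "event"))
})

test_that("administrative censoring caps follow-up at the horizon", {
  co <- make_cohort(treatment_day = NA, event_day = 75L,
                    event_type = "discharge")
  cloned <- clone_cohort(co, protocol_config(2, 60))
  expect_true(all(cloned$clones$end_day == 60L))
  expect_true(all(cloned$clones$end_reason == "admin_censor"))
  expect_true(all(is.na(cloned$clones$event_type)))
})

test_that("grace-period censoring follows the protocol deviation rules", {
  cloned <- apply_grace_censoring(clone_cohort(fig_ten_cohort()))
  cl <- cloned$clones
  tr <- cl[cl$arm == "treated", ]
  un <- cl[cl$arm == "untreated", ]

  # ids 1-4 treated within grace: followed in the treated arm, censored at
  # their treatment day in the untreated arm
  expect_equal(tr$end_reason[1:4], rep("event", 4))
  expect_equal(un$end_reason[1:4], rep("artificial_censor", 4))
  expect_equal(un$end_day[1:4], c(1L, 2L, 1L, 2L))

  # ids 5-10 (late or never treated): censored at day 2 in the treated arm,
  # followed in the untreated arm
  expect_equal(tr$end_reason[5:10], rep("artificial_censor", 6))
  expect_equal(tr$end_day[5:10], rep(2L, 6))
  expect_equal(un$end_reason[5:10], rep("event", 6))

  expect_error(apply_grace_censoring(cloned), "already")
})

test_that("events within the grace period contribute to both arms", {
  # never treated, died day 1: both clones keep the death
  co <- make_cohort(treatment_day = c(NA, NA), event_day = c(1L, 2L),
                    event_type = c("death", "discharge"))
  cl <- apply_grace_censoring(clone_cohort(co))$clones
  expect_true(all(cl$end_reason == "event"))
  expect_equal(cl$event_type[cl$arm == "treated"], c("death", "discharge"))
  expect_equal(cl$end_day, rep(c(1L, 2L), 2))
})

test_that("a same-day treatment and event inside grace censors the untreated clone", {
  co <- make_cohort(treatment_day = 2L, event_day = 2L, event_type = "death")
  cl <- apply_grace_censoring(clone_cohort(co))$clones
  expect_equal(cl$end_reason[cl$arm == "treated"], "event")
  expect_equal(cl$end_reason[cl$arm == "untreated"], "artificial_censor")
  expect_equal(cl$end_day[cl$arm == "untreated"], 2L)
})

test_that("arm status counts mirror each other without grace-period events", {
  counts <- arm_status_counts(apply_grace_censoring(clone_cohort(fig_ten_cohort())))
  tr <- counts[counts$arm == "treated", ]
  un <- counts[counts$arm == "untreated", ]
  expect_equal(tr$followed, 4L)
  expect_equal(tr$artificially_censored, 6L)
  expect_equal(un$followed, 6L)
  expect_equal(un$artificially_censored, 4L)
  expect_equal(tr$followed + tr$artificially_censored, 10L)

  # nobody ever treated: the treated arm follows no one
  co <- make_cohort(treatment_day = c(NA, NA), event_day = c(5L, 8L),
                    event_type = c("death", "discharge"))
  counts <- arm_status_counts(apply_grace_censoring(clone_cohort(co)))
  expect_equal(counts$followed[counts$arm == "treated"], 0L)

  # everyone treated on day 1: the untreated arm follows no one
  co <- make_cohort(treatment_day = c(1L, 1L), event_day = c(5L, 8L),
                    event_type = c("death", "discharge"))
  counts <- suppressWarnings(
    arm_status_counts(apply_grace_censoring(clone_cohort(co)))
  )
  expect_equal(counts$followed[counts$arm == "untreated"], 0L)
})

test_that("the person-day table conserves days and flags events on final rows", {
  cloned <- apply_grace_censoring(clone_cohort(fig_ten_cohort()))
  pd <- person_day_table(cloned)
  expect_equal(nrow(pd), sum(cloned$clones$end_day))

  # a death on day 9 shows as 0,...,0,1
  rows <- pd[pd$arm == "treated" & pd$patient_id == "1", ]
  expect_equal(rows$death, c(rep(0L, 8), 1L))
  expect_equal(rows$discharge, rep(0L, 9))

  # an artificially censored clone has no events at all
  rows <- pd[pd$arm == "untreated" & pd$patient_id == "1", ]
  expect_equal(nrow(rows), 1L)
  expect_equal(rows$death + rows$discharge, 0L)

  # per arm and cause, person-day events match clone-level events
  cl <- cloned$clones
  for (a in c("treated", "untreated")) {
    expect_equal(sum(pd$death[pd$arm == a]),
                 sum(cl$arm == a & cl$end_reason == "event" &
                       cl$event_type == "death"))
    expect_equal(sum(pd$discharge[pd$arm == a]),
                 sum(cl$arm == a & cl$end_reason == "event" &
                       cl$event_type == "discharge"))
  }
})

test_that("after weighting, grace-period rows carry ladder weights", {
  set.seed(5)
  co <- simulate_cohort(recovery_config(400), seed = 8)
  cloned <- attach_weights(apply_grace_censoring(clone_cohort(co)))
  pd <- person_day_table(cloned)
  g <- cloned$protocol$grace_period_days

  # beyond the grace period every row carries its clone's final weight
  cl <- cloned$clones
  key <- paste(pd$patient_id, pd$arm)
  clone_w <- cl$weight[match(key, paste(cl$patient_id, cl$arm))]
  post <- pd$day > g
  expect_equal(pd$weight[post], clone_w[post])

  # ladder weights never decrease over the grace period for an uncensored
  # clone and end at most at the final weight
  first_day <- pd$day == 1 & pd$at_risk == 1
  expect_true(all(pd$weight[first_day] >= 1))

  # the treatment day of an untreated-arm censored clone bears no risk time
  cen <- cl[cl$arm == "untreated" & cl$end_reason == "artificial_censor", ]
  final_rows <- pd[pd$arm == "untreated" &
                     pd$patient_id %in% cen$patient_id &
                     pd$day == cen$end_day[match(pd$patient_id,
                                                 cen$patient_id)], ]
  expect_true(all(final_rows$at_risk == 0))
})
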