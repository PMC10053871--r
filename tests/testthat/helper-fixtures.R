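# deterministic fixture builders shared across the test files

# fill in complete baseline covariates around a skeleton of ids, treatment
# days and outcomes
make_cohort <- function(treatment_day, event_day, event_type,
                        patient_id = as.character(seq_along(event_day)),
                        age = 60, spo2 = 92, resp_rate = 20,
                        creatinine = 1.1, sex = 1, admission_month = "Mar") {
  n <- length(event_day)
  new_cohort(data.frame(
    patient_id = patient_id,
    age = rep_len(age, n), sex = rep_len(sex, n),
    spo2 = rep_len(spo2, n), resp_rate = rep_len(resp_rate, n),
    creatinine = rep_len(creatinine, n),
    admission_month = rep_len(admission_month, n),
    treatment_day = treatment_day, event_day = event_day,
    event_type = event_type,
    stringsAsFactors = FALSE
  ))
}

# the ten-patient hypothetical example: ids 1-4 treated within the two-day
# grace period, 5-6 treated after it, 7-10 never treated; odd ids die, even
# ids are discharged alive, all after the grace period
fig_ten_cohort <- function() {
  make_cohort(
    treatment_day = c(1L, 2L, 1L, 2L, 4L, 5L, NA, NA, NA, NA),
    event_day = c(9L, 9L, 12L, 9L, 10L, 11L, 10L, 8L, 6L, 7L),
    event_type = rep(c("death", "discharge"), 5)
  )
}

# unconfounded recovery world: initiation only inside the grace period, so
# the configured rates are exactly the counterfactual truth
recovery_config <- function(n, hr_death = 0.8, hr_discharge = 1.0) {
  simulation_config(
    n = n,
    treatment_model = list(daily_logit = c(qlogis(0.51), qlogis(0.07), -Inf),
                           coefficients = numeric()),
    hazard_model = list(lambda_02 = 0.01, lambda_03 = 0.115,
                        hr_death = hr_death, hr_discharge = hr_discharge,
                        death_coefficients = numeric(),
                        discharge_coefficients = numeric())
  )
}

# strong confounding by indication: low oxygen saturation drives both
# treatment initiation and the death hazard
confounded_config <- function(n) {
  simulation_config(
    n = n,
    treatment_model = list(daily_logit = c(qlogis(0.51), qlogis(0.07), -Inf),
                           coefficients = c(spo2 = -0.25)),
    hazard_model = list(lambda_02 = 0.01, lambda_03 = 0.115,
                        hr_death = 0.8, hr_discharge = 1.0,
                        death_coefficients = c(spo2 = -0.25),
                        discharge_coefficients = numeric())
  )
}
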