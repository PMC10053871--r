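#' Configuration for the synthetic hospital cohort generator
#'
#' The generator stands in for sensitive hospital data that cannot be shared:
#' it draws baseline covariates, lets them drive a discrete-time treatment
#' initiation process (confounding by indication: by default lower oxygen
#' saturation makes treatment more likely), and gives every patient competing
#' constant daily cause-specific hazards of in-hospital death and discharge
#' alive, multiplied by the treatment effect once treatment has started.
#' Within a day, treatment initiation is resolved before the exit draw,
#' mirroring the emulation's tie-break.
#'
#' Default rates are a daily death hazard of 0.01 and discharge hazard of
#' 0.115 untreated (eventual mortality 8%, mean stay of 8 days), a death
#' hazard ratio of 0.8 and discharge hazard ratio of 1.0 under treatment, and
#' day-1/day-2 initiation probabilities of 0.51/0.07 with a 0.02 daily rate
#' thereafter, so roughly half the cohort starts treatment on admission day
#' and a further handful within the two-day grace period.
#'
#' Covariate coefficients (log odds for treatment, log rate for hazards) act
#' on covariates centred at their configured means, so the configured
#' baseline rates stay interpretable as rates for an average patient.
#'
#' @param n cohort size (default 618 admissions).
#' @param tau follow-up horizon in days (default 60); the generator lets every
#'   patient run to an absorbing state, and administrative censoring at `tau`
#'   is applied later by the emulation.
#' @param seed default seed used by [simulate_cohort()].
#' @param covariates list of per-covariate specifications: `age` (mean, sd;
#'   truncated to \[18, 100\]), `sex` (p = probability of 1), `spo2` (mean,
#'   sd; clamped to \[50, 100\]), `resp_rate` (mean, sd; floored at 8),
#'   `creatinine` (meanlog, sdlog), `month_probs` (named probabilities).
#' @param treatment_model list with `daily_logit` (vector of per-day
#'   initiation log-odds for days 1, 2, ...; the last entry is recycled for
#'   all later days; `-Inf` disables initiation) and `coefficients` (named
#'   log-odds-per-unit covariate effects).
#' @param hazard_model list with untreated daily rates `lambda_02` (death)
#'   and `lambda_03` (discharge), treated multipliers `hr_death` and
#'   `hr_discharge`, and named covariate log-rate effects
#'   `death_coefficients` and `discharge_coefficients`.
#' @return object of class `ccw_sim_config`.
#' @export
simulation_config <- function(
    n = 618L,
    tau = 60L,
    seed = 1L,
    covariates = list(
      age = c(mean = 58, sd = 15),
      sex = c(p = 0.55),
      spo2 = c(mean = 90, sd = 5),
      resp_rate = c(mean = 22, sd = 5),
      creatinine = c(meanlog = log(1.1), sdlog = 0.4),
      month_probs = c(Feb = 0.3, Mar = 0.45, Apr = 0.25)
    ),
    treatment_model = list(
      daily_logit = stats::qlogis(c(0.51, 0.07, 0.02)),
      coefficients = c(spo2 = -0.15)
    ),
    hazard_model = list(
      lambda_02 = 0.01, lambda_03 = 0.115,
      hr_death = 0.8, hr_discharge = 1.0,
      death_coefficients = c(spo2 = -0.08),
      discharge_coefficients = numeric()
    )) {
  if (n < 1L) stop("n must be at least 1")
  hm <- hazard_model
  rates <- c(hm$lambda_02, hm$lambda_03,
             hm$lambda_02 * hm$hr_death, hm$lambda_03 * hm$hr_discharge)
  if (any(rates < 0) || any(rates > 1)) {
    stop("daily hazards must lie in [0, 1]")
  }
  if (hm$lambda_02 + hm$lambda_03 > 1 ||
      hm$lambda_02 * hm$hr_death + hm$lambda_03 * hm$hr_discharge > 1) {
    stop("all-cause daily hazard exceeds 1")
  }
  mp <- covariates$month_probs
  if (abs(sum(mp) - 1) > 1e-8 || any(mp < 0)) {
    stop("month_probs must be nonnegative and sum to 1")
  }
  structure(
    list(n = as.integer(n), tau = as.integer(tau), seed = as.integer(seed),
         covariates = covariates, treatment_model = treatment_model,
         hazard_model = hazard_model),
    class = "ccw_sim_config"
  )
}

# covariate centers used when applying coefficient effects
.config_centers <- function(config) {
  cv <- config$covariates
  c(age = unname(cv$age["mean"]),
    sex = unname(cv$sex["p"]),
    spo2 = unname(cv$spo2["mean"]),
    resp_rate = unname(cv$resp_rate["mean"]),
    creatinine = unname(exp(cv$creatinine["meanlog"] +
                              cv$creatinine["sdlog"]^2 / 2)))
}

.draw_covariates <- function(config, n) {
  cv <- config$covariates
  data.frame(
    age = pmin(pmax(stats::rnorm(n, cv$age["mean"], cv$age["sd"]), 18), 100),
    sex = as.numeric(stats::runif(n) < cv$sex["p"]),
    spo2 = pmin(pmax(stats::rnorm(n, cv$spo2["mean"], cv$spo2["sd"]), 50), 100),
    resp_rate = pmax(stats::rnorm(n, cv$resp_rate["mean"], cv$resp_rate["sd"]),
                     8),
    creatinine = stats::rlnorm(n, cv$creatinine["meanlog"],
                               cv$creatinine["sdlog"]),
    admission_month = sample(names(cv$month_probs), n, replace = TRUE,
                             prob = cv$month_probs),
    stringsAsFactors = FALSE
  )
}

# linear predictor of named coefficients on centred covariates
.linpred <- function(X, coefs, centers) {
  if (length(coefs) == 0L) return(rep(0, nrow(X)))
  lp <- rep(0, nrow(X))
  for (v in names(coefs)) {
    lp <- lp + coefs[[v]] * (X[[v]] - centers[[v]])
  }
  lp
}

# per-patient daily cause-specific rates by arm, clamped to a valid
# probability pair
.patient_rates <- function(config, X) {
  hm <- config$hazard_model
  centers <- .config_centers(config)
  md <- exp(.linpred(X, hm$death_coefficients, centers))
  mc <- exp(.linpred(X, hm$discharge_coefficients, centers))
  clamp_pair <- function(d, c.) {
    tot <- d + c.
    over <- tot > 0.99
    d[over] <- d[over] * 0.99 / tot[over]
    c.[over] <- c.[over] * 0.99 / tot[over]
    list(death = d, discharge = c.)
  }
  list(
    untreated = clamp_pair(hm$lambda_02 * md, hm$lambda_03 * mc),
    treated = clamp_pair(hm$lambda_02 * hm$hr_death * md,
                         hm$lambda_03 * hm$hr_discharge * mc)
  )
}

# day-by-day walk shared by the free simulation and the forced-arm oracle.
# forced_arm: NULL for the natural treatment process, "treated"/"untreated"
# to hold every patient in one counterfactual arm from admission.
.simulate_walk <- function(config, X, forced_arm = NULL) {
  n <- nrow(X)
  rates <- .patient_rates(config, X)
  tm <- config$treatment_model
  centers <- .config_centers(config)
  eta <- .linpred(X, tm$coefficients, centers)
  logits <- tm$daily_logit

  treated <- rep(identical(forced_arm, "treated"), n)
  treatment_day <- rep(NA_integer_, n)
  event_day <- rep(NA_integer_, n)
  event_type <- rep(NA_character_, n)
  active <- rep(TRUE, n)
  cap <- max(10L * config$tau, 1000L)

  for (t in seq_len(cap)) {
    if (!any(active)) break
    if (is.null(forced_arm)) {
      logit_t <- logits[min(t, length(logits))]
      cand <- which(active & !treated)
      if (length(cand) > 0L && is.finite(logit_t)) {
        p <- stats::plogis(logit_t + eta[cand])
        init <- cand[stats::runif(length(cand)) < p]
        treated[init] <- TRUE
        treatment_day[init] <- t
      }
    }
    idx <- which(active)
    ld <- ifelse(treated[idx], rates$treated$death[idx],
                 rates$untreated$death[idx])
    lc <- ifelse(treated[idx], rates$treated$discharge[idx],
                 rates$untreated$discharge[idx])
    u <- stats::runif(length(idx))
    died <- u < ld
    disch <- !died & u < ld + lc
    out <- died | disch
    event_day[idx[out]] <- t
    event_type[idx[died]] <- "death"
    event_type[idx[disch]] <- "discharge"
    active[idx[out]] <- FALSE
  }
  # stragglers past the hard cap (vanishingly rare with sane rates)
  if (any(active)) {
    event_day[active] <- cap
    event_type[active] <- "discharge"
  }
  data.frame(treatment_day = treatment_day, event_day = event_day,
             event_type = event_type, stringsAsFactors = FALSE)
}

#' Simulate a hospital cohort
#'
#' Draws a cohort from a [simulation_config()]: covariates first, then for
#' each day treatment initiation (if still untreated) followed by the exit
#' draw under the current arm's daily rates, until every patient dies or is
#' discharged. Identical seeds give identical cohorts.
#'
#' @param config a `ccw_sim_config`.
#' @param seed integer seed; defaults to `config$seed`.
#' @return a `ccw_cohort`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ccw_sim_config"))
  set.seed(seed)
  X <- .draw_covariates(config, config$n)
  walk <- .simulate_walk(config, X)
  rec <- cbind(
    data.frame(patient_id = as.character(seq_len(config$n)),
               stringsAsFactors = FALSE),
    X, walk
  )
  new_cohort(rec)
}

#' True counterfactual quantities implied by a simulation configuration
#'
#' Returns the estimand values the emulation pipeline should recover: the
#' four constant cause-specific hazards under "everyone treated from
#' admission" versus "everyone untreated", and the effect-measure catalogue
#' they imply. Without covariate effects on the hazards the truth is the
#' configured rates in closed form; with covariate effects the marginal rates
#' are obtained by Monte-Carlo, simulating a large internal sample in each
#' forced arm and taking the occurrence/exposure ratio of events to
#' person-days.
#'
#' @param config a `ccw_sim_config`.
#' @param n_mc internal Monte-Carlo sample size per arm (only used when
#'   covariate effects on the hazards are present; default `2e5`).
#' @param seed seed for the Monte-Carlo draw (default `config$seed + 1`).
#' @return list with `hazards` (a `ccw_hazards`-shaped list) and `effects`
#'   (from [effect_measures()] at the config's `tau`).
#' @export
true_quantities <- function(config, n_mc = 2e5,
                            seed = config$seed + 1L) {
  stopifnot(inherits(config, "ccw_sim_config"))
  hm <- config$hazard_model
  no_cov <- length(hm$death_coefficients) == 0L &&
    length(hm$discharge_coefficients) == 0L
  if (no_cov) {
    lam <- list(lambda_02 = hm$lambda_02, lambda_03 = hm$lambda_03,
                lambda_12 = hm$lambda_02 * hm$hr_death,
                lambda_13 = hm$lambda_03 * hm$hr_discharge)
  } else {
    set.seed(seed)
    X <- .draw_covariates(config, n_mc)
    rate_one <- function(arm) {
      walk <- .simulate_walk(config, X, forced_arm = arm)
      days <- pmin(walk$event_day, config$tau)
      counted <- walk$event_day <= config$tau
      c(death = sum(counted & walk$event_type == "death") / sum(days),
        discharge = sum(counted & walk$event_type == "discharge") / sum(days))
    }
    untr <- rate_one("untreated")
    trt <- rate_one("treated")
    lam <- list(lambda_02 = unname(untr["death"]),
                lambda_03 = unname(untr["discharge"]),
                lambda_12 = unname(trt["death"]),
                lambda_13 = unname(trt["discharge"]))
  }
  hazards <- structure(c(lam, list(detail = NULL, fits = NULL)),
                       class = "ccw_hazards")
  list(hazards = hazards, effects = effect_measures(hazards, tau = config$tau))
}

#' Continuous-time exponential competing-risks draws
#'
#' Companion generator in continuous time: exit times are exponential with
#' constant cause-specific rates, the exact data-generating process behind
#' the closed-form cumulative incidence functions. Returns a clone-style
#' table (unit weights, no censoring) that feeds straight into
#' [weighted_aalen_johansen()] and [weighted_nelson_aalen()], which accept
#' non-integer event times; useful for validating the estimators against
#' [cif_constant()] without daily-grid discretisation error.
#'
#' @param n number of draws.
#' @param lambda_death,lambda_discharge constant cause-specific rates per day.
#' @param seed integer seed.
#' @return data frame with columns `end_day` (continuous), `end_reason`
#'   (`"event"`), `event_type`, `weight`.
#' @export
simulate_exit_times <- function(n, lambda_death, lambda_discharge, seed = 1) {
  stopifnot(lambda_death >= 0, lambda_discharge >= 0,
            lambda_death + lambda_discharge > 0)
  set.seed(seed)
  total <- lambda_death + lambda_discharge
  times <- stats::rexp(n, total)
  cause <- ifelse(stats::runif(n) < lambda_death / total, "death", "discharge")
  data.frame(end_day = times, end_reason = "event", event_type = cause,
             weight = 1, stringsAsFactors = FALSE)
}
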