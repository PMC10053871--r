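#' Weighted pooled logistic regression for one arm and cause
#'
#' With time-constant daily hazards, a logistic regression pooled over
#' person-days estimates the discrete-time cause-specific hazard: the daily
#' indicator of this cause's event is regressed on the adjustment covariates,
#' weighting each person-day by its clone's IPC weight. Person-days ending in
#' the competing cause count as censored (indicator 0) for this cause's fit.
#' With no adjustment the fitted hazard is exactly the occurrence/exposure
#' ratio `sum(w * events) / sum(w * person-days)` (the intercept-only MLE).
#' With adjustment for admission month, the marginal hazard is obtained by
#' standardisation: the per-month fitted hazards are averaged over the
#' month distribution of the whole table (both arms), weighted by person-days.
#'
#' `method = "ratio"` skips the logistic optimiser and returns the
#' occurrence/exposure ratio directly; it is only available without
#' adjustment, where the two are algebraically identical, and is useful
#' inside bootstrap loops.
#'
#' @param person_days a [person_day_table()] data frame.
#' @param arm `"treated"` or `"untreated"`.
#' @param cause `"death"` or `"discharge"`.
#' @param adjustment character vector of adjustment columns (only
#'   `"admission_month"` is meaningful for the daily table), or `NULL`.
#' @param method `"glm"` (default) or `"ratio"`.
#' @return list of class `ccw_pooled_fit` with `hazard` (marginal daily
#'   hazard), `coefficients`, `events` (weighted event count), `person_days`
#'   (weighted person-day total), `arm`, `cause`.
#' @export
fit_pooled_logistic <- function(person_days, arm, cause, adjustment = NULL,
                                method = c("glm", "ratio")) {
  method <- match.arg(method)
  arm <- match.arg(arm, c("treated", "untreated"))
  cause <- match.arg(cause, c("death", "discharge"))
  if (inherits(person_days, "ccw_clones")) {
    if (method == "ratio" && (is.null(adjustment) || length(adjustment) == 0L)) {
      return(.ratio_fit_from_clones(person_days, arm, cause))
    }
    person_days <- person_day_table(person_days)
  }
  if (!is.null(person_days$at_risk)) {
    person_days <- person_days[person_days$at_risk > 0, , drop = FALSE]
  }
  pd <- person_days[person_days$arm == arm, , drop = FALSE]
  if (nrow(pd) == 0L || sum(pd$weight) <= 0) {
    stop("no person-days for the ", arm, " arm")
  }
  y <- pd[[cause]]
  w <- pd$weight
  events <- sum(w * y)
  denom <- sum(w)

  if (is.null(adjustment) || length(adjustment) == 0L) {
    if (method == "glm") {
      # quasibinomial: identical point estimate, no non-integer-weight noise;
      # tight epsilon so the MLE matches the closed-form ratio to ~1e-10
      fit <- stats::glm(y ~ 1, family = stats::quasibinomial(), weights = w,
                        control = stats::glm.control(epsilon = 1e-12,
                                                     maxit = 100))
      hazard <- unname(stats::plogis(stats::coef(fit)[1L]))
      coefs <- stats::coef(fit)
    } else {
      hazard <- events / denom
      coefs <- c(`(Intercept)` = stats::qlogis(events / denom))
    }
  } else {
    if (method == "ratio") {
      stop("method = 'ratio' is only available without adjustment")
    }
    missing_adj <- setdiff(adjustment, names(pd))
    if (length(missing_adj) > 0L) {
      stop("adjustment columns not in person-day table: ",
           paste(missing_adj, collapse = ", "))
    }
    dat <- pd[, adjustment, drop = FALSE]
    dat[] <- lapply(dat, function(x) if (is.character(x)) factor(x) else x)
    dat$.y <- y
    dat$.w <- w
    fml <- stats::as.formula(paste(".y ~", paste(adjustment, collapse = " + ")))
    fit <- tryCatch(
      stats::glm(fml, family = stats::quasibinomial(), data = dat,
                 weights = .w,
                 control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
      error = function(e) stop("adjusted pooled logistic fit failed (",
                               conditionMessage(e),
                               "); consider dropping the adjustment")
    )
    if (anyNA(stats::coef(fit)) || !fit$converged) {
      stop("adjusted pooled logistic fit did not converge (possible ",
           "separation); consider dropping the adjustment")
    }
    # standardise over the person-day-weighted covariate distribution of the
    # FULL table (both arms), so arm hazards marginalise to the same population
    ref <- person_days[, adjustment, drop = FALSE]
    ref[] <- lapply(ref, function(x) if (is.character(x)) factor(x) else x)
    p_ref <- stats::predict(fit, newdata = ref, type = "response")
    hazard <- sum(person_days$weight * p_ref) / sum(person_days$weight)
    coefs <- stats::coef(fit)
  }
  structure(
    list(hazard = unname(hazard), coefficients = coefs, events = events,
         person_days = denom, arm = arm, cause = cause,
         adjustment = adjustment),
    class = "ccw_pooled_fit"
  )
}

# occurrence/exposure ratio computed straight from the clone table without
# expanding person-days: identical to the intercept-only weighted pooled
# logistic on the expanded table, and the hot path of the bootstrap
.ratio_fit_from_clones <- function(cloned, arm, cause) {
  g <- cloned$protocol$grace_period_days
  sel <- cloned$clones$arm == arm
  cl <- cloned$clones[sel, , drop = FALSE]
  if (nrow(cl) == 0L) stop("no person-days for the ", arm, " arm")
  if (is.null(cloned$grace_weights)) {
    denom <- sum(cl$weight * cl$end_day)
    w_event <- cl$weight
  } else {
    # at-risk flags already zero cells beyond each clone's end day
    W <- cloned$grace_weights[sel, , drop = FALSE] *
      cloned$grace_at_risk[sel, , drop = FALSE]
    denom <- sum(W) + sum(cl$weight * pmax(cl$end_day - g, 0))
    w_event <- ifelse(cl$end_day <= g,
                      cloned$grace_weights[sel, , drop = FALSE][
                        cbind(seq_len(nrow(cl)), pmin(cl$end_day, g))],
                      cl$weight)
  }
  if (denom <= 0) stop("no person-days for the ", arm, " arm")
  is_ev <- cl$end_reason == "event" & !is.na(cl$event_type) &
    cl$event_type == cause
  events <- sum(w_event[is_ev])
  structure(
    list(hazard = events / denom,
         coefficients = c(`(Intercept)` = stats::qlogis(events / denom)),
         events = events, person_days = denom, arm = arm, cause = cause,
         adjustment = NULL),
    class = "ccw_pooled_fit"
  )
}

#' Estimate the four constant cause-specific hazards
#'
#' Fits the weighted pooled logistic model for every arm-by-cause combination
#' and assembles the four daily rates of the three-state model: from
#' admission-as-untreated (0) or admission-as-treated (1) into in-hospital
#' death (2) or discharge alive (3).
#'
#' @inheritParams fit_pooled_logistic
#' @return object of class `ccw_hazards`: list with `lambda_02`, `lambda_03`,
#'   `lambda_12`, `lambda_13`, plus a `detail` data frame of weighted event
#'   counts and person-day denominators.
#' @export
hazard_estimates <- function(person_days, adjustment = NULL,
                             method = c("glm", "ratio")) {
  method <- match.arg(method)
  combos <- expand.grid(arm = c("untreated", "treated"),
                        cause = c("death", "discharge"),
                        stringsAsFactors = FALSE)
  fits <- Map(function(a, c.) {
    fit_pooled_logistic(person_days, a, c., adjustment = adjustment,
                        method = method)
  }, combos$arm, combos$cause)
  key <- paste(combos$arm, combos$cause, sep = ".")
  names(fits) <- key
  lam <- vapply(fits, `[[`, numeric(1), "hazard")
  detail <- data.frame(
    rate = paste0("lambda_", ifelse(combos$arm == "untreated", "0", "1"),
                  ifelse(combos$cause == "death", "2", "3")),
    arm = combos$arm, cause = combos$cause,
    events = vapply(fits, `[[`, numeric(1), "events"),
    person_days = vapply(fits, `[[`, numeric(1), "person_days"),
    hazard = unname(lam),
    stringsAsFactors = FALSE
  )
  structure(
    list(lambda_02 = unname(lam[["untreated.death"]]),
         lambda_03 = unname(lam[["untreated.discharge"]]),
         lambda_12 = unname(lam[["treated.death"]]),
         lambda_13 = unname(lam[["treated.discharge"]]),
         detail = detail, fits = fits),
    class = "ccw_hazards"
  )
}

#' @export
print.ccw_hazards <- function(x, digits = 4, ...) {
  cat("<ccw_hazards> constant daily cause-specific rates\n")
  cat(sprintf("  untreated: death %.*f, discharge %.*f\n",
              digits, x$lambda_02, digits, x$lambda_03))
  cat(sprintf("  treated:   death %.*f, discharge %.*f\n",
              digits, x$lambda_12, digits, x$lambda_13))
  invisible(x)
}

#' Closed-form cumulative incidence under constant hazards
#'
#' For constant cause-specific hazards the cumulative incidence of a cause by
#' time `t` is `(lambda_cause / lambda_total) * (1 - exp(-lambda_total * t))`:
#' the eventual cause fraction times the probability of having left the
#' initial state. Returns 0 when `lambda_total = 0`.
#'
#' @param lambda_cause cause-specific rate, `0 <= lambda_cause <= lambda_total`.
#' @param lambda_total all-cause exit rate.
#' @param t time (days) since admission; vectorised.
#' @return probability (vector) in `[0, 1]`.
#' @export
cif_constant <- function(lambda_cause, lambda_total, t) {
  if (any(lambda_cause < 0) || any(lambda_total < 0) ||
      any(lambda_cause > lambda_total + 1e-12)) {
    stop("need 0 <= lambda_cause <= lambda_total")
  }
  if (any(t < 0)) stop("t must be nonnegative")
  n <- max(length(lambda_cause), length(lambda_total), length(t))
  lc <- rep_len(lambda_cause, n)
  lt <- rep_len(lambda_total, n)
  tt <- rep_len(t, n)
  out <- numeric(n)
  nz <- lt > 0
  out[nz] <- (lc[nz] / lt[nz]) * (1 - exp(-lt[nz] * tt[nz]))
  out
}

#' Full effect-measure catalogue under the constant-hazards model
#'
#' Given the four constant rates, computes every treatment-effect summary of
#' the parametric analysis: end-of-follow-up mortality risks per arm (the
#' eventual cause fractions `MR = lambda_death / lambda_total`), their ratio
#' and difference; the complementary discharge risks (one minus mortality,
#' since the two absorbing states exhaust probability in the absence of right
#' censoring), their ratio and difference; cause-specific hazard ratios; the
#' four CIF curves on the integer day grid `0..tau` with the associated
#' risk-difference and risk-ratio curves; and expected lengths of stay
#' `1 / lambda_total` per arm.
#'
#' Ratios with a zero denominator are reported as `NA` rather than raising.
#'
#' @param h a `ccw_hazards` object (or list with the four `lambda_*` fields).
#' @param tau follow-up horizon in days (default 60).
#' @return object of class `ccw_effects`: scalar measures plus a `curves`
#'   data frame (`time`, `cif_death_untreated`, `cif_discharge_untreated`,
#'   `cif_death_treated`, `cif_discharge_treated`, `rd_death`, `rd_discharge`,
#'   `rr_death`, `rr_discharge`).
#' @export
effect_measures <- function(h, tau = 60) {
  stopifnot(tau >= 1)
  l02 <- h$lambda_02; l03 <- h$lambda_03
  l12 <- h$lambda_12; l13 <- h$lambda_13
  l0 <- l02 + l03; l1 <- l12 + l13
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)

  mr0 <- safe_div(l02, l0)
  mr1 <- safe_div(l12, l1)
  dr0 <- 1 - mr0
  dr1 <- 1 - mr1

  tt <- 0:tau
  cif02 <- cif_constant(l02, l0, tt)
  cif03 <- cif_constant(l03, l0, tt)
  cif12 <- cif_constant(l12, l1, tt)
  cif13 <- cif_constant(l13, l1, tt)
  curves <- data.frame(
    time = tt,
    cif_death_untreated = cif02,
    cif_discharge_untreated = cif03,
    cif_death_treated = cif12,
    cif_discharge_treated = cif13,
    rd_death = cif12 - cif02,
    rd_discharge = cif13 - cif03,
    rr_death = safe_div(cif12, cif02),
    rr_discharge = safe_div(cif13, cif03)
  )

  structure(
    list(
      tau = tau,
      mortality_risk_untreated = mr0,
      mortality_risk_treated = mr1,
      mortality_risk_ratio = safe_div(mr1, mr0),
      mortality_difference = mr1 - mr0,
      discharge_risk_untreated = dr0,
      discharge_risk_treated = dr1,
      discharge_risk_ratio = safe_div(dr1, dr0),
      discharge_difference = dr1 - dr0,
      hr_death = safe_div(l12, l02),
      hr_discharge = safe_div(l13, l03),
      rd_death_tau = cif_constant(l12, l1, tau) - cif_constant(l02, l0, tau),
      rd_discharge_tau = cif_constant(l13, l1, tau) - cif_constant(l03, l0, tau),
      los_untreated = safe_div(1, l0),
      los_treated = safe_div(1, l1),
      los_difference = safe_div(1, l1) - safe_div(1, l0),
      curves = curves
    ),
    class = "ccw_effects"
  )
}

#' @export
print.ccw_effects <- function(x, digits = 3, ...) {
  cat("<ccw_effects> constant-hazards treatment effect measures (tau = ",
      x$tau, " days)\n", sep = "")
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  cat("  mortality risk:  treated ", fmt(x$mortality_risk_treated),
      ", untreated ", fmt(x$mortality_risk_untreated),
      "  (difference ", fmt(x$mortality_difference),
      ", ratio ", fmt(x$mortality_risk_ratio), ")\n", sep = "")
  cat("  discharge risk:  treated ", fmt(x$discharge_risk_treated),
      ", untreated ", fmt(x$discharge_risk_untreated),
      "  (difference ", fmt(x$discharge_difference),
      ", ratio ", fmt(x$discharge_risk_ratio), ")\n", sep = "")
  cat("  hazard ratios:   death ", fmt(x$hr_death),
      ", discharge ", fmt(x$hr_discharge), "\n", sep = "")
  cat("  length of stay:  treated ", fmt(x$los_treated),
      " d, untreated ", fmt(x$los_untreated),
      " d  (difference ", fmt(x$los_difference), " d)\n", sep = "")
  invisible(x)
}

#' Tidy export of the effect-measure catalogue
#'
#' @param effects a `ccw_effects` object.
#' @return data frame with columns `measure`, `estimate` for the scalar
#'   summaries (curves are available in `effects$curves`).
#' @export
effects_table <- function(effects) {
  keep <- setdiff(names(effects), c("curves", "tau"))
  data.frame(measure = keep,
             estimate = vapply(effects[keep], as.numeric, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cause-specific hazard ratios with bootstrap confidence intervals
#'
#' Point estimates are the rate ratios `lambda_12 / lambda_02` (death) and
#' `lambda_13 / lambda_03` (discharge); under small daily hazards these equal
#' the odds ratios of the pooled logistic fits to close approximation.
#' Intervals, when requested, come from the patient-level bootstrap
#' ([bootstrap_ci()]), which re-runs cloning, censoring, weighting and
#' estimation in every replicate.
#'
#' @param h a `ccw_hazards` object for the point estimates.
#' @param cohort optional `ccw_cohort`; when supplied, percentile intervals
#'   are computed by bootstrap.
#' @param protocol,covariates,adjustment analysis settings forwarded to the
#'   bootstrap pipeline (used only with `cohort`).
#' @param B,seed,level bootstrap settings (see [bootstrap_ci()]).
#' @return data frame with columns `measure`, `estimate` and, with a cohort,
#'   `ci_low`, `ci_high`.
#' @export
hazard_ratio_ci <- function(h, cohort = NULL, protocol = protocol_config(),
                            covariates = c("age", "sex", "spo2", "resp_rate",
                                           "creatinine"),
                            adjustment = NULL, B = 500, seed = 1,
                            level = 0.95) {
  out <- data.frame(
    measure = c("hr_death", "hr_discharge"),
    estimate = c(ifelse(h$lambda_02 == 0, NA_real_, h$lambda_12 / h$lambda_02),
                 ifelse(h$lambda_03 == 0, NA_real_, h$lambda_13 / h$lambda_03)),
    stringsAsFactors = FALSE
  )
  if (!is.null(cohort)) {
    stat <- function(co) {
      hh <- ccw_analysis(co, protocol = protocol, covariates = covariates,
                         adjustment = adjustment, method = "ratio")$hazards
      c(hr_death = hh$lambda_12 / hh$lambda_02,
        hr_discharge = hh$lambda_13 / hh$lambda_03)
    }
    bt <- bootstrap_ci(cohort, stat, B = B, seed = seed, level = level)
    out$ci_low <- bt$ci_low[match(out$measure, bt$statistic)]
    out$ci_high <- bt$ci_high[match(out$measure, bt$statistic)]
  }
  out
}
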