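#' Protocol of the emulated trial
#'
#' The protocol fixes the grace period (the window after admission during
#' which starting treatment is still consistent with the "treat" strategy)
#' and the administrative follow-up horizon. "Within `g` days" is inclusive:
#' a patient treated on day `g` belongs to the treated strategy.
#'
#' @param grace_period_days positive integer `g`, default 2 days.
#' @param max_followup_days positive integer horizon `tau`, default 60 days;
#'   clones still in hospital at `tau` are administratively censored.
#' @return An object of class `ccw_protocol`.
#' @export
protocol_config <- function(grace_period_days = 2L, max_followup_days = 60L) {
  g <- as.integer(grace_period_days)
  tau <- as.integer(max_followup_days)
  if (is.na(g) || g < 1L) stop("grace_period_days must be a positive integer")
  if (is.na(tau) || tau <= g) stop("max_followup_days must exceed the grace period")
  structure(
    list(grace_period_days = g, max_followup_days = tau,
         arms = c("treated", "untreated")),
    class = "ccw_protocol"
  )
}

#' @export
print.ccw_protocol <- function(x, ...) {
  cat("<ccw_protocol> grace period ", x$grace_period_days,
      " days, follow-up ", x$max_followup_days, " days\n", sep = "")
  invisible(x)
}

#' Clone every patient into both treatment strategies
#'
#' Each admission is duplicated at time zero (hospital admission) and one
#' copy assigned to each strategy arm, independently of the treatment the
#' patient actually received. Both arms are therefore identical in baseline
#' characteristics. No artificial censoring is applied yet: every clone ends
#' at `min(event_day, tau)`, with reason `"event"` or `"admin_censor"`.
#'
#' @param cohort a `ccw_cohort`.
#' @param protocol a [protocol_config()].
#' @return An object of class `ccw_clones`: list with `clones` (data frame,
#'   one row per clone, carrying baseline covariates, `arm`, `end_day`,
#'   `end_reason`, `event_type`, `weight`), `source` and `protocol`.
#' @export
clone_cohort <- function(cohort, protocol = protocol_config()) {
  stopifnot(inherits(cohort, "ccw_cohort"), inherits(protocol, "ccw_protocol"))
  rec <- cohort$records
  if (nrow(rec) == 0L) stop("cannot clone an empty cohort")
  tau <- protocol$max_followup_days
  n <- nrow(rec)
  in_fu <- rec$event_day <= tau
  end_day <- pmin(rec$event_day, tau)
  end_reason <- rep("admin_censor", n)
  end_reason[in_fu] <- "event"
  ev_type <- rec$event_type
  ev_type[!in_fu] <- NA_character_
  dup <- function(x) c(x, x)
  clones <- c(
    lapply(rec[setdiff(names(rec), c("event_type"))], dup),
    list(arm = rep(protocol$arms, each = n),
         end_day = dup(end_day),
         end_reason = dup(end_reason),
         event_type = dup(ev_type),
         weight = rep(1, 2L * n))
  )
  clones <- structure(clones, class = "data.frame",
                      row.names = c(NA_integer_, -2L * n))
  structure(
    list(clones = clones, source = cohort, protocol = protocol,
         censored = FALSE, weighted = FALSE),
    class = "ccw_clones"
  )
}

#' Apply grace-period artificial censoring to a cloned cohort
#'
#' Clones are censored when the patient's observed data deviate from the
#' clone's assigned strategy during the grace period:
#' \itemize{
#'   \item treatment started within the grace period (`treatment_day <= g`):
#'     the untreated-arm clone is censored at the treatment day; the
#'     treated-arm clone keeps its outcome;
#'   \item no treatment by day `g` (never treated, or started after `g`): the
#'     treated-arm clone is censored at day `g`; the untreated-arm clone keeps
#'     its outcome -- late initiators count as untreated throughout;
#'   \item terminal event within the grace period before any treatment: both
#'     clones keep the event, so early deaths and discharges contribute
#'     person-time and events to both arms.
#' }
#' When treatment and the terminal event fall on the same day inside the grace
#' period the treatment is taken to precede the event (a recorded drug
#' administration implies the patient was still in hospital), so the
#' untreated-arm clone is censored at that day.
#'
#' @param cloned a `ccw_clones` object from [clone_cohort()], not yet censored.
#' @return The `ccw_clones` object with artificial censoring applied.
#' @export
apply_grace_censoring <- function(cloned) {
  stopifnot(inherits(cloned, "ccw_clones"))
  if (isTRUE(cloned$censored)) stop("grace-period censoring already applied")
  g <- cloned$protocol$grace_period_days
  cl <- cloned$clones

  treated_in_grace <- !is.na(cl$treatment_day) & cl$treatment_day <= g
  # event strictly before any possible treatment and inside the grace period
  event_in_grace_untreated <-
    cl$end_reason == "event" & cl$end_day <= g &
    (is.na(cl$treatment_day) | cl$end_day < cl$treatment_day |
       (cl$treatment_day > g & cl$end_day <= g))

  # untreated-arm clones of patients treated within grace: censor at treatment
  cen_untx <- cl$arm == "untreated" & treated_in_grace
  cl$end_day[cen_untx] <- cl$treatment_day[cen_untx]
  cl$end_reason[cen_untx] <- "artificial_censor"
  cl$event_type[cen_untx] <- NA_character_

  # treated-arm clones of patients not treated within grace: censor at day g,
  # unless the terminal event occurred in the grace period before treatment
  cen_tx <- cl$arm == "treated" & !treated_in_grace & !event_in_grace_untreated
  cl$end_day[cen_tx] <- g
  cl$end_reason[cen_tx] <- "artificial_censor"
  cl$event_type[cen_tx] <- NA_character_

  cloned$clones <- cl
  cloned$censored <- TRUE
  cloned
}

#' Per-arm counts of followed and artificially censored clones
#'
#' @param cloned a censored `ccw_clones`.
#' @return data frame with columns `arm`, `followed`, `artificially_censored`;
#'   rows sum to the cohort size per arm.
#' @export
arm_status_counts <- function(cloned) {
  stopifnot(inherits(cloned, "ccw_clones"))
  if (!isTRUE(cloned$censored)) stop("apply grace-period censoring first")
  cl <- cloned$clones
  out <- lapply(cloned$protocol$arms, function(a) {
    sub <- cl[cl$arm == a, ]
    cen <- sum(sub$end_reason == "artificial_censor")
    data.frame(arm = a, followed = nrow(sub) - cen,
               artificially_censored = cen, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expand clones into a person-day table
#'
#' A clone ending on day `d` contributes rows for days `1..d`. The death and
#' discharge indicators are zero everywhere except on the final row of a
#' clone ending in that event; censored clones (artificial or administrative)
#' contribute their days with zero event indicators, so they enter the
#' denominator of the constant-hazard estimates but never the numerator.
#'
#' After [attach_weights()], rows during the grace period carry the
#' scheme-specific day weights and rows after it the clone's final weight;
#' the `at_risk` flag is 0 on the treatment day of an artificially censored
#' untreated-arm clone under the ladder scheme (the patient was treated
#' before any event opportunity that day). Before weighting, all weights are
#' 1 and all rows are at risk.
#'
#' @param cloned a censored `ccw_clones` (weights optional; default 1).
#' @return data frame with columns `patient_id`, `arm`, `day`, `at_risk`,
#'   `death`, `discharge`, `weight`, plus the `admission_month` label used for
#'   outcome-model adjustment.
#' @export
person_day_table <- function(cloned) {
  stopifnot(inherits(cloned, "ccw_clones"))
  if (!isTRUE(cloned$censored)) stop("apply grace-period censoring first")
  cl <- cloned$clones
  g <- cloned$protocol$grace_period_days
  n_days <- cl$end_day
  idx <- rep.int(seq_len(nrow(cl)), n_days)
  day <- sequence(n_days)
  last <- cumsum(n_days)          # row index of each clone's final day
  is_last <- logical(length(idx))
  is_last[last] <- TRUE
  ev <- rep.int(ifelse(cl$end_reason == "event", cl$event_type, ""), n_days)
  weight <- cl$weight[idx]
  at_risk <- rep(1L, length(idx))
  if (!is.null(cloned$grace_weights)) {
    in_grace <- day <= g
    gidx <- cbind(idx[in_grace], day[in_grace])
    weight[in_grace] <- cloned$grace_weights[gidx]
    at_risk[in_grace] <- as.integer(cloned$grace_at_risk[gidx])
  }
  data.frame(
    patient_id = cl$patient_id[idx],
    arm = cl$arm[idx],
    day = day,
    at_risk = at_risk,
    death = as.integer(is_last & ev == "death"),
    discharge = as.integer(is_last & ev == "discharge"),
    weight = weight,
    admission_month = cl$admission_month[idx],
    stringsAsFactors = FALSE
  )
}

#' @export
print.ccw_clones <- function(x, ...) {
  cat("<ccw_clones> ", nrow(x$clones), " clones (",
      nrow(x$source$records), " patients x 2 arms)\n", sep = "")
  cat("  censored: ", x$censored, "; weighted: ", x$weighted, "\n", sep = "")
  if (isTRUE(x$censored)) print(arm_status_counts(x))
  invisible(x)
}
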