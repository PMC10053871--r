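#' Step functions for cumulative hazards and incidences
#'
#' Lightweight right-continuous step function: value `initial` before the
#' first jump, then `values[i]` from `jump_times[i]` onward.
#'
#' @param jump_times increasing numeric vector of jump locations.
#' @param values function values after each jump.
#' @param initial value before the first jump (default 0).
#' @return object of class `ccw_stepfun`.
#' @export
new_stepfun <- function(jump_times, values, initial = 0) {
  stopifnot(length(jump_times) == length(values),
            !is.unsorted(jump_times, strictly = TRUE))
  structure(list(jump_times = jump_times, values = values, initial = initial),
            class = "ccw_stepfun")
}

#' Evaluate a step function
#'
#' @param sf a `ccw_stepfun`.
#' @param t evaluation times (vector).
#' @return numeric vector `sf(t)`.
#' @export
eval_stepfun <- function(sf, t) {
  stopifnot(inherits(sf, "ccw_stepfun"))
  idx <- findInterval(t, sf$jump_times)
  c(sf$initial, sf$values)[idx + 1L]
}

#' @export
print.ccw_stepfun <- function(x, ...) {
  cat("<ccw_stepfun> ", length(x$jump_times), " jumps on [",
      if (length(x$jump_times)) min(x$jump_times) else NA, ", ",
      if (length(x$jump_times)) max(x$jump_times) else NA, "], final value ",
      if (length(x$values)) signif(x$values[length(x$values)], 4) else
        x$initial, "\n", sep = "")
  invisible(x)
}

#' Turn a step function into a (time, estimate) table
#'
#' @param sf a `ccw_stepfun`.
#' @return data frame with columns `time` and `estimate` (one row per jump,
#'   preceded by the initial value at time 0).
#' @export
stepfun_table <- function(sf) {
  data.frame(time = c(0, sf$jump_times),
             estimate = c(sf$initial, sf$values))
}

# extract the clone-level fields needed by the estimators from a ccw_clones
# object, a ccw_cohort, or a bare data frame
.as_clone_table <- function(clones) {
  if (inherits(clones, "ccw_clones")) {
    cl <- clones$clones
  } else if (inherits(clones, "ccw_cohort")) {
    cl <- cohort_as_clones(clones)
  } else {
    cl <- as.data.frame(clones)
  }
  need <- c("end_day", "end_reason", "event_type", "weight")
  if (!all(need %in% names(cl))) {
    stop("clone table needs columns: ", paste(need, collapse = ", "))
  }
  cl
}

#' View an uncloned cohort as a single-group clone table
#'
#' Convenience for running the non-parametric estimators on the original
#' (uncloned) data: every patient keeps their observed outcome with unit
#' weight.
#'
#' @param cohort a `ccw_cohort`.
#' @param tau optional administrative horizon; events after `tau` become
#'   administrative censorings. Default `Inf` (no truncation).
#' @return data frame with columns `patient_id`, `end_day`, `end_reason`,
#'   `event_type`, `weight`.
#' @export
cohort_as_clones <- function(cohort, tau = Inf) {
  rec <- cohort$records
  ended <- rec$event_day <= tau
  data.frame(
    patient_id = rec$patient_id,
    end_day = pmin(rec$event_day, tau),
    end_reason = ifelse(ended, "event", "admin_censor"),
    event_type = ifelse(ended, rec$event_type, NA_character_),
    weight = 1,
    stringsAsFactors = FALSE
  )
}

#' Weighted Nelson--Aalen cause-specific cumulative hazard
#'
#' At each event day `t` the cumulative hazard increments by the weighted
#' number of events of the cause at `t` over the weighted number at risk
#' (clones with `end_day >= t`). Causes tied on the same day share the same
#' risk set; the within-day order is unidentifiable at daily resolution and
#' irrelevant here. The estimator is invariant to rescaling all weights by a
#' constant.
#'
#' @param clones a weighted `ccw_clones`, a `ccw_cohort`, or a data frame with
#'   columns `end_day`, `end_reason`, `event_type`, `weight`.
#' @param cause `"death"` or `"discharge"`.
#' @return a `ccw_stepfun` cumulative hazard.
#' @export
weighted_nelson_aalen <- function(clones, cause = c("death", "discharge")) {
  cause <- match.arg(cause)
  cl <- .as_clone_table(clones)
  inc <- .hazard_increments(cl)
  new_stepfun(inc$time, cumsum(inc[[paste0("dl_", cause)]]))
}

# per-day hazard increments shared by Nelson-Aalen and Aalen-Johansen:
# for every distinct end day, weighted events by cause and weighted risk set
.hazard_increments <- function(cl) {
  o <- order(cl$end_day)
  d <- cl$end_day[o]
  w <- cl$weight[o]
  is_event <- cl$end_reason[o] == "event"
  type <- cl$event_type[o]
  days <- unique(d)
  grp <- factor(match(d, days), levels = seq_along(days))
  sum_by <- function(x) as.numeric(rowsum(x, grp))
  w_death <- sum_by(w * (is_event & !is.na(type) & type == "death"))
  w_disch <- sum_by(w * (is_event & !is.na(type) & type == "discharge"))
  # risk set: everyone still in hospital at the start of each day
  at_risk <- rev(cumsum(rev(sum_by(w))))
  if (any(at_risk <= 0)) stop("empty risk set at an event time")
  data.frame(time = days, dl_death = w_death / at_risk,
             dl_discharge = w_disch / at_risk, at_risk = at_risk)
}

#' Weighted Aalen--Johansen cumulative incidence functions
#'
#' Generalises Kaplan--Meier to competing risks: the cumulative incidence of a
#' cause is the sum over event days of the probability of still being in
#' hospital just before the day times that day's cause-specific hazard
#' increment, `CIF_cause(t) = sum_{s<=t} S(s-) dLambda_cause(s)`, with `S`
#' the all-cause product-limit survival. With no external censoring mass,
#' `CIF_death + CIF_discharge + S = 1` at every time.
#'
#' @inheritParams weighted_nelson_aalen
#' @return list with `ccw_stepfun` elements `cif_death`, `cif_discharge` and
#'   `surv` (all-cause product-limit survival).
#' @export
weighted_aalen_johansen <- function(clones) {
  cl <- .as_clone_table(clones)
  inc <- .hazard_increments(cl)
  dl_all <- inc$dl_death + inc$dl_discharge
  surv <- cumprod(1 - dl_all)
  s_minus <- c(1, surv[-length(surv)])
  list(
    cif_death = new_stepfun(inc$time, cumsum(s_minus * inc$dl_death)),
    cif_discharge = new_stepfun(inc$time, cumsum(s_minus * inc$dl_discharge)),
    surv = new_stepfun(inc$time, surv, initial = 1)
  )
}

#' Naive Kaplan--Meier estimate of the in-hospital death probability
#'
#' The comparator analysis that ignores competing risks: on the original,
#' uncloned cohort, discharges alive are treated as plain right-censoring and
#' one minus the Kaplan--Meier survival is reported per treatment group. In
#' the presence of discharges this overestimates the cumulative probability
#' of in-hospital death relative to the Aalen--Johansen cumulative incidence
#' (and, with `grouping = "ever_treated"`, additionally exhibits immortal
#' time bias).
#'
#' @param cohort a `ccw_cohort` (original data, no cloning).
#' @param grouping how patients are split into "treated" and "untreated":
#'   `"treated_within_grace"` (default; matches the emulation's
#'   classification) or `"ever_treated"`.
#' @param grace_period_days grace period used by `"treated_within_grace"`.
#' @return named list of `ccw_stepfun` cumulative death probabilities, one
#'   per group (`treated`, `untreated`); groups absent from the data are
#'   dropped with an error if both are empty.
#' @export
naive_km_death <- function(cohort,
                           grouping = c("treated_within_grace", "ever_treated"),
                           grace_period_days = 2L) {
  grouping <- match.arg(grouping)
  rec <- cohort$records
  grp <- if (grouping == "treated_within_grace") {
    !is.na(rec$treatment_day) & rec$treatment_day <= grace_period_days
  } else {
    !is.na(rec$treatment_day)
  }
  out <- list()
  for (label in c("treated", "untreated")) {
    sel <- if (label == "treated") grp else !grp
    if (!any(sel)) next
    sub <- rec[sel, ]
    fit <- survival::survfit(
      survival::Surv(sub$event_day, sub$event_type == "death") ~ 1
    )
    jumps <- fit$time[fit$n.event > 0]
    vals <- 1 - fit$surv[fit$n.event > 0]
    out[[label]] <- new_stepfun(jumps, vals)
  }
  if (length(out) == 0L) stop("both treatment groups are empty")
  out
}
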