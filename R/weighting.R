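#' Fit the artificial-censoring model for one arm
#'
#' Within an arm, being artificially censored during the grace period is
#' itself a time-to-event process: follow-up runs from admission to the end
#' of the grace period, the "event" is artificial censoring, and clones that
#' exit earlier through death or discharge, or reach the end of the grace
#' period, are censoring-free. The model captures how baseline admission
#' characteristics (in linear form) drove physicians' treatment decisions and
#' hence the censoring mechanism, and stores everything needed to evaluate
#' each patient's probability of remaining uncensored through day `g`.
#'
#' Two engines are available:
#' \describe{
#'   \item{`"discrete"` (default)}{a discrete-time hazard model: pooled
#'     logistic regression of the daily censoring indicator on a per-day
#'     intercept plus the covariates, over the daily censoring risk sets.
#'     This is the natural model when censoring decisions are made once per
#'     day and daily censoring probabilities are large -- in this design
#'     roughly half of all patients start treatment on the first day, so the
#'     untreated arm loses about half its risk set in one step. For rare
#'     daily censoring it coincides with the Cox model.}
#'   \item{`"cox"`}{Cox proportional hazards by Breslow partial likelihood
#'     with the matching Breslow baseline cumulative hazard. With daily ties
#'     this heavy the partial likelihood noticeably attenuates the
#'     coefficients (kept for comparison and for data with light ties).}
#' }
#'
#' Within-day ordering differs by arm and is encoded in the risk sets. In the
#' untreated arm censoring is a treatment administration, which precedes any
#' same-day terminal event, so clones exiting by death or discharge on day
#' `d` remain in the censoring risk set at `d`. In the treated arm censoring
#' happens at the end of the grace period, after any same-day event, so
#' grace-period events leave the risk set just before the censoring time.
#'
#' Covariates are centred at their arm means before fitting, which keeps the
#' linear predictor numerically tame; the stored baseline hazard refers to
#' the centred scale.
#'
#' @param cloned a censored `ccw_clones`.
#' @param arm `"treated"` or `"untreated"`.
#' @param covariates character vector of covariate columns; defaults to the
#'   five baseline covariates (age, sex, spo2, resp_rate, creatinine). May be
#'   empty, giving the nonparametric per-day censoring hazards.
#' @param engine `"discrete"` or `"cox"`, see Details.
#' @return An object of class `ccw_censoring_model` with elements `arm`,
#'   `engine`, `coefficients` (per-covariate), `day_intercepts` (logit scale,
#'   discrete engine), `centers`, `baseline_cumhaz` (data frame `day`,
#'   `increment`, `hazard`: per-day censoring hazard at the centred
#'   covariates and its running sum), `covariate_list`, `degenerate`, `fit`.
#' @export
fit_censoring_model <- function(cloned, arm,
                                covariates = c("age", "sex", "spo2",
                                               "resp_rate", "creatinine"),
                                engine = c("discrete", "cox")) {
  if (!inherits(cloned, "ccw_clones")) stop("cloned must be a ccw_clones")
  if (!isTRUE(cloned$censored)) stop("apply grace-period censoring first")
  arm <- match.arg(arm, cloned$protocol$arms)
  engine <- match.arg(engine)
  g <- cloned$protocol$grace_period_days
  in_arm <- cloned$clones$arm == arm
  cl <- cloned$clones[in_arm, c("end_day", "end_reason", covariates)]

  status <- as.integer(cl$end_reason == "artificial_censor")
  time <- pmin(cl$end_day, g)
  if (arm == "treated") {
    # grace-period events precede the end-of-grace censoring: shift them just
    # before the integer day so they drop out of that day's censoring risk set
    ev_in_grace <- cl$end_reason == "event" & cl$end_day <= g
    time[ev_in_grace] <- time[ev_in_grace] - 0.5
  }

  base <- structure(
    list(arm = arm, engine = engine, covariate_list = covariates,
         grace_period_days = g),
    class = "ccw_censoring_model"
  )
  if (sum(status) == 0L) {
    warning("no artificial censorings in the ", arm,
            " arm; weights will all be 1")
    base$degenerate <- TRUE
    base$coefficients <- stats::setNames(rep(0, length(covariates)), covariates)
    base$day_intercepts <- rep(-Inf, g)
    base$centers <- stats::setNames(rep(0, length(covariates)), covariates)
    base$baseline_cumhaz <- data.frame(day = seq_len(g), increment = 0,
                                       hazard = 0)
    base$fit <- NULL
    return(base)
  }

  if (length(covariates) > 0L) {
    X <- as.matrix(cl[, covariates, drop = FALSE])
    centers <- colMeans(X)
    Xc <- sweep(X, 2L, centers)
  } else {
    Xc <- matrix(numeric(0), nrow(cl), 0)
    centers <- stats::setNames(numeric(0), character(0))
  }

  if (engine == "discrete") {
    base <- .fit_censoring_discrete(base, time, status, Xc, covariates,
                                    centers, g, arm)
  } else {
    base <- .fit_censoring_cox(base, time, status, Xc, covariates, centers, g,
                               arm)
  }
  base
}

# weighted-least-squares Newton iterations for a logistic fit; returns the
# coefficient vector (NA entries for non-estimable columns)
.logit_irls <- function(X, y, max_iter = 25L, tol = 1e-9) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1L] <- stats::qlogis(max(min(mean(y), 1 - 1e-8), 1e-8))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w[w < 1e-12] <- 1e-12
    z <- eta + (y - mu) / w
    fit <- tryCatch(
      solve(crossprod(X, X * w), crossprod(X, w * z)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      # singular information: fall back to the reference implementation,
      # which pivots non-estimable columns out
      co <- suppressWarnings(
        stats::glm.fit(X, y, family = stats::binomial())$coefficients
      )
      return(co)
    }
    beta_new <- drop(fit)
    done <- max(abs(beta_new - beta)) < tol
    beta <- beta_new
    if (done) break
  }
  beta
}

# pooled per-day logistic censoring model over the daily risk sets
.fit_censoring_discrete <- function(base, time, status, Xc, covariates,
                                    centers, g, arm) {
  k <- length(covariates)
  n_s <- vapply(seq_len(g), function(s) sum(time >= s), integer(1))
  X <- matrix(0, sum(n_s), g + k)
  y <- integer(sum(n_s))
  offset <- 0L
  for (s in seq_len(g)) {
    if (n_s[s] == 0L) next
    at_risk <- which(time >= s)
    rows <- offset + seq_len(n_s[s])
    X[rows, s] <- 1
    if (k > 0L) X[rows, g + seq_len(k)] <- Xc[at_risk, , drop = FALSE]
    y[rows] <- as.integer(status[at_risk] == 1L & time[at_risk] == s)
    offset <- offset + n_s[s]
  }
  estimable <- n_s > 0L
  keep <- c(estimable, rep(TRUE, k))
  coefs <- rep(NA_real_, g + k)
  coefs[keep] <- .logit_irls(X[, keep, drop = FALSE], y)
  alpha <- coefs[seq_len(g)]
  # a day with no one at risk gets a degenerate intercept
  alpha[is.na(alpha)] <- -Inf
  beta <- coefs[g + seq_len(k)]
  beta[is.na(beta)] <- 0
  names(beta) <- covariates
  fit <- list(coefficients = coefs, n_rows = sum(n_s))
  inc <- stats::plogis(alpha)
  base$degenerate <- FALSE
  base$coefficients <- beta
  base$day_intercepts <- unname(alpha)
  base$centers <- centers
  base$baseline_cumhaz <- data.frame(day = seq_len(g), increment = unname(inc),
                                     hazard = cumsum(unname(inc)))
  base$fit <- fit
  base
}

# Breslow partial likelihood via the fitting engine directly (identical to
# the coxph formula interface with ties = "breslow", without its model-frame
# overhead), plus the matching Breslow baseline hazard increments
.fit_censoring_cox <- function(base, time, status, Xc, covariates, centers,
                               g, arm) {
  if (length(covariates) > 0L) {
    y <- cbind(time = time, status = status)
    attr(y, "type") <- "right"
    class(y) <- "Surv"
    fit <- tryCatch(
      survival::coxph.fit(Xc, y, strata = NULL, offset = NULL, init = NULL,
                          control = survival::coxph.control(),
                          weights = NULL, method = "breslow",
                          rownames = NULL),
      error = function(e) stop("censoring model failed to fit in the ", arm,
                               " arm: ", conditionMessage(e))
    )
    beta <- fit$coefficients
    if (anyNA(beta)) {
      stop("censoring model did not converge in the ", arm,
           " arm (singular or separated covariates)")
    }
    names(beta) <- covariates
  } else {
    fit <- NULL
    beta <- stats::setNames(numeric(0), character(0))
  }
  r <- if (length(covariates) > 0L) exp(drop(Xc %*% beta)) else
    rep(1, length(time))
  d_s <- vapply(seq_len(g), function(s) sum(status[time == s]), numeric(1))
  denom_s <- vapply(seq_len(g), function(s) sum(r[time >= s]), numeric(1))
  inc <- ifelse(d_s > 0, d_s / denom_s, 0)
  base$degenerate <- FALSE
  base$coefficients <- beta
  base$day_intercepts <- NULL
  base$centers <- centers
  base$baseline_cumhaz <- data.frame(day = seq_len(g), increment = inc,
                                     hazard = cumsum(inc))
  base$fit <- fit
  base
}

# per-day conditional probability of being censored on day s given uncensored
# before, for each row of rec: matrix n x g
.daily_censor_prob <- function(model, rec) {
  g <- model$grace_period_days
  covs <- model$covariate_list
  n <- nrow(rec)
  if (isTRUE(model$degenerate)) return(matrix(0, n, g))
  lp <- if (length(covs) > 0L) {
    X <- as.matrix(rec[, covs, drop = FALSE])
    if (anyNA(X)) stop("covariates must be complete to evaluate probabilities")
    drop(sweep(X, 2L, model$centers) %*% model$coefficients)
  } else rep(0, n)
  if (model$engine == "discrete") {
    outer_lp <- outer(lp, model$day_intercepts, `+`)
    stats::plogis(outer_lp)
  } else {
    # grouped-PH form: 1 - (1 - dLambda0(s))^exp(lp); always a probability
    risk <- exp(lp)
    inc <- model$baseline_cumhaz$increment
    1 - outer(risk, pmax(1 - inc, 0), function(rr, s0) s0^rr)
  }
}

#' Probability of remaining uncensored through the grace period
#'
#' Evaluates the censoring-survival function of a fitted artificial-censoring
#' model at day `g` for each supplied patient: the product over days
#' `1..g` of one minus the patient's conditional daily censoring probability.
#' With no covariates this reduces exactly to the nonparametric product-limit
#' survival of remaining uncensored. For the `"cox"` engine the daily
#' probabilities come from the grouped proportional-hazards form
#' `1 - (1 - dLambda0(s))^exp(x'beta)`; `form = "exponential"` instead
#' returns the continuous relative-risk form `exp(-Lambda0(g) exp(x'beta))`,
#' adequate for small daily hazards. Probabilities are floored at `1e-10` to
#' avoid weights blowing up on pathological inputs.
#'
#' @param model a `ccw_censoring_model`.
#' @param records data frame (or `ccw_cohort`) with the model's covariate
#'   columns; one probability per row.
#' @param g day through which to evaluate; defaults to the model's grace
#'   period.
#' @param form survival representation: `"product-limit"` (default) or
#'   `"exponential"` (cox engine only).
#' @param floor lower truncation for the probability (default `1e-10`).
#' @return numeric vector of probabilities in `(0, 1]`.
#' @export
prob_uncensored <- function(model, records, g = model$grace_period_days,
                            form = c("product-limit", "exponential"),
                            floor = 1e-10) {
  stopifnot(inherits(model, "ccw_censoring_model"))
  form <- match.arg(form)
  rec <- if (inherits(records, "ccw_cohort")) records$records else
    as.data.frame(records)
  if (isTRUE(model$degenerate)) return(rep(1, nrow(rec)))
  if (g > model$grace_period_days) {
    stop("baseline hazard not available at day ", g)
  }
  if (form == "exponential") {
    if (model$engine != "cox") {
      stop("the exponential form applies to the cox engine only")
    }
    covs <- model$covariate_list
    lp <- if (length(covs) > 0L) {
      X <- as.matrix(rec[, covs, drop = FALSE])
      drop(sweep(X, 2L, model$centers) %*% model$coefficients)
    } else rep(0, nrow(rec))
    lam0 <- model$baseline_cumhaz$hazard[match(g, model$baseline_cumhaz$day)]
    return(pmax(exp(-lam0 * exp(lp)), floor))
  }
  h <- .daily_censor_prob(model, rec)
  p <- rep(1, nrow(h))
  for (s in seq_len(g)) p <- p * (1 - h[, s])
  pmax(p, floor)
}

# per-clone, per-grace-day inverse-probability weights and at-risk flags.
# Returns list(W, at_risk): matrices n_clones x g. Under the "ladder" scheme
# the day-t weight is the reciprocal of the probability of being uncensored
# through the censoring opportunities preceding day t's events: through day t
# in the untreated arm (treatment precedes same-day events) and through day
# t-1 in the treated arm (end-of-grace censoring follows same-day events).
# Rows where a clone bears no event risk (its own treatment day in the
# untreated arm, days past end_day anywhere) are flagged 0.
.grace_day_weights <- function(cloned, models, scheme, floor = 1e-10) {
  g <- cloned$protocol$grace_period_days
  cl <- cloned$clones
  n <- nrow(cl)
  W <- matrix(1, n, g)
  at_risk <- matrix(FALSE, n, g)
  for (t in seq_len(g)) at_risk[, t] <- cl$end_day >= t

  if (scheme == "fixed") {
    # final clone weight on every row; censored clones keep weight 1 and all
    # their days at risk (they contribute their days in the original state)
    W[] <- cl$weight
    return(list(W = W, at_risk = at_risk))
  }
  # in the untreated arm a clone censored at day c is treated during day c,
  # so its final day carries no event risk time
  cen_untx <- cl$arm == "untreated" & cl$end_reason == "artificial_censor"
  at_risk[cbind(which(cen_untx), cl$end_day[cen_untx])] <- FALSE

  for (a in cloned$protocol$arms) {
    sel <- cl$arm == a
    m <- models[[a]]
    if (isTRUE(m$degenerate)) next
    h <- .daily_censor_prob(m, cl[sel, , drop = FALSE])
    p <- rep(1, sum(sel))
    for (t in seq_len(g)) {
      if (a == "untreated") p <- p * (1 - h[, t])
      # treated arm: censoring opportunities before day t are days 1..t-1
      W[sel, t] <- 1 / pmax(p, floor)
      if (a == "treated") p <- p * (1 - h[, t])
    }
  }
  list(W = W, at_risk = at_risk)
}

#' Attach inverse-probability-of-censoring weights to clones
#'
#' Clones that survive the grace period uncensored are a selected sample --
#' the censoring depended on covariates that also predict the outcome. Each
#' such clone is up-weighted by the reciprocal of its own arm's probability
#' of remaining uncensored through day `g`, so that from the end of the grace
#' period onward the weighted survivors represent the clones censored away;
#' clones ending within the grace period keep clone-level weight 1.
#'
#' Two schemes govern the person-day weights during the grace period itself:
#' \describe{
#'   \item{`"ladder"` (default)}{day `t` rows carry the reciprocal of the
#'     probability of remaining uncensored through the censoring
#'     opportunities preceding day `t`'s events, rising day by day to the
#'     final weight. This keeps the weighted risk set equal to the
#'     censoring-free cohort on every single day, so the constant-hazard
#'     estimates stay unbiased even with the strong day-1 initiation rates
#'     seen in hospital data.}
#'   \item{`"fixed"`}{every row of an uncensored clone carries the final
#'     weight and rows of censored clones carry 1 (probabilities evaluated at
#'     day `g` only). Simpler, but over-represents grace-period person-time
#'     when censoring is heavy.}
#' }
#'
#' Weights are unstabilised and not truncated by default; `cap` trims them at
#' an upper quantile when requested.
#'
#' @param cloned a censored `ccw_clones`.
#' @param models named list with entries `treated` and `untreated`, each a
#'   `ccw_censoring_model`; defaults to fitting both with the standard
#'   covariate set and the discrete engine.
#' @param scheme grace-period person-day weighting scheme, see Details.
#' @param cap optional quantile in (0, 1); weights above that quantile of the
#'   clone weight distribution are truncated to it (with a message). Default
#'   `NULL` (no truncation).
#' @return The `ccw_clones` object with its `weight` column filled in,
#'   grace-period day weights stored for [person_day_table()], and
#'   `weighted = TRUE`.
#' @export
attach_weights <- function(cloned, models = NULL,
                           scheme = c("ladder", "fixed"), cap = NULL) {
  stopifnot(inherits(cloned, "ccw_clones"))
  scheme <- match.arg(scheme)
  if (!isTRUE(cloned$censored)) stop("apply grace-period censoring first")
  if (is.null(models)) {
    models <- list(
      treated = fit_censoring_model(cloned, "treated"),
      untreated = fit_censoring_model(cloned, "untreated")
    )
  }
  if (!all(cloned$protocol$arms %in% names(models))) {
    stop("models must be a named list with entries 'treated' and 'untreated'")
  }
  g <- cloned$protocol$grace_period_days
  cl <- cloned$clones
  cl$weight <- 1
  for (a in cloned$protocol$arms) {
    sel <- cl$arm == a & cl$end_day > g    # survived the grace period in arm
    if (any(sel)) {
      p <- prob_uncensored(models[[a]], cl[sel, , drop = FALSE], g = g)
      cl$weight[sel] <- 1 / p
    }
  }
  if (!is.null(cap)) {
    q <- stats::quantile(cl$weight, cap)
    n_cap <- sum(cl$weight > q)
    if (n_cap > 0L) {
      message("truncating ", n_cap, " weights at the ",
              format(cap), " quantile (", signif(q, 4), ")")
      cl$weight <- pmin(cl$weight, q)
    }
  }
  cloned$clones <- cl
  gw <- .grace_day_weights(cloned, models, scheme)
  cloned$grace_weights <- gw$W
  cloned$grace_at_risk <- gw$at_risk
  cloned$scheme <- scheme
  cloned$weighted <- TRUE
  cloned$censoring_models <- models
  cloned
}
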