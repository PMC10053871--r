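#' Patient-level bootstrap percentile confidence intervals
#'
#' Resamples original patients (never clones: the two clones of a patient are
#' not independent) with replacement, re-runs the supplied analysis on each
#' resampled cohort -- including re-cloning, re-censoring and refitting the
#' censoring models, so the weighting step's variability enters the
#' intervals -- and returns percentile intervals for every statistic the
#' analysis reports. Replicate seeds are derived deterministically from the
#' master seed, so a fixed seed gives identical intervals on identical input.
#' Replicates whose analysis fails are dropped and counted; more than 10%
#' failures aborts with diagnostics.
#'
#' @param cohort a `ccw_cohort`; the resampling unit is the patient.
#' @param statistic function taking a `ccw_cohort` and returning a named
#'   numeric vector of statistics (the full pipeline or any part of it).
#' @param B number of bootstrap replicates (default 500).
#' @param seed master integer seed.
#' @param level confidence level (default 0.95, i.e. 2.5th/97.5th
#'   percentiles).
#' @return object of class `ccw_boot`: data frame with one row per statistic
#'   (`statistic`, `estimate`, `ci_low`, `ci_high`), plus attributes
#'   `replicates` (B x k matrix), `B`, `failed`, `seed`, `level`.
#' @export
bootstrap_ci <- function(cohort, statistic, B = 500, seed = 1, level = 0.95) {
  stopifnot(inherits(cohort, "ccw_cohort"), is.function(statistic))
  if (B < 2) stop("B must be at least 2")
  est <- statistic(cohort)
  if (is.null(names(est)) || anyNA(names(est)) || any(names(est) == "")) {
    stop("statistic() must return a named numeric vector")
  }
  n <- nrow(cohort$records)
  rec <- cohort$records

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  reps <- matrix(NA_real_, nrow = B, ncol = length(est),
                 dimnames = list(NULL, names(est)))
  failures <- character()
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    boot_rec <- rec[idx, , drop = FALSE]
    boot_rec$patient_id <- as.character(seq_len(n))  # resampled ids collide
    boot_cohort <- structure(
      list(records = boot_rec, exclusion_log = integer()),
      class = "ccw_cohort"
    )
    val <- tryCatch(
      suppressWarnings(statistic(boot_cohort)),
      error = function(e) conditionMessage(e)
    )
    if (is.character(val)) {
      failures <- c(failures, val)
    } else {
      reps[b, ] <- val[names(est)]
    }
  }
  if (length(failures) > B * 0.10) {
    stop("more than 10% of bootstrap replicates failed (",
         length(failures), "/", B, "); first error: ", failures[1L])
  }
  ok <- reps[stats::complete.cases(reps), , drop = FALSE]
  alpha <- (1 - level) / 2
  ci <- apply(ok, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)
  out <- data.frame(
    statistic = names(est),
    estimate = unname(est),
    ci_low = ci[1L, ],
    ci_high = ci[2L, ],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("ccw_boot", "data.frame"),
            replicates = reps, B = B, failed = length(failures),
            seed = seed, level = level)
}
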