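#' @keywords internal
"_PACKAGE"

# canonical covariates used throughout the package
.ccw_covariates <- c("age", "sex", "spo2", "resp_rate", "creatinine")
.ccw_columns <- c("patient_id", .ccw_covariates, "admission_month",
                  "treatment_day", "event_day", "event_type")
.ccw_event_types <- c("death", "discharge")

#' Construct a hospital cohort from a patient-level data frame
#'
#' A cohort holds one row per hospital admission with baseline covariates
#' measured at admission, the day treatment was first given (if ever), and the
#' terminal event. Days are positive integers counted from admission: an event
#' or treatment on the admission calendar day is day 1, so "treated within two
#' days" means `treatment_day` in `{1, 2}`. Every retained patient must reach
#' exactly one of the two absorbing states, in-hospital death or discharge
#' alive.
#'
#' Rows with any missing covariate, missing `event_day` or missing
#' `event_type` are dropped (complete-case rule; no imputation) and counted in
#' the exclusion log.
#'
#' @param records data frame with columns `patient_id`, `age`, `sex` (0/1),
#'   `spo2` (percent, in \[0,100\]), `resp_rate`, `creatinine`,
#'   `admission_month` (category label), `treatment_day` (positive integer or
#'   `NA` if never treated), `event_day` (positive integer), `event_type`
#'   (`"death"` or `"discharge"`).
#' @param exclusion_log named integer vector of rows dropped per reason
#'   (filled in by [read_cohort()]).
#' @return An object of class `ccw_cohort`: a list with elements `records`
#'   (the validated data frame) and `exclusion_log`.
#' @seealso [read_cohort()], [validate_cohort()], [baseline_table()]
#' @export
new_cohort <- function(records, exclusion_log = integer()) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(.ccw_columns, names(records))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, .ccw_columns]
  records$patient_id <- as.character(records$patient_id)
  records$sex <- as.numeric(records$sex)
  records$admission_month <- as.character(records$admission_month)
  records$treatment_day <- suppressWarnings(as.integer(records$treatment_day))
  records$event_day <- as.integer(records$event_day)
  records$event_type <- as.character(records$event_type)
  rownames(records) <- NULL
  out <- structure(
    list(records = records, exclusion_log = exclusion_log),
    class = "ccw_cohort"
  )
  report <- validate_cohort(out)
  if (nrow(report) > 0L) {
    stop("invalid cohort: ", report$rule[1L], " (patient ",
         report$patient_id[1L], ")",
         if (nrow(report) > 1L) paste0(" and ", nrow(report) - 1L, " more"))
  }
  out
}

#' Read a cohort table from delimited text
#'
#' Reads a comma-separated file with a header row, renames columns through
#' `schema`, applies the complete-case exclusion rule, and validates the
#' result. The exclusion log records how many rows were dropped and why, so
#' that `nrow(input) == nrow(cohort) + sum(exclusion_log)` always holds.
#'
#' @param path path to a CSV file.
#' @param schema named character vector mapping canonical column names
#'   (`patient_id`, `age`, `sex`, `spo2`, `resp_rate`, `creatinine`,
#'   `admission_month`, `treatment_day`, `event_day`, `event_type`) to the
#'   column names used in the file. Defaults to the identity mapping.
#' @return A [new_cohort()] object with a populated `exclusion_log`.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("could not parse cohort file '", path, "': ",
                             conditionMessage(e))
  )
  if (is.null(schema)) {
    schema <- stats::setNames(.ccw_columns, .ccw_columns)
  }
  schema <- schema[.ccw_columns]
  if (anyNA(schema)) {
    stop("schema must map every canonical column; missing: ",
         paste(.ccw_columns[is.na(schema)], collapse = ", "))
  }
  absent <- setdiff(unname(schema), names(raw))
  if (length(absent) > 0L) {
    stop("mapped columns not present in file: ", paste(absent, collapse = ", "))
  }
  df <- raw[, unname(schema)]
  names(df) <- .ccw_columns

  # treatment_day may be blank (never treated); every other field is required
  miss_cov <- rowSums(is.na(df[, .ccw_covariates])) > 0 |
    is.na(df$admission_month) | df$admission_month == "" |
    is.na(df$patient_id) | df$patient_id == ""
  miss_event <- is.na(df$event_day) |
    is.na(df$event_type) | df$event_type == ""
  log <- c(
    missing_covariate = sum(miss_cov & !miss_event),
    missing_event = sum(miss_event)
  )
  log <- log[log > 0L]
  keep <- df[!(miss_cov | miss_event), , drop = FALSE]

  if (anyDuplicated(keep$patient_id)) {
    dup <- unique(keep$patient_id[duplicated(keep$patient_id)])
    stop("duplicate patient_id: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  bad_order <- which(!is.na(keep$treatment_day) &
                       keep$treatment_day > keep$event_day)
  if (length(bad_order) > 0L) {
    stop("event_day < treatment_day for patient_id ",
         keep$patient_id[bad_order[1L]])
  }
  new_cohort(keep, exclusion_log = log)
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()] with the identity schema: a written cohort reads
#' back record for record.
#'
#' @param cohort a `ccw_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ccw_cohort"))
  utils::write.csv(cohort$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Check a cohort against its structural invariants
#'
#' Violations are data, not exceptions: each row of the report names the
#' offending patient and the rule broken. An empty report means the cohort is
#' valid.
#'
#' @param cohort a `ccw_cohort` (or a bare list with a `records` data frame).
#' @return data frame with columns `patient_id` and `rule`; zero rows when all
#'   invariants hold.
#' @export
validate_cohort <- function(cohort) {
  rec <- cohort$records
  bad <- list()
  flag <- function(ids, rule) {
    if (length(ids) > 0L) {
      bad[[length(bad) + 1L]] <<- data.frame(
        patient_id = as.character(ids), rule = rule,
        stringsAsFactors = FALSE
      )
    }
  }
  dup <- unique(rec$patient_id[duplicated(rec$patient_id)])
  flag(dup, "patient_id not unique")
  flag(rec$patient_id[is.na(rec$event_day) | rec$event_day < 1L],
       "event_day must be a positive integer")
  flag(rec$patient_id[!rec$event_type %in% .ccw_event_types &
                        !is.na(rec$event_type)],
       "event_type must be 'death' or 'discharge'")
  flag(rec$patient_id[is.na(rec$event_type)], "event_type missing")
  flag(rec$patient_id[!is.na(rec$treatment_day) &
                        (rec$treatment_day < 1L |
                           rec$treatment_day > rec$event_day)],
       "treatment_day must satisfy 1 <= treatment_day <= event_day")
  flag(rec$patient_id[rowSums(is.na(rec[, .ccw_covariates])) > 0],
       "incomplete baseline covariates")
  flag(rec$patient_id[!is.na(rec$age) & rec$age < 0], "age must be nonnegative")
  flag(rec$patient_id[!is.na(rec$spo2) & (rec$spo2 < 0 | rec$spo2 > 100)],
       "spo2 must lie in [0, 100]")
  flag(rec$patient_id[!is.na(rec$resp_rate) & rec$resp_rate <= 0],
       "resp_rate must be positive")
  flag(rec$patient_id[!is.na(rec$creatinine) & rec$creatinine <= 0],
       "creatinine must be positive")
  if (length(bad) == 0L) {
    return(data.frame(patient_id = character(), rule = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}

#' Baseline characteristics table
#'
#' One summary row per baseline covariate: count of non-missing values and
#' mean (which for the binary `sex` indicator is a proportion). Used to check
#' that cloned arms are balanced at baseline -- cloning makes them identical
#' by construction.
#'
#' @param cohort a `ccw_cohort`, or any data frame carrying the covariate
#'   columns (e.g. one arm of a cloned cohort).
#' @return data frame with columns `covariate`, `n`, `mean`.
#' @export
baseline_table <- function(cohort) {
  rec <- if (inherits(cohort, "ccw_cohort")) cohort$records else
    as.data.frame(cohort)
  if (nrow(rec) == 0L) stop("cannot summarise an empty cohort")
  vals <- lapply(.ccw_covariates, function(v) {
    x <- rec[[v]]
    data.frame(covariate = v, n = sum(!is.na(x)), mean = mean(x, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, vals)
}

#' @export
print.ccw_cohort <- function(x, ...) {
  cat("<ccw_cohort> ", nrow(x$records), " admissions\n", sep = "")
  if (length(x$exclusion_log) > 0L) {
    cat("  excluded:", paste(names(x$exclusion_log), x$exclusion_log,
                             sep = "=", collapse = ", "), "\n")
  }
  tab <- table(factor(x$records$event_type, levels = .ccw_event_types))
  cat("  events: death=", tab[["death"]],
      ", discharge=", tab[["discharge"]], "\n", sep = "")
  invisible(x)
}
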