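#' Cohort container
#'
#' A cohort bundles a per-patient table with a long table of time-stamped
#' observations. Times are hours (non-negative reals) from a per-cohort
#' origin; "days" in reports are hours / 24.
#'
#' The patient table has columns `patient_id`, `age`, `sex`, `diagnosis`,
#' `charlson`, `obs_start_h`, `terminal_h`, `terminal_status` (`"died"` or
#' `"censored"`), `censor_reason` (one of [censor_reasons()] or `NA`).
#'
#' The observation table has columns `patient_id`, `time_h`, one 0/1/NA column
#' per charted sign (see [sign_ids()]; `NA` = form not filled, which is
#' neither present nor absent), and optional vitals `sbp`, `dbp`, `hr`,
#' `temp`, `rr`, `spo2` (`NA` = not measured).
#'
#' @param patients Patient data frame as described above.
#' @param observations Observation data frame as described above.
#' @param validate Check all invariants (default `TRUE`).
#' @return An object of class `sid_cohort`.
#' @export
cohort <- function(patients, observations, validate = TRUE) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  obj <- structure(list(patients = patients, observations = observations),
                   class = "sid_cohort")
  if (validate) validate_cohort(obj)
  obj
}

#' Recognised observation-discontinuation reasons
#'
#' Observation stops short of death when one of the study's discontinuation
#' criteria fires: the patient eats more than half of each day's meals for two
#' or more consecutive days, 60 days elapse from the start of observation,
#' discharge or transfer, ventilator management starts, artificial nutrition
#' starts, or a solid-cancer diagnosis is made.
#'
#' @return Character vector of reason codes.
#' @export
censor_reasons <- function() {
  c("ate_half_meal_2d", "elapsed_60d", "discharged", "ventilator",
    "artificial_nutrition", "cancer_diagnosed")
}

.patient_cols <- function() {
  c("patient_id", "age", "sex", "diagnosis", "charlson", "obs_start_h",
    "terminal_h", "terminal_status", "censor_reason")
}

.vitals_cols <- function() c("sbp", "dbp", "hr", "temp", "rr", "spo2")

.obs_cols <- function() c("patient_id", "time_h", sign_ids(), .vitals_cols())

#' Validate a cohort's invariants
#'
#' Checks referential integrity (every observation's patient exists), strict
#' per-patient timestamp ordering, no observation after the terminal time,
#' terminal time not before observation start, and vitals ranges (SBP > 0,
#' HR >= 0, SpO2 in \[0, 100\] where present).
#'
#' @param x A `sid_cohort`.
#' @return `x`, invisibly; stops with a descriptive error on violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "sid_cohort"))
  p <- x$patients
  o <- x$observations
  miss <- setdiff(.patient_cols(), names(p))
  if (length(miss)) stop("patient table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(.obs_cols(), names(o))
  if (length(miss)) stop("observation table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(p$patient_id))
    stop("duplicate patient_id in patient table", call. = FALSE)
  if (!all(p$terminal_status %in% c("died", "censored")))
    stop("terminal_status must be 'died' or 'censored'", call. = FALSE)
  bad <- !is.na(p$censor_reason) & !(p$censor_reason %in% censor_reasons())
  if (any(bad)) stop("unknown censor_reason: ",
                     paste(unique(p$censor_reason[bad]), collapse = ", "),
                     call. = FALSE)
  if (any(p$terminal_h < p$obs_start_h))
    stop("terminal time before observation start for patient(s): ",
         paste(p$patient_id[p$terminal_h < p$obs_start_h], collapse = ", "),
         call. = FALSE)
  if (nrow(o)) {
    unknown <- setdiff(unique(o$patient_id), p$patient_id)
    if (length(unknown))
      stop("observations reference unknown patient(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    ord <- order(match(o$patient_id, p$patient_id), o$time_h)
    os <- o[ord, , drop = FALSE]
    same <- os$patient_id[-1L] == os$patient_id[-nrow(os)]
    nonmono <- same & diff(os$time_h) <= 0
    if (any(nonmono))
      stop("non-increasing timestamps for patient(s): ",
           paste(unique(os$patient_id[-1L][nonmono]), collapse = ", "),
           call. = FALSE)
    term <- p$terminal_h[match(o$patient_id, p$patient_id)]
    start <- p$obs_start_h[match(o$patient_id, p$patient_id)]
    if (any(o$time_h > term))
      stop("observation after terminal time for patient(s): ",
           paste(unique(o$patient_id[o$time_h > term]), collapse = ", "),
           call. = FALSE)
    if (any(o$time_h < start))
      stop("observation before observation start for patient(s): ",
           paste(unique(o$patient_id[o$time_h < start]), collapse = ", "),
           call. = FALSE)
    flags <- as.matrix(o[sign_ids()])
    if (!all(flags %in% c(0, 1, NA)))
      stop("sign flags must be 0, 1 or NA", call. = FALSE)
    if (any(!is.na(o$sbp) & o$sbp <= 0)) stop("SBP must be > 0 where present",
                                              call. = FALSE)
    if (any(!is.na(o$hr) & o$hr < 0)) stop("HR must be >= 0 where present",
                                           call. = FALSE)
    if (any(!is.na(o$spo2) & (o$spo2 < 0 | o$spo2 > 100)))
      stop("SpO2 must lie in [0, 100] where present", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.sid_cohort <- function(x, ...) {
  nd <- sum(x$patients$terminal_status == "died")
  cat(sprintf("<sid_cohort> %d patients (%d died, %d censored), %d observations\n",
              nrow(x$patients), nd, nrow(x$patients) - nd,
              nrow(x$observations)))
  invisible(x)
}

#' Subset a cohort to its decedents
#'
#' All rule statistics are defined on the analysis population of patients who
#' died under observation; censored patients are dropped with a warning when
#' present.
#'
#' @param x A `sid_cohort`.
#' @param warn Warn when censored patients are dropped.
#' @return A `sid_cohort` containing only decedents.
#' @export
decedents <- function(x, warn = TRUE) {
  stopifnot(inherits(x, "sid_cohort"))
  keep <- x$patients$terminal_status == "died"
  if (all(keep)) return(x)
  if (warn) warning(sum(!keep), " censored patient(s) excluded from analysis",
                    call. = FALSE)
  ids <- x$patients$patient_id[keep]
  cohort(x$patients[keep, , drop = FALSE],
         x$observations[x$observations$patient_id %in% ids, , drop = FALSE],
         validate = FALSE)
}

#' Read a cohort from its two CSV files
#'
#' @param patients_path CSV with the patient table columns.
#' @param observations_path CSV with the observation table columns; empty
#'   cells are missing values (never sentinel numbers).
#' @return A validated `sid_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(patients_path, observations_path) {
  for (pth in c(patients_path, observations_path)) {
    if (!file.exists(pth)) stop("file not found: ", pth, call. = FALSE)
  }
  p <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  o <- utils::read.csv(observations_path, stringsAsFactors = FALSE)
  miss <- setdiff(.patient_cols(), names(p))
  if (length(miss)) stop("patient table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(.obs_cols(), names(o))
  if (length(miss)) stop("observation table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(o), .obs_cols())
  if (length(extra)) stop("unknown observation column(s): ",
                          paste(extra, collapse = ", "), call. = FALSE)
  p$patient_id <- as.character(p$patient_id)
  o$patient_id <- as.character(o$patient_id)
  for (cl in c("sex", "diagnosis", "terminal_status", "censor_reason"))
    p[[cl]] <- as.character(p[[cl]])
  for (cl in c("age", "charlson", "obs_start_h", "terminal_h"))
    p[[cl]] <- as.numeric(p[[cl]])
  p$censor_reason[!is.na(p$censor_reason) & p$censor_reason == ""] <- NA
  for (cl in c(sign_ids(), .vitals_cols(), "time_h")) o[[cl]] <- as.numeric(o[[cl]])
  cohort(p[.patient_cols()], o[.obs_cols()])
}

#' Write a cohort to its two CSV files
#'
#' Missing flags and vitals are written as empty cells. `read_cohort()` on the
#' written files returns an equal cohort.
#'
#' @param x A valid `sid_cohort`.
#' @param patients_path,observations_path Output CSV paths.
#' @return The two paths, invisibly.
#' @export
write_cohort <- function(x, patients_path, observations_path) {
  validate_cohort(x)
  utils::write.csv(x$patients[.patient_cols()], patients_path,
                   row.names = FALSE, na = "")
  utils::write.csv(x$observations[.obs_cols()], observations_path,
                   row.names = FALSE, na = "")
  invisible(c(patients_path, observations_path))
}

#' First time a charted sign is observed present
#'
#' Returns the earliest observation timestamp at which the flag is present
#' (1). Missing flags (`NA`) are skipped: absence of a filled form is not
#' absence of the sign. Only the first appearance matters; later
#' disappearance does not undo the event.
#'
#' @param x A `sid_cohort`.
#' @param patient_id Patient identifier.
#' @param sign One of the 11 charted sign ids (the shock-index predictor is
#'   derived from vitals; see [si_event_time()]).
#' @return Time in hours, or `NA_real_` if the sign is never present.
#' @export
first_event_time <- function(x, patient_id, sign) {
  stopifnot(inherits(x, "sid_cohort"))
  if (!sign %in% sign_ids()) stop("unknown sign id: ", sign, call. = FALSE)
  if (!patient_id %in% x$patients$patient_id)
    stop("unknown patient id: ", patient_id, call. = FALSE)
  o <- x$observations[x$observations$patient_id == patient_id, , drop = FALSE]
  hit <- !is.na(o[[sign]]) & o[[sign]] == 1
  if (!any(hit)) return(NA_real_)
  min(o$time_h[hit])
}

#' Apply the observation-discontinuation rules to one patient
#'
#' Truncates a patient record according to the study's stopping rules that can
#' be decided from an intake diary: observation is censored at the end of the
#' second consecutive day on which the patient ate more than half of each
#' meal, or when 60 days have elapsed since the start of observation —
#' whichever fires first. Death occurring before any trigger leaves the record
#' unchanged. Observations after the censoring time are dropped.
#'
#' @param x A `sid_cohort`.
#' @param patient_id Patient to truncate.
#' @param intake Data frame with columns `day` (1-based day index from
#'   observation start) and `ate_more_than_half` (logical), covering the
#'   observation span.
#' @return A new `sid_cohort` with the patient's record truncated (or
#'   unchanged if no trigger fires before the terminal time).
#' @export
apply_discontinuation <- function(x, patient_id, intake) {
  stopifnot(inherits(x, "sid_cohort"))
  i <- match(patient_id, x$patients$patient_id)
  if (is.na(i)) stop("unknown patient id: ", patient_id, call. = FALSE)
  stopifnot(all(c("day", "ate_more_than_half") %in% names(intake)))
  p <- x$patients[i, ]
  intake <- intake[order(intake$day), , drop = FALSE]
  triggers <- c(meal = Inf, sixty = p$obs_start_h + 60 * 24)
  ate <- intake$ate_more_than_half
  if (nrow(intake) >= 2L) {
    consec <- which(ate[-1L] & ate[-length(ate)] &
                      diff(intake$day) == 1L)
    if (length(consec)) {
      # censor at the end of the second qualifying day
      triggers[["meal"]] <- p$obs_start_h + intake$day[consec[1L] + 1L] * 24
    }
  }
  t_trig <- min(triggers)
  if (!is.finite(t_trig) || t_trig >= p$terminal_h) return(x)
  reason <- if (which.min(triggers) == 1L) "ate_half_meal_2d" else "elapsed_60d"
  x$patients$terminal_h[i] <- t_trig
  x$patients$terminal_status[i] <- "censored"
  x$patients$censor_reason[i] <- reason
  drop <- x$observations$patient_id == patient_id & x$observations$time_h > t_trig
  x$observations <- x$observations[!drop, , drop = FALSE]
  validate_cohort(x)
  x
}

# internal: empty observation table with the right columns/types
.empty_observations <- function() {
  cols <- c(list(patient_id = character(0), time_h = numeric(0)),
            stats::setNames(rep(list(numeric(0)), length(sign_ids())), sign_ids()),
            stats::setNames(rep(list(numeric(0)), 6L), .vitals_cols()))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# internal: empty patient table
.empty_patients <- function() {
  data.frame(patient_id = character(0), age = numeric(0), sex = character(0),
             diagnosis = character(0), charlson = numeric(0),
             obs_start_h = numeric(0), terminal_h = numeric(0),
             terminal_status = character(0), censor_reason = character(0),
             stringsAsFactors = FALSE)
}
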