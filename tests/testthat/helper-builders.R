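# tiny builders shared across test files

withr_like_tempdir <- function() {
  d <- file.path(tempdir(), paste0("sid", sample.int(1e8, 1)))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

one_patient_table <- function(pid, death_h, start_h = 0, status = "died") {
  data.frame(patient_id = pid, age = 84, sex = "female", diagnosis = "other",
             charlson = 3, obs_start_h = start_h, terminal_h = death_h,
             terminal_status = status, censor_reason = NA_character_,
             stringsAsFactors = FALSE)
}

empty_obs_table <- function() {
  o <- data.frame(patient_id = character(0), time_h = numeric(0),
                  stringsAsFactors = FALSE)
  for (s in sidmodels::sign_ids()) o[[s]] <- numeric(0)
  for (v in c("sbp", "dbp", "hr", "temp", "rr", "spo2")) o[[v]] <- numeric(0)
  o
}

# observation table for one patient; named args set sign columns (vectors
# aligned with `times`), all other signs default to absent
obs_with_flags <- function(pid, times, ...) {
  o <- data.frame(patient_id = pid, time_h = times, stringsAsFactors = FALSE)
  flags <- list(...)
  for (s in sidmodels::sign_ids())
    o[[s]] <- if (s %in% names(flags)) flags[[s]] else 0
  for (v in c("sbp", "dbp", "hr", "temp", "rr", "spo2")) o[[v]] <- NA_real_
  o
}

# observation table carrying only vitals
obs_with_vitals <- function(pid, times, hr = NA_real_, sbp = NA_real_,
                            ...) {
  o <- obs_with_flags(pid, times)
  o$hr <- hr
  o$sbp <- sbp
  extra <- list(...)
  for (v in names(extra)) o[[v]] <- extra[[v]]
  o
}
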