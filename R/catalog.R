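#' Predictor catalog
#'
#' The fixed, ordered catalog of the 12 binary predictors used throughout the
#' package: 11 bedside physical signs recorded every ~12 hours during the
#' dying phase, plus the derived predictor "shock index > 1.0" (heart rate /
#' systolic blood pressure). The order is part of the contract: it defines
#' tie-breaking in the best-subset search and the column order of every
#' exported table.
#'
#' @return A data frame with columns `id` (snake-case identifier used in CSV
#'   columns), `label` (display name), and `derived` (`TRUE` for the
#'   shock-index predictor, which is computed from vitals rather than charted
#'   as a flag).
#' @examples
#' sign_catalog()
#' @export
sign_catalog <- function() {
  data.frame(
    id = c(
      "resp_verbal_decreased",
      "resp_visual_decreased",
      "peripheral_cyanosis",
      "mandibular_respiration",
      "death_rattle",
      "neck_hyperextension",
      "eyes_unable_to_close",
      "nasolabial_drooping",
      "cheyne_stokes",
      "pulseless_radial",
      "apnea",
      "si_gt1"
    ),
    label = c(
      "Decreased response to verbal stimuli",
      "Decreased response to visual stimuli",
      "Peripheral cyanosis",
      "Respiration with mandibular movement",
      "Death rattle",
      "Hyperextension of the neck",
      "Inability to close the eyes",
      "Drooping of the nasolabial fold",
      "Cheyne-Stokes breathing",
      "Pulselessness of the radial artery",
      "Apnea",
      "Shock index > 1.0"
    ),
    derived = c(rep(FALSE, 11), TRUE),
    stringsAsFactors = FALSE
  )
}

#' Identifiers of the 11 charted physical signs (catalog order, no shock index)
#' @return Character vector of length 11.
#' @export
sign_ids <- function() {
  cat <- sign_catalog()
  cat$id[!cat$derived]
}

#' Identifiers of all 12 predictors (catalog order)
#' @return Character vector of length 12.
#' @export
predictor_ids <- function() sign_catalog()$id

# internal: catalog index of a predictor id, erroring on unknown ids
.predictor_index <- function(id) {
  idx <- match(id, predictor_ids())
  if (anyNA(idx)) {
    stop("unknown predictor id(s): ", paste(id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Prediction horizons
#'
#' The three prediction windows: death within 7 days (168 h), within 72 hours,
#' and within 24 hours of the rule event.
#'
#' @param label One of `"7d"`, `"72h"`, `"24h"`.
#' @return A list with `label` and `hours`.
#' @examples
#' horizon("7d")$hours  # 168
#' @export
horizon <- function(label = c("7d", "72h", "24h")) {
  label <- match.arg(label)
  hours <- c("7d" = 168, "72h" = 72, "24h" = 24)[[label]]
  structure(list(label = label, hours = hours), class = "sid_horizon")
}

# internal: accept a sid_horizon, a label, or a positive number of hours
.horizon_hours <- function(h) {
  if (inherits(h, "sid_horizon")) return(h$hours)
  if (is.character(h)) return(horizon(h)$hours)
  if (is.numeric(h) && length(h) == 1L && h > 0) return(as.numeric(h))
  stop("invalid horizon: supply '7d', '72h', '24h' or a positive number of hours",
       call. = FALSE)
}
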