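# Deriving the trial's exposure and severe-hypoxia definitions from
# raw-style medication-administration and respiratory-support records.

GLUCOCORTICOIDS <- c(prednisone = 5, prednisolone = 5, methylprednisolone = 4,
                     hydrocortisone = 20, dexamethasone = 0.75)

RESP_MODES <- c("room_air", "nasal_cannula", "high_flow_nc", "venturi",
                "niv", "imv")

#' Methylprednisolone-equivalent dose
#'
#' Converts a glucocorticoid dose to its methylprednisolone equivalent using
#' the standard equivalency table (methylprednisolone 4 mg = prednisone 5 mg
#' = prednisolone 5 mg = hydrocortisone 20 mg = dexamethasone 0.75 mg).
#'
#' @param drug Drug name (one of the five systemic glucocorticoids).
#' @param dose_mg Administered dose in mg (> 0).
#' @return Dose in mg methylprednisolone-equivalent.
#' @examples
#' mpred_equivalent("dexamethasone", 6)   # 32 mg
#' @export
mpred_equivalent <- function(drug, dose_mg) {
  drug <- as.character(drug)
  bad <- !drug %in% names(GLUCOCORTICOIDS)
  if (any(bad)) {
    stop("unknown drug: ", paste(unique(drug[bad]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(dose_mg > 0))
  unname(dose_mg * 4 / GLUCOCORTICOIDS[drug])
}

#' Daily corticosteroid exposure from medication-administration records
#'
#' A day counts as exposed when some rolling 24-hour window ending within
#' that day accumulates at least `threshold_mg_kg` (default 0.5) mg/kg of
#' methylprednisolone-equivalent corticosteroid.  The window sum is
#' evaluated event-wise: within a day it can only peak at the start of the
#' day or at a record time, so those endpoints are checked.
#'
#' @param records Data frame with `timestamp` (hours from admission),
#'   `drug`, `dose_mg`.
#' @param weight_kg Patient weight (> 0).
#' @param horizon Days of follow-up.
#' @param threshold_mg_kg Dose threshold per 24 h.
#' @return Integer 0/1 vector of length `horizon` (day 0 first).
#' @examples
#' rec <- data.frame(timestamp = c(0, 12), drug = "methylprednisolone",
#'                   dose_mg = c(20, 25))
#' derive_daily_exposure(rec, weight_kg = 80, horizon = 3)
#' @export
derive_daily_exposure <- function(records, weight_kg, horizon,
                                  threshold_mg_kg = 0.5) {
  stopifnot(weight_kg > 0, horizon >= 1)
  out <- integer(horizon)
  if (is.null(records) || nrow(records) == 0L) return(out)
  if (any(records$timestamp < 0)) {
    stop("records with negative timestamps", call. = FALSE)
  }
  eq <- mpred_equivalent(records$drug, records$dose_mg)
  ts <- records$timestamp
  thr <- threshold_mg_kg * weight_kg
  win_sum <- function(e) sum(eq[ts > e - 24 & ts <= e])
  for (t in seq_len(horizon) - 1L) {
    ends <- c(24 * t, ts[ts >= 24 * t & ts < 24 * (t + 1)])
    if (any(vapply(ends, win_sum, numeric(1)) >= thr)) out[t + 1L] <- 1L
  }
  out
}

#' Daily severe-hypoxia indicator from respiratory-support records
#'
#' A day is severely hypoxic if any record that day shows high-flow nasal
#' cannula, venturi mask, noninvasive or invasive mechanical ventilation, or
#' nasal cannula at 6 L/min or more with an oxygen saturation below 93%.
#'
#' @param records Data frame with `timestamp` (hours), `mode`,
#'   `o2_flow_lpm`, `spo2_pct`.
#' @param horizon Days of follow-up.
#' @return Integer 0/1 vector of length `horizon`.
#' @examples
#' rec <- data.frame(timestamp = 80, mode = "nasal_cannula",
#'                   o2_flow_lpm = 6, spo2_pct = 92)
#' derive_daily_hypoxia(rec, horizon = 5)
#' @export
derive_daily_hypoxia <- function(records, horizon) {
  stopifnot(horizon >= 1)
  out <- integer(horizon)
  if (is.null(records) || nrow(records) == 0L) return(out)
  bad <- !records$mode %in% RESP_MODES
  if (any(bad)) {
    stop("unknown respiratory mode: ",
         paste(unique(records$mode[bad]), collapse = ", "), call. = FALSE)
  }
  qualifies <- records$mode %in% c("high_flow_nc", "venturi", "niv", "imv") |
    (records$mode == "nasal_cannula" &
       records$o2_flow_lpm >= 6 & records$spo2_pct < 93)
  day <- floor(records$timestamp / 24)
  hit <- unique(day[qualifies & day >= 0 & day < horizon])
  out[hit + 1L] <- 1L
  out
}

#' Apply the trial's eligibility criteria
#'
#' Retains patients with neither chronic pre-hospitalization corticosteroid
#' use nor transfer from an outside hospital, and logs exclusion counts per
#' reason.  Idempotent.
#'
#' @param patients Data frame with logical/0-1 columns `chronic_steroids`
#'   and `transfer_in`.
#' @return The retained rows, with attribute `exclusion_log` (named counts).
#' @export
apply_eligibility <- function(patients) {
  need <- c("chronic_steroids", "transfer_in")
  miss <- setdiff(need, names(patients))
  if (length(miss)) {
    stop("missing eligibility flags: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  chronic <- as.logical(patients$chronic_steroids)
  transfer <- as.logical(patients$transfer_in)
  if (anyNA(chronic) || anyNA(transfer)) {
    stop("eligibility flags contain missing values", call. = FALSE)
  }
  keep <- !chronic & !transfer
  out <- patients[keep, , drop = FALSE]
  attr(out, "exclusion_log") <- c(chronic_steroids = sum(chronic),
                                  transfer_in = sum(transfer & !chronic),
                                  retained = sum(keep))
  out
}

#' Read medication-administration records from delimited text
#'
#' Expects columns `patient_id`, `timestamp` (hours from admission),
#' `drug`, `dose_mg`.
#' @param path File path.
#' @return A validated data.frame.
#' @export
read_med_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timestamp", "drug", "dose_mg")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  mpred_equivalent(x$drug, x$dose_mg)  # validates drugs and doses
  x
}

#' Read respiratory-support records from delimited text
#'
#' Expects columns `patient_id`, `timestamp`, `mode`, `o2_flow_lpm`,
#' `spo2_pct`.
#' @param path File path.
#' @return A validated data.frame.
#' @export
read_resp_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timestamp", "mode", "o2_flow_lpm", "spo2_pct")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  stopifnot(all(x$spo2_pct >= 0 & x$spo2_pct <= 100), all(x$o2_flow_lpm >= 0))
  x
}
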