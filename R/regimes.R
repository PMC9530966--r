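#' Treatment regimes
#'
#' A regime maps a patient's evolving history to a treatment decision each
#' day.  Two regimes are supported, mirroring the two arms of the emulated
#' trial: a dynamic corticosteroid regime that starts a fixed-length course
#' (default 6 days) on the first day the patient meets severe-hypoxia
#' criteria, and a static regime that never treats.
#'
#' @param kind `"dynamic"` (treat for `duration` consecutive days beginning
#'   the first hypoxic day) or `"never"` (never treat).
#' @param duration Course length in days for the dynamic regime.
#' @return An object of class `regime`.
#' @examples
#' regime("dynamic")
#' regime("never")
#' @export
regime <- function(kind = c("dynamic", "never"), duration = 6L) {
  kind <- match.arg(kind)
  duration <- as.integer(duration)
  stopifnot(duration >= 1L)
  structure(list(kind = kind, duration = duration), class = "regime")
}

#' @export
print.regime <- function(x, ...) {
  if (x$kind == "dynamic") {
    cat(sprintf("<regime> dynamic: %d-day corticosteroid course from first hypoxic day\n",
                x$duration))
  } else {
    cat("<regime> static: never treat\n")
  }
  invisible(x)
}

#' Treatment assignment under a regime
#'
#' Given the daily severe-hypoxia indicators observed for one patient from
#' admission (day 0) onward, returns the treatment the regime assigns on each
#' of those days.  The dynamic regime treats on days `t*` through
#' `t* + duration - 1`, where `t*` is the first hypoxic day, truncated at the
#' end of follow-up; the never-treat regime assigns 0 always.
#'
#' @param regime A [regime()] object.
#' @param hypoxia Integer/logical vector of daily hypoxia indicators,
#'   day 0 first.
#' @return Integer 0/1 vector of the same length.
#' @examples
#' assign_regime(regime("dynamic"), c(0, 0, 1, 0, 1, 0, 0, 0, 0))
#' @export
assign_regime <- function(regime, hypoxia) {
  stopifnot(inherits(regime, "regime"))
  hypoxia <- as.integer(hypoxia)
  days <- seq_along(hypoxia) - 1L
  if (regime$kind == "never" || !any(hypoxia == 1L)) {
    return(integer(length(hypoxia)))
  }
  t_star <- days[which(hypoxia == 1L)[1L]]
  as.integer(days >= t_star & days <= t_star + regime$duration - 1L)
}
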