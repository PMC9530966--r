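# Shared fixtures, generated in code.

# small enumerable process used across oracle tests
tiny_cfg <- function(...) discrete_dgp_config(seed = 11, ...)

sat_learner <- function() list(learner("saturated"))
lin_learner <- function() list(learner("linear_additive"))

# per-patient summary flags
patient_flag <- function(cohort, col, fun = function(v) any(v == 1L)) {
  vapply(split(cohort[[col]], cohort$patient_id), fun, logical(1))
}

# a minimal hand-built point-treatment cohort (horizon 1): known propensity
# 0.5, no censoring.  Returns a valid long_cohort.
ht_fixture <- function() {
  coh <- data.frame(
    patient_id = 1:10, day = 0L,
    age = 0, sex = 0L, comorb = 0L,
    severity = rep(c(0, 1), 5), hypoxia = rep(c(0L, 1L), 5),
    A = c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 1L),
    Y = c(1L, 0L, 1L, 0L, 0L, 0L, 1L, 1L, 0L, 0L),
    C = 0L)
  attr(coh, "horizon") <- 1L
  attr(coh, "treat_window") <- 6L
  class(coh) <- c("long_cohort", "data.frame")
  coh
}
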