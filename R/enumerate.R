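# Exact enumeration over the finite-state (binary-severity) cohort process.
# These are the oracles the Monte-Carlo and estimation machinery are tested
# against: no sampling, just summation over all trajectories weighted by
# their probabilities under the process.

baseline_cells <- function(cfg) {
  bl <- cfg$baseline_coefs
  if (is.null(bl$age_values)) {
    stop("exact enumeration needs a discrete age support (age_values/age_probs); ",
         "see discrete_dgp_config()", call. = FALSE)
  }
  cells <- expand.grid(age_i = seq_along(bl$age_values),
                       sex = 0:1, comorb = 0:1)
  cells$age <- bl$age_values[cells$age_i]
  p_male <- bl$p_male %||% 0.5
  p_com <- bl$p_comorb %||% 0
  cells$p <- bl$age_probs[cells$age_i] *
    ifelse(cells$sex == 1, p_male, 1 - p_male) *
    ifelse(cells$comorb == 1, p_com, 1 - p_com)
  cells[cells$p > 0, c("age", "sex", "comorb", "p")]
}

# P(S_t = 1 | history) in binary severity mode
binary_sev_prob <- function(cfg, t, S_prev, A_prev, age, sex, comorb) {
  sc <- cfg$severity_coefs
  lp <- if (t == 0L) {
    lin_pred(sc$init, list(age = age, comorb = comorb, sex = sex), 1L)
  } else {
    lin_pred(effective_trans_coefs(cfg),
             list(prev_severity = S_prev, prev_treat = A_prev,
                  age = age, comorb = comorb, sex = sex), 1L)
  }
  stats::plogis(lp)
}

hazard_prob <- function(coefs, extra, age, sex, comorb, S, hyp, A_prev) {
  stats::plogis(lin_pred(coefs, list(age = age, sex = sex, comorb = comorb,
                                     severity = S, hypoxia = hyp,
                                     prev_treat = A_prev), 1L) + extra)
}

#' Exact counterfactual mortality risk by trajectory enumeration
#'
#' For a finite-state configuration (binary severity, discrete baseline
#' support; see [discrete_dgp_config()]) and a treatment regime, computes the
#' exact probability of death by the horizon in the hypothetical world where
#' treatment follows the regime and loss to follow-up is abolished, by
#' summing over every baseline cell and severity path weighted by its
#' probability.  Deterministic; the brute-force oracle for
#' [counterfactual_risk_mc()] and the estimators.
#'
#' @param config A binary-severity [dgp_config()].
#' @param regime A [regime()].
#' @param state_cap Refuse to enumerate more than this many (cell, severity
#'   path) combinations.
#' @return The exact counterfactual risk (scalar).
#' @examples
#' cfg <- discrete_dgp_config()
#' enumerate_truth(cfg, regime("dynamic")) - enumerate_truth(cfg, regime("never"))
#' @export
enumerate_truth <- function(config, regime, state_cap = 1e6) {
  validate_dgp_config(config)
  stopifnot(inherits(regime, "regime"))
  if (config$severity_mode != "binary") {
    stop("enumerate_truth requires severity_mode = 'binary'", call. = FALSE)
  }
  horizon <- config$horizon
  cells <- baseline_cells(config)
  n_states <- nrow(cells) * 2^horizon
  if (n_states > state_cap) {
    stop("state space (", n_states, ") exceeds state_cap", call. = FALSE)
  }
  sev_paths <- as.matrix(expand.grid(rep(list(0:1), horizon)))

  total <- 0
  for (ci in seq_len(nrow(cells))) {
    age <- cells$age[ci]; sex <- cells$sex[ci]; comorb <- cells$comorb[ci]
    for (pi in seq_len(nrow(sev_paths))) {
      s <- sev_paths[pi, ]
      # hypoxia == severity in binary mode; regime fixes treatment
      a <- assign_regime(regime, s)
      p_path <- 1
      surv <- 1
      p_die_path <- 0
      last_treat <- -999L
      for (t in seq_len(horizon) - 1L) {
        A_prev <- if (t == 0L) 0L else a[t]
        pS1 <- binary_sev_prob(config, t, if (t == 0L) 0 else s[t], A_prev,
                               age, sex, comorb)
        p_path <- p_path * if (s[t + 1L] == 1) pS1 else 1 - pS1
        if (a[t + 1L] == 1L) last_treat <- t
        recent <- as.integer(last_treat >= 0L &&
                               t - last_treat < config$treat_window)
        h <- hazard_prob(config$death_hazard_coefs,
                         config$treatment_effect * recent,
                         age, sex, comorb, s[t + 1L], s[t + 1L], A_prev)
        p_die_path <- p_die_path + surv * h
        surv <- surv * (1 - h)
      }
      total <- total + cells$p[ci] * p_path * p_die_path
    }
  }
  unname(total)
}

#' Exact observed-data law as a trajectory-weighted cohort
#'
#' Enumerates every possible observed trajectory of a finite-state
#' configuration under the observational law (random treatment from the
#' propensity, informative discharge active) and emits each as a pseudo
#' patient whose person-day rows carry the trajectory's exact probability in
#' the `.w` column.  Running an estimator with these weights is equivalent to
#' running it on the population distribution itself: with saturated
#' (cell-mean) regressions the estimators then reproduce the exact g-formula
#' value, which is how the estimator implementations are verified against
#' [enumerate_truth()] to numerical precision.
#'
#' @inheritParams enumerate_truth
#' @param traj_cap Refuse to emit more than this many trajectories.
#' @return A `long_cohort` with a `.w` weight column (constant within
#'   patient).
#' @export
enumerate_cohort <- function(config, traj_cap = 1e6) {
  validate_dgp_config(config)
  if (config$severity_mode != "binary") {
    stop("enumerate_cohort requires severity_mode = 'binary'", call. = FALSE)
  }
  horizon <- config$horizon
  cells <- baseline_cells(config)
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$pid <- 0L

  emit <- function(hist_rows, w) {
    env$pid <- env$pid + 1L
    if (env$pid > traj_cap) stop("trajectory cap exceeded", call. = FALSE)
    out <- do.call(rbind, hist_rows)
    out$patient_id <- env$pid
    out$.w <- w
    env$rows[[env$pid]] <- out
  }

  walk <- function(t, age, sex, comorb, S_prev, A_prev, last_treat,
                   cum_treat, seen_hyp, prob, hist_rows) {
    pS1 <- binary_sev_prob(config, t, S_prev, A_prev, age, sex, comorb)
    for (S in 0:1) {
      pS <- if (S == 1) pS1 else 1 - pS1
      if (pS <= 0) next
      pA1 <- stats::plogis(lin_pred(
        config$treat_propensity_coefs,
        list(age = age, sex = sex, comorb = comorb, severity = S,
             hypoxia = S, prev_treat = A_prev,
             new_hypoxia = as.integer(S == 1 && !seen_hyp),
             cum_treat_prev = cum_treat,
             on_course = as.integer(A_prev == 1L &&
                                      cum_treat < config$treat_window)), 1L))
      for (A in 0:1) {
        pA <- if (A == 1) pA1 else 1 - pA1
        if (pA <= 0) next
        lt <- if (A == 1L) t else last_treat
        recent <- as.integer(lt >= 0L && t - lt < config$treat_window)
        pd <- hazard_prob(config$death_hazard_coefs,
                          config$treatment_effect * recent,
                          age, sex, comorb, S, S, A_prev)
        pc <- hazard_prob(config$discharge_hazard_coefs, 0,
                          age, sex, comorb, S, S, A_prev)
        row <- function(Y, C) {
          data.frame(patient_id = NA_integer_, day = t, age = age, sex = sex,
                     comorb = comorb, severity = S, hypoxia = S, A = A,
                     Y = Y, C = C)
        }
        # death during the day
        emit(c(hist_rows, list(row(1L, 0L))), prob * pS * pA * pd)
        # survive + discharged at end of day
        emit(c(hist_rows, list(row(0L, 1L))), prob * pS * pA * (1 - pd) * pc)
        # survive, remain in follow-up
        p_cont <- prob * pS * pA * (1 - pd) * (1 - pc)
        if (t == horizon - 1L) {
          emit(c(hist_rows, list(row(0L, 0L))), p_cont)
        } else {
          walk(t + 1L, age, sex, comorb, S, A, lt, cum_treat + A,
               seen_hyp || S == 1, p_cont,
               c(hist_rows, list(row(0L, 0L))))
        }
      }
    }
  }

  for (ci in seq_len(nrow(cells))) {
    walk(0L, cells$age[ci], cells$sex[ci], cells$comorb[ci],
         S_prev = 0, A_prev = 0L, last_treat = -999L,
         cum_treat = 0L, seen_hyp = FALSE,
         prob = cells$p[ci], hist_rows = list())
  }
  cohort <- do.call(rbind, env$rows)
  rownames(cohort) <- NULL
  attr(cohort, "horizon") <- horizon
  attr(cohort, "treat_window") <- config$treat_window
  class(cohort) <- c("long_cohort", "data.frame")
  cohort
}
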