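#' Configuration of the synthetic hospitalized-cohort generating process
#'
#' The generator emulates the observed-data structure of a daily-resolution
#' hospital cohort followed for 28 days: a latent illness-severity process
#' drives severe hypoxia, corticosteroid treatment, death, and discharge, and
#' is itself pushed down by recent treatment — the treatment-confounder
#' feedback loop that makes naive analyses of such cohorts biased.  Time is
#' binned into calendar days from admission; when death and discharge would
#' both occur in a day, death is adjudicated first.
#'
#' Per day, in order: severity updates (AR(1) in the continuous mode, a
#' two-state Markov chain in the binary mode); hypoxia is severity above
#' `hypoxia_threshold` (in binary mode, severity itself); a labs-measured
#' indicator is drawn with probability increasing in severity (informative
#' measurement); treatment is drawn from a logistic propensity on baseline
#' covariates, severity, hypoxia and previous-day treatment; death occurs
#' with a logistic discrete hazard shifted by `treatment_effect` on the
#' log-odds scale while the patient is within `treat_window` days of a
#' treated day; survivors may be discharged (lost to follow-up) with a
#' logistic hazard decreasing in severity, making censoring informative.
#'
#' Baseline covariates are standardized age, binary sex, and a binary
#' comorbidity indicator.  All coefficient vectors are named; names must be
#' `intercept` or a state variable (`age`, `sex`, `comorb`, `severity`,
#' `hypoxia`, `prev_severity`, `prev_treat`, `recent_treat`).
#'
#' @param n_patients Number of patients.
#' @param horizon Days of follow-up from admission (day 0 .. horizon-1).
#' @param baseline_coefs List with `p_male`, `p_comorb`, and (binary mode
#'   only) `age_values`/`age_probs` giving a discrete age support.
#' @param severity_mode `"gaussian"` (continuous AR(1) severity) or
#'   `"binary"` (two-state Markov severity, enumerable exactly).
#' @param severity_coefs Severity-process coefficients.  Gaussian mode:
#'   `init_intercept`, `init_age`, `init_comorb`, `init_sd`, `rho`, `drift`,
#'   `treat_lag`, `shock_sd`.  Binary mode: named vectors `init` (logit of
#'   P(S_0 = 1)) and `trans` (logit of P(S_t = 1 | history)).  The severity
#'   relief from recent treatment (`treat_lag`, and the `prev_treat` entry
#'   of `trans`) is a per-unit scale multiplied by `treatment_effect`, so
#'   the null switches off both the direct hazard shift and the severity
#'   pathway — under `treatment_effect = 0` every regime has identical
#'   counterfactual risks.
#' @param hypoxia_threshold Severity above this value means a severely
#'   hypoxic day (gaussian mode).
#' @param measurement_coefs Named coefficients for the daily labs-measured
#'   indicator, or `NULL` to omit the indicator.
#' @param treat_propensity_coefs Logistic coefficients of the observational
#'   treatment mechanism.
#' @param death_hazard_coefs Logistic discrete-hazard coefficients for death.
#' @param treatment_effect Log-odds shift on the death hazard on days within
#'   `treat_window` days of a treated day; 0 encodes the null.
#' @param treat_window Days a treated day keeps shifting the death hazard
#'   (matches the 6-day course of the dynamic regime).
#' @param discharge_hazard_coefs Logistic hazard coefficients for discharge;
#'   a negative severity coefficient makes loss to follow-up informative.
#' @param seed Master seed; expanded into per-(day, draw) substreams so that
#'   increasing `n_patients` appends patients without altering earlier ones.
#' @return An object of class `dgp_config`.
#' @seealso [simulate_cohort()], [counterfactual_risk_mc()],
#'   [enumerate_truth()], [discrete_dgp_config()]
#' @export
dgp_config <- function(n_patients = 3000L,
                       horizon = 28L,
                       baseline_coefs = list(p_male = 0.5, p_comorb = 0.3),
                       severity_mode = c("gaussian", "binary"),
                       severity_coefs = list(
                         init_intercept = 0.0, init_age = 0.6,
                         init_comorb = 0.8, init_sd = 0.8,
                         rho = 0.9, drift = 0.02, treat_lag = 0.3,
                         shock_sd = 0.45),
                       hypoxia_threshold = 0.8,
                       measurement_coefs = c(intercept = 0.2, severity = 0.8),
                       treat_propensity_coefs = c(intercept = -5.4,
                                                  severity = 0.6,
                                                  hypoxia = 0.8,
                                                  new_hypoxia = 1.9,
                                                  comorb = 0.3,
                                                  on_course = 8.6),
                       death_hazard_coefs = c(intercept = -5.2,
                                              severity = 1.3,
                                              age = 0.3, comorb = 0.4),
                       treatment_effect = -0.2,
                       treat_window = 6L,
                       discharge_hazard_coefs = c(intercept = -2.2,
                                                  severity = -1.2),
                       seed = 1L) {
  severity_mode <- match.arg(severity_mode)
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    horizon = as.integer(horizon),
    baseline_coefs = baseline_coefs,
    severity_mode = severity_mode,
    severity_coefs = severity_coefs,
    hypoxia_threshold = hypoxia_threshold,
    measurement_coefs = measurement_coefs,
    treat_propensity_coefs = treat_propensity_coefs,
    death_hazard_coefs = death_hazard_coefs,
    treatment_effect = treatment_effect,
    treat_window = as.integer(treat_window),
    discharge_hazard_coefs = discharge_hazard_coefs,
    seed = as.integer(seed)
  ), class = "dgp_config")
  validate_dgp_config(cfg)
}

#' A small exactly-enumerable cohort process
#'
#' Restriction of [dgp_config()] to a finite state space: two-point age
#' support, binary comorbidity, two-state Markov severity (hypoxia equals
#' severity), horizon 3, no measurement indicator.  Small enough that
#' counterfactual risks can be computed exactly by summing over all
#' trajectories ([enumerate_truth()]), which serves as the oracle for the
#' Monte-Carlo and estimation machinery.
#'
#' @param n_patients,horizon,treatment_effect,seed Overrides of the defaults.
#' @param ... Further fields passed to [dgp_config()].
#' @return A `dgp_config` with `severity_mode = "binary"`.
#' @export
discrete_dgp_config <- function(n_patients = 2000L, horizon = 3L,
                                treatment_effect = -0.7, seed = 1L, ...) {
  args <- list(
    n_patients = n_patients,
    horizon = horizon,
    baseline_coefs = list(p_male = 0.5, p_comorb = 0.4,
                          age_values = c(-1, 1), age_probs = c(0.5, 0.5)),
    severity_mode = "binary",
    severity_coefs = list(
      init = c(intercept = -0.4, age = 0.5, comorb = 0.8),
      trans = c(intercept = -1.4, prev_severity = 2.2, prev_treat = 1.0,
                comorb = 0.4)),
    hypoxia_threshold = 0.5,
    measurement_coefs = NULL,
    treat_propensity_coefs = c(intercept = -1.6, severity = 1.6,
                               prev_treat = 1.2),
    death_hazard_coefs = c(intercept = -2.4, severity = 1.5, age = 0.3,
                           comorb = 0.3),
    treatment_effect = treatment_effect,
    discharge_hazard_coefs = c(intercept = -1.6, severity = -1.3),
    seed = seed)
  do.call(dgp_config, utils::modifyList(args, list(...)))
}

validate_dgp_config <- function(cfg) {
  stopifnot(inherits(cfg, "dgp_config"))
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (cfg$horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  assert_finite_coefs(cfg$baseline_coefs, "baseline_coefs")
  assert_finite_coefs(cfg$severity_coefs, "severity_coefs")
  assert_finite_coefs(cfg$death_hazard_coefs, "death_hazard_coefs")
  assert_finite_coefs(cfg$discharge_hazard_coefs, "discharge_hazard_coefs")
  assert_finite_coefs(cfg$treat_propensity_coefs, "treat_propensity_coefs")
  if (!is.finite(cfg$treatment_effect)) {
    stop("non-finite values in treatment_effect", call. = FALSE)
  }
  if (cfg$severity_mode == "binary" &&
      !all(c("init", "trans") %in% names(cfg$severity_coefs))) {
    stop("binary severity_coefs need 'init' and 'trans'", call. = FALSE)
  }
  cfg
}

#' @export
print.dgp_config <- function(x, ...) {
  cat(sprintf("<dgp_config> %d patients, horizon %d days, %s severity\n",
              x$n_patients, x$horizon, x$severity_mode))
  cat(sprintf("  treatment_effect (log-odds on death while recently treated): %.3g\n",
              x$treatment_effect))
  invisible(x)
}

# In binary mode the prev_treat transition coefficient is a per-unit scale on
# treatment_effect, so the null (treatment_effect = 0) silences the severity
# pathway as well as the direct death-hazard shift.
effective_trans_coefs <- function(cfg) {
  tr <- cfg$severity_coefs$trans
  if ("prev_treat" %in% names(tr)) {
    tr[["prev_treat"]] <- tr[["prev_treat"]] * cfg$treatment_effect
  }
  tr
}

# Draw baseline covariates for n patients (substreams of day 0, kinds 6-8).
draw_baseline <- function(cfg, n, seed) {
  U <- sub_runif_block(n, 3L, seed, -1L)
  u_age <- U[1L, ]; u_sex <- U[2L, ]; u_com <- U[3L, ]
  bl <- cfg$baseline_coefs
  if (!is.null(bl$age_values)) {
    age <- bl$age_values[1L + findInterval(u_age, cumsum(bl$age_probs),
                                           left.open = TRUE)]
  } else {
    age <- stats::qnorm(u_age)
  }
  list(age = age,
       sex = as.integer(u_sex < (bl$p_male %||% 0.5)),
       comorb = as.integer(u_com < (bl$p_comorb %||% 0)))
}

# One pass of the data-generating process, vectorized over patients.
# mode "observational": treatment from the propensity, discharge active.
# mode "intervention": treatment forced by `regime`, discharge disabled
# (the trial's hypothetical world with no loss to follow-up).
run_dgp <- function(cfg, n, seed, mode = c("observational", "intervention"),
                    regime = NULL, keep_rows = TRUE) {
  mode <- match.arg(mode)
  if (mode == "intervention") stopifnot(inherits(regime, "regime"))
  horizon <- cfg$horizon
  bl <- draw_baseline(cfg, n, seed)
  age <- bl$age; sex <- bl$sex; comorb <- bl$comorb

  alive <- rep(TRUE, n)
  censored <- rep(FALSE, n)
  S_prev <- rep(0, n)
  A_prev <- rep(0L, n)
  recent_prev <- rep(0L, n)          # recently treated as of end of yesterday
  last_treat <- rep(-999L, n)
  cum_treat <- rep(0L, n)            # treated days before today
  t_star <- rep(NA_integer_, n)      # first hypoxic day
  has_meas <- !is.null(cfg$measurement_coefs)
  rows <- if (keep_rows) vector("list", horizon)

  for (t in seq_len(horizon) - 1L) {
    U <- sub_runif_block(n, 5L, seed, t)
    u_sev <- U[1L, ]; u_meas <- U[2L, ]; u_trt <- U[3L, ]
    u_die <- U[4L, ]; u_dis <- U[5L, ]
    at_risk <- alive & !censored

    sc <- cfg$severity_coefs
    if (cfg$severity_mode == "gaussian") {
      if (t == 0L) {
        S <- sc$init_intercept + sc$init_age * age + sc$init_comorb * comorb +
          sc$init_sd * stats::qnorm(u_sev)
      } else {
        # the severity relief from treatment scales with treatment_effect:
        # at the null the regime has no effect through any pathway
        S <- sc$drift + sc$rho * S_prev +
          sc$treat_lag * cfg$treatment_effect * recent_prev +
          sc$shock_sd * stats::qnorm(u_sev)
      }
    } else {
      lp <- if (t == 0L) {
        lin_pred(sc$init, list(age = age, comorb = comorb, sex = sex), n)
      } else {
        lin_pred(effective_trans_coefs(cfg), list(
          prev_severity = S_prev, prev_treat = A_prev,
          age = age, comorb = comorb, sex = sex), n)
      }
      S <- as.numeric(u_sev < stats::plogis(lp))
    }
    hypox <- as.integer(S > cfg$hypoxia_threshold)
    t_star <- ifelse(is.na(t_star) & hypox == 1L & at_risk, t, t_star)

    state <- list(age = age, sex = sex, comorb = comorb, severity = S,
                  hypoxia = hypox, prev_treat = A_prev,
                  new_hypoxia = as.integer(!is.na(t_star) & t_star == t),
                  cum_treat_prev = cum_treat,
                  on_course = as.integer(A_prev == 1L &
                                           cum_treat < cfg$treat_window))
    meas <- if (has_meas) {
      as.integer(u_meas < stats::plogis(
        lin_pred(cfg$measurement_coefs, state, n)))
    } else rep(NA_integer_, n)

    if (mode == "observational") {
      pA <- stats::plogis(lin_pred(cfg$treat_propensity_coefs, state, n))
      A <- as.integer(u_trt < pA)
    } else if (regime$kind == "dynamic") {
      A <- as.integer(!is.na(t_star) & t >= t_star &
                        t <= t_star + regime$duration - 1L)
    } else {
      A <- integer(n)
    }
    A[!at_risk] <- 0L
    last_treat <- ifelse(A == 1L, t, last_treat)
    cum_treat <- cum_treat + A
    recent <- as.integer(t - last_treat < cfg$treat_window & last_treat >= 0L)

    p_die <- stats::plogis(
      lin_pred(cfg$death_hazard_coefs, state, n) +
        cfg$treatment_effect * recent)
    died_today <- at_risk & (u_die < p_die)

    if (mode == "observational") {
      p_dis <- stats::plogis(lin_pred(cfg$discharge_hazard_coefs, state, n))
      disch_today <- at_risk & !died_today & (u_dis < p_dis)
    } else {
      disch_today <- rep(FALSE, n)
    }

    if (keep_rows && any(at_risk)) {
      idx <- which(at_risk)
      rows[[t + 1L]] <- data.frame(
        patient_id = idx, day = t,
        age = age[idx], sex = sex[idx], comorb = comorb[idx],
        severity = S[idx], hypoxia = hypox[idx], measured = meas[idx],
        A = A[idx], Y = as.integer(died_today[idx]),
        C = as.integer(disch_today[idx]))
    }

    alive[died_today] <- FALSE
    censored[disch_today] <- TRUE
    S_prev <- S; A_prev <- A; recent_prev <- recent
  }

  out <- list(died = !alive, censored = censored, n = n)
  if (keep_rows) {
    cohort <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    cohort <- cohort[order(cohort$patient_id, cohort$day), , drop = FALSE]
    rownames(cohort) <- NULL
    if (!has_meas) cohort$measured <- NULL
    attr(cohort, "horizon") <- horizon
    attr(cohort, "treat_window") <- cfg$treat_window
    class(cohort) <- c("long_cohort", "data.frame")
    out$cohort <- cohort
  }
  out
}

#' Simulate an observational hospitalized cohort
#'
#' Draws a longitudinal cohort from the configured process under the
#' observational treatment mechanism, with informative discharge.  The
#' result is a person-day table: one row per patient per day at risk, with
#' baseline covariates (`age`, `sex`, `comorb`), time-varying covariates
#' (`severity`, `hypoxia`, and `measured` if configured), daily treatment
#' `A`, death `Y`, and loss to follow-up `C`.  Death is absorbing and takes
#' precedence over discharge; no rows follow either event.
#'
#' @param config A [dgp_config()].
#' @param n_patients,seed Optional overrides of the config's values.
#' @param regime Optional [regime()]: simulate the hypothetical world
#'   instead — treatment forced to the regime's assignment and loss to
#'   follow-up abolished.
#' @return A `long_cohort` (data.frame) sorted by patient and day, with a
#'   `horizon` attribute.
#' @examples
#' coh <- simulate_cohort(dgp_config(n_patients = 200, seed = 7))
#' head(coh)
#' @export
simulate_cohort <- function(config, n_patients = config$n_patients,
                            seed = config$seed, regime = NULL) {
  validate_dgp_config(config)
  if (is.null(regime)) {
    run_dgp(config, n_patients, seed, mode = "observational")$cohort
  } else {
    run_dgp(config, n_patients, seed, mode = "intervention",
            regime = regime)$cohort
  }
}

#' @export
print.long_cohort <- function(x, ...) {
  np <- length(unique(x$patient_id))
  cat(sprintf("<long_cohort> %d patients, %d person-days, horizon %d\n",
              np, nrow(x), attr(x, "horizon")))
  cat(sprintf("  deaths %d, lost to follow-up %d, ever treated %d, ever hypoxic %d\n",
              sum(x$Y), sum(x$C),
              length(unique(x$patient_id[x$A == 1])),
              length(unique(x$patient_id[x$hypoxia == 1]))))
  NextMethod()
}

#' Counterfactual 28-day mortality risk by Monte Carlo
#'
#' Simulates the configured process in the hypothetical world of the target
#' trial: treatment each day is forced to the regime's assignment and loss to
#' follow-up is abolished, so every patient is observed to death or the end
#' of the horizon.  Returns the fraction dead by the horizon with its
#' binomial Monte-Carlo standard error.
#'
#' @param config A [dgp_config()].
#' @param regime A [regime()].
#' @param n_mc Number of simulated patients.
#' @param seed Seed for the Monte-Carlo draw (defaults to the config seed).
#' @return A `cf_risk` object: list with `risk`, `mc_se`, `n_mc`.
#' @examples
#' counterfactual_risk_mc(discrete_dgp_config(), regime("never"), n_mc = 5000)
#' @export
counterfactual_risk_mc <- function(config, regime, n_mc = 100000L,
                                   seed = config$seed) {
  validate_dgp_config(config)
  stopifnot(n_mc >= 1)
  res <- run_dgp(config, as.integer(n_mc), seed, mode = "intervention",
                 regime = regime, keep_rows = FALSE)
  p <- mean(res$died)
  structure(list(risk = p, mc_se = sqrt(p * (1 - p) / n_mc),
                 n_mc = as.integer(n_mc)),
            class = "cf_risk")
}

#' @export
print.cf_risk <- function(x, ...) {
  cat(sprintf("counterfactual risk %.4f (MC se %.4f, n = %d)\n",
              x$risk, x$mc_se, x$n_mc))
  invisible(x)
}
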