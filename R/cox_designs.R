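# The ten "model-first" study designs: point-treatment Cox models anchored
# at the day severe-hypoxia criteria are met (designs A-I, with varying
# exposure windows, exclusions, and censoring-at-treatment rules) and a
# time-varying Cox model from admission (design J).  Run against cohorts
# with known counterfactual truth these designs exhibit the classic
# immortal-time, exclusion, and feedback biases.

design_table <- function() {
  data.frame(
    design_id = LETTERS[1:10],
    exposure_window = c("any", "1", "1", "1", "1", "5", "5", "5", "5",
                        "time_varying"),
    exclude_deaths_in_window = c(FALSE, FALSE, TRUE, TRUE, FALSE,
                                 FALSE, TRUE, TRUE, FALSE, FALSE),
    exclude_pretreated = c(FALSE, FALSE, FALSE, TRUE, TRUE,
                           FALSE, FALSE, TRUE, TRUE, FALSE),
    post_window_treated_handling = c("control", "control", "control",
                                     "control", "censor_at_treatment",
                                     "control", "control", "control",
                                     "censor_at_treatment", "control"),
    time_zero = c(rep("hypoxia", 9), "admission"),
    stringsAsFactors = FALSE)
}

#' Specification of one model-first study design
#'
#' Machine-readable encoding of one of the ten study designs (A-J): the
#' exposure window relative to the day hypoxia criteria are met (`any`
#' treatment during hospitalization, up to 1 or 5 days after hypoxia, or
#' time-varying from admission), whether patients dying within the window or
#' treated before hypoxia are excluded, how patients treated after the
#' window are handled (kept as controls or censored at treatment), and the
#' time origin.
#'
#' @param design_id One of `"A"`..`"J"`.
#' @return A `cox_design_spec`.
#' @examples
#' cox_design_spec("A")
#' @export
cox_design_spec <- function(design_id) {
  tab <- design_table()
  i <- match(toupper(design_id), tab$design_id)
  if (is.na(i)) stop("design_id must be one of A..J", call. = FALSE)
  structure(as.list(tab[i, ]), class = "cox_design_spec")
}

#' @export
print.cox_design_spec <- function(x, ...) {
  cat(sprintf("<cox_design_spec %s> window %s, excl. deaths-in-window %s, excl. pretreated %s, post-window %s, time zero %s\n",
              x$design_id, x$exposure_window, x$exclude_deaths_in_window,
              x$exclude_pretreated, x$post_window_treated_handling,
              x$time_zero))
  invisible(x)
}

# per-patient summary used by the point-treatment designs
patient_summary <- function(cohort) {
  sp <- split(seq_len(nrow(cohort)), cohort$patient_id)
  first <- vapply(sp, `[`, integer(1), 1L)
  out <- data.frame(
    patient_id = cohort$patient_id[first],
    age = cohort$age[first], sex = cohort$sex[first],
    comorb = cohort$comorb[first])
  out$t_star <- vapply(sp, function(ix) {
    h <- which(cohort$hypoxia[ix] == 1L)
    if (length(h)) cohort$day[ix][h[1]] else NA_integer_
  }, integer(1))
  out$first_treat <- vapply(sp, function(ix) {
    a <- which(cohort$A[ix] == 1L)
    if (length(a)) cohort$day[ix][a[1]] else NA_integer_
  }, integer(1))
  out$death_day <- vapply(sp, function(ix) {
    d <- which(cohort$Y[ix] == 1L)
    if (length(d)) cohort$day[ix][d[1]] else NA_integer_
  }, integer(1))
  out$last_day <- vapply(sp, function(ix) max(cohort$day[ix]), integer(1))
  # severity and measurement on the day hypoxia is first met ("day zero"
  # time-varying adjustment values)
  out$sev0 <- vapply(sp, function(ix) {
    h <- which(cohort$hypoxia[ix] == 1L)
    if (length(h)) cohort$severity[ix][h[1]] else NA_real_
  }, numeric(1))
  out
}

#' Construct the analysis data set for one point-treatment design
#'
#' Restricts to patients meeting hypoxia criteria, anchors time at the first
#' hypoxic day, classifies exposure by the design's window, applies its
#' exclusion and censoring-at-treatment rules, and returns one survival
#' record per retained patient together with an exclusion log.
#'
#' @param cohort A `long_cohort`.
#' @param spec A [cox_design_spec()] with `time_zero = "hypoxia"`.
#' @return A data.frame of survival records (`time`, `event`, `exposed`,
#'   covariates) with attribute `exclusions` (named counts).
#' @export
construct_design_dataset <- function(cohort, spec) {
  stopifnot(inherits(spec, "cox_design_spec"))
  if (spec$time_zero != "hypoxia") {
    stop("design ", spec$design_id, " is time-varying; use expand_time_varying()",
         call. = FALSE)
  }
  ps <- patient_summary(cohort)
  excl <- c(no_hypoxia = sum(is.na(ps$t_star)))
  ps <- ps[!is.na(ps$t_star), , drop = FALSE]

  if (spec$exclude_pretreated) {
    pre <- !is.na(ps$first_treat) & ps$first_treat < ps$t_star
    excl <- c(excl, pretreated = sum(pre))
    ps <- ps[!pre, , drop = FALSE]
  }

  win_end <- switch(spec$exposure_window,
                    any = rep(Inf, nrow(ps)),
                    `1` = ps$t_star + 1L, `5` = ps$t_star + 5L)
  exposed <- !is.na(ps$first_treat) & ps$first_treat <= win_end

  if (spec$exclude_deaths_in_window) {
    died_in <- !is.na(ps$death_day) & ps$death_day <= win_end
    excl <- c(excl, died_in_window = sum(died_in))
    ps <- ps[!died_in, , drop = FALSE]
    exposed <- exposed[!died_in]
    win_end <- win_end[!died_in]
  }

  # follow-up from hypoxia; deaths during day d count at d - t* + 1
  time <- ifelse(!is.na(ps$death_day), ps$death_day - ps$t_star + 1L,
                 ps$last_day - ps$t_star + 1L)
  event <- as.integer(!is.na(ps$death_day))
  if (spec$post_window_treated_handling == "censor_at_treatment") {
    late <- !exposed & !is.na(ps$first_treat) & ps$first_treat > win_end
    time[late] <- ps$first_treat[late] - ps$t_star[late] + 1L
    event[late] <- 0L
  }
  keep <- time > 0
  rec <- data.frame(patient_id = ps$patient_id, time = time, event = event,
                    exposed = as.integer(exposed),
                    age = ps$age, sex = ps$sex, comorb = ps$comorb,
                    sev0 = ps$sev0)[keep, , drop = FALSE]
  attr(rec, "exclusions") <- excl
  attr(rec, "design_id") <- spec$design_id
  rec
}

#' Counting-process expansion for the time-varying Cox model (design J)
#'
#' One `(start, stop]` interval per person-day from admission, carrying the
#' day's treatment indicator and time-varying covariates.  By default
#' exposure is the current-day treatment indicator; `ever_exposed = TRUE`
#' switches to an ever-treated coding.
#'
#' @param cohort A `long_cohort`.
#' @param ever_exposed Code exposure as ever-treated-so-far instead of
#'   current-day treatment.
#' @return A counting-process data.frame (`start`, `stop`, `event`,
#'   `exposed`, covariates).
#' @export
expand_time_varying <- function(cohort, ever_exposed = FALSE) {
  n <- nrow(cohort)
  id <- cohort$patient_id
  newp <- c(TRUE, id[-1L] != id[-n])
  expo <- if (ever_exposed) {
    as.integer(grp_cumsum(cohort$A, newp) > 0L)
  } else cohort$A
  out <- data.frame(patient_id = id, start = cohort$day,
                    stop = cohort$day + 1L, event = cohort$Y,
                    exposed = expo, age = cohort$age, sex = cohort$sex,
                    comorb = cohort$comorb, severity = cohort$severity,
                    hypoxia = cohort$hypoxia)
  if (!is.null(cohort$measured)) out$measured <- cohort$measured
  out
}

#' Cox proportional-hazards fit for an exposure effect
#'
#' Thin wrapper over [survival::coxph()] reporting the exposure hazard
#' ratio with its Wald confidence interval.  Efron tie handling by default
#' (daily binning produces heavily tied event times).  Non-convergence and
#' apparent complete separation are reported distinctly.
#'
#' @param records Survival records from [construct_design_dataset()] (or a
#'   counting-process frame from [expand_time_varying()]).
#' @param covariates Character vector of adjustment columns.
#' @param ties `"efron"` or `"breslow"`.
#' @return A `cox_fit`: list with `hr`, `ci_low`, `ci_high`, `coef`, `se`,
#'   `n`, `events`, `status`.
#' @export
fit_cox <- function(records, covariates = c("age", "sex", "comorb", "sev0"),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(records$event) < 1) stop("no events in records", call. = FALSE)
  covariates <- intersect(covariates, names(records))
  keep <- covariates[vapply(covariates,
                            function(v) stats::sd(records[[v]]) > 0, logical(1))]
  surv <- if ("start" %in% names(records)) "Surv(start, stop, event)"
          else "Surv(time, event)"
  fml <- stats::reformulate(c("exposed", keep), response = surv)
  status <- "ok"
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = ties),
    warning = function(w) {
      status <<- if (grepl("infinite|beta may be infinite", conditionMessage(w)))
        "possible_separation" else "non_convergence"
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  b <- co["exposed", "coef"]; se <- co["exposed", "se(coef)"]
  structure(list(hr = exp(b), ci_low = exp(b - 1.96 * se),
                 ci_high = exp(b + 1.96 * se), coef = b, se = se,
                 n = fit$n, events = fit$nevent, status = status,
                 fit = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("HR %.3f (95%% CI %.3f-%.3f), n = %d, events = %d%s\n",
              x$hr, x$ci_low, x$ci_high, x$n, x$events,
              if (x$status != "ok") paste0(" [", x$status, "]") else ""))
  invisible(x)
}

#' Fit all ten model-first designs on one cohort
#'
#' Applies [construct_design_dataset()] (A-I) or [expand_time_varying()] (J)
#' and [fit_cox()] per design and collects the hazard ratios into a forest
#' table.  Per-design failures are recorded and the run continues.
#'
#' @param cohort A `long_cohort`.
#' @param designs Which designs to run.
#' @param ties Tie handling passed to [fit_cox()].
#' @return A `design_forest` data.frame: `design`, `hr`, `ci_low`,
#'   `ci_high`, `n`, `events`, `excluded`, `status`.
#' @examples
#' coh <- simulate_cohort(dgp_config(n_patients = 400, seed = 3))
#' run_all_designs(coh, designs = c("A", "B", "J"))
#' @export
run_all_designs <- function(cohort, designs = LETTERS[1:10],
                            ties = "efron") {
  res <- lapply(designs, function(dd) {
    spec <- cox_design_spec(dd)
    out <- tryCatch({
      if (spec$time_zero == "admission") {
        rec <- expand_time_varying(cohort)
        fit <- fit_cox(rec, covariates = c("age", "sex", "comorb",
                                           "severity", "hypoxia", "measured"),
                       ties = ties)
        excl <- 0L
      } else {
        rec <- construct_design_dataset(cohort, spec)
        fit <- fit_cox(rec, ties = ties)
        excl <- sum(attr(rec, "exclusions"))
      }
      data.frame(design = dd, hr = fit$hr, ci_low = fit$ci_low,
                 ci_high = fit$ci_high, n = fit$n, events = fit$events,
                 excluded = excl, status = fit$status)
    }, error = function(e) {
      data.frame(design = dd, hr = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, n = NA_integer_, events = NA_integer_,
                 excluded = NA_integer_, status = conditionMessage(e))
    })
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("design_forest", "data.frame")
  out
}

#' @export
print.design_forest <- function(x, ...) {
  cat("Model-first Cox designs (exposure hazard ratios)\n")
  y <- as.data.frame(x)
  y$hr <- round(y$hr, 3); y$ci_low <- round(y$ci_low, 3)
  y$ci_high <- round(y$ci_high, 3)
  print(y)
  invisible(x)
}
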