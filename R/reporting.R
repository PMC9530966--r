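# Descriptive tables, effect-measure conversion, cohort/config IO, and
# experiment orchestration.

fmt_count_pct <- function(x, n) {
  if (n == 0L) return("0")
  pct <- round(100 * x / n)
  if (x > 0 && pct == 0) sprintf("%d (<1)", x) else sprintf("%d (%d)", x, pct)
}

fmt_med_iqr <- function(v, digits = 1) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
  sprintf("%.*f (%.*f-%.*f)", digits, q[2], digits, q[1], digits, q[3])
}

#' Descriptive table for a cohort, stratified by any corticosteroid exposure
#'
#' Counts with integer-rounded percents (positive values rounding to zero
#' shown as `<1`) and median (IQR) for continuous covariates, overall and in
#' never- versus ever-treated strata (any treated day during follow-up).
#'
#' @param cohort A `long_cohort`.
#' @return A `descriptive_table` data.frame: characteristic, overall,
#'   never-treated, ever-treated.
#' @examples
#' describe_cohort(simulate_cohort(dgp_config(n_patients = 300, seed = 2)))
#' @export
describe_cohort <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  sp <- split(seq_len(nrow(cohort)), cohort$patient_id)
  first <- vapply(sp, `[`, integer(1), 1L)
  base <- data.frame(age = cohort$age[first], sex = cohort$sex[first],
                     comorb = cohort$comorb[first])
  base$ever_treat <- vapply(sp, function(ix) any(cohort$A[ix] == 1L), logical(1))
  base$ever_hyp <- vapply(sp, function(ix) any(cohort$hypoxia[ix] == 1L),
                          logical(1))
  base$died <- vapply(sp, function(ix) any(cohort$Y[ix] == 1L), logical(1))

  strata <- list(overall = rep(TRUE, nrow(base)),
                 never = !base$ever_treat, ever = base$ever_treat)
  cnt <- function(flag) vapply(strata, function(s) {
    n <- sum(s)
    if (n == 0L) return("0")
    fmt_count_pct(sum(flag & s), n)
  }, character(1))
  med <- function(v) vapply(strata, function(s) {
    if (!any(s)) return("-")
    fmt_med_iqr(v[s])
  }, character(1))

  rows <- rbind(
    c("N", vapply(strata, function(s) as.character(sum(s)), character(1))),
    c("Age, median (IQR), SD units", med(base$age)),
    c("Male sex", cnt(base$sex == 1L)),
    c("Comorbidity", cnt(base$comorb == 1L)),
    c("Ever severe hypoxia", cnt(base$ever_hyp)),
    c("Outcome: 28-d mortality", cnt(base$died)))
  out <- data.frame(characteristic = rows[, 1], overall = rows[, 2],
                    never_treated = rows[, 3], ever_treated = rows[, 4],
                    stringsAsFactors = FALSE)
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' @export
print.descriptive_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Odds ratio from two risks
#'
#' `[p_treat/(1-p_treat)] / [p_control/(1-p_control)]`.
#'
#' @param p_treat,p_control Risks in (0, 1).
#' @return The odds ratio.
#' @examples
#' rates_to_or(0.257, 0.322)  # ~0.73
#' @export
rates_to_or <- function(p_treat, p_control) {
  stopifnot(all(p_treat > 0 & p_treat < 1), all(p_control > 0 & p_control < 1))
  (p_treat / (1 - p_treat)) / (p_control / (1 - p_control))
}

# ---- cohort and config IO --------------------------------------------------

#' Write / read a person-day cohort as delimited text
#'
#' One row per patient-day; columns `patient_id, day, age, sex, comorb,
#' severity, hypoxia[, measured], A, Y, C[, .w]`.  `read_cohort` validates
#' the person-day contract (sorted, consecutive days, absorbing death).
#'
#' @param cohort A `long_cohort`.
#' @param path File path.
#' @return `read_cohort` returns a `long_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$horizon <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param horizon Follow-up horizon; defaults to `max(day) + 1`.
#' @param treat_window Days a treated day keeps shifting the death hazard.
#' @export
read_cohort <- function(path, horizon = NULL, treat_window = 6L) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "A", "Y", "C", "hypoxia")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x <- x[order(x$patient_id, x$day), , drop = FALSE]
  validate_cohort(x)
  attr(x, "horizon") <- horizon %||% (max(x$day) + 1L)
  attr(x, "treat_window") <- treat_window
  class(x) <- c("long_cohort", "data.frame")
  x
}

validate_cohort <- function(x) {
  sp <- split(seq_len(nrow(x)), x$patient_id)
  for (ix in sp) {
    d <- x$day[ix]
    if (any(diff(d) != 1L)) stop("days not consecutive within a patient",
                                 call. = FALSE)
    ev <- x$Y[ix] + x$C[ix]
    if (any(x$Y[ix] == 1L & x$C[ix] == 1L))
      stop("death and censoring on the same row", call. = FALSE)
    if (any(ev[-length(ev)] == 1L))
      stop("rows after an absorbing event", call. = FALSE)
  }
  invisible(x)
}

#' Write / read a generating-process configuration as YAML
#'
#' @param config A [dgp_config()].
#' @param path File path.
#' @export
write_dgp_config <- function(config, path) {
  stopifnot(inherits(config, "dgp_config"))
  as_plain <- function(x) {
    if (is.list(x)) lapply(x, as_plain)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(as_plain(unclass(config)), path)
  invisible(path)
}

#' @rdname write_dgp_config
#' @export
read_dgp_config <- function(path) {
  raw <- yaml::read_yaml(path)
  renumber <- function(x) {
    if (!is.list(x)) return(x)
    if (length(x) && all(vapply(x, function(e) is.numeric(e) && length(e) == 1,
                                logical(1))) && !is.null(names(x))) {
      return(unlist(x))
    }
    lapply(x, renumber)
  }
  args <- renumber(raw)
  # baseline_coefs stays a list even when all-scalar
  if (!is.null(raw$baseline_coefs)) {
    args$baseline_coefs <- lapply(raw$baseline_coefs,
                                  function(e) unlist(e, use.names = TRUE))
  }
  do.call(dgp_config, args[names(args) %in% names(formals(dgp_config))])
}

# ---- experiment orchestration ----------------------------------------------

#' Run a replicated simulation experiment
#'
#' Orchestrates simulate, estimate, and model-first stages over replicates
#' of one generating process, benchmarks against a Monte-Carlo truth run,
#' and writes a reproducible report bundle (`results/`, `logs/`) of
#' delimited tables and JSON summaries.
#'
#' @param config A list (or path to a YAML file) with sections: `dgp`
#'   (arguments of [dgp_config()], or `discrete: true` for
#'   [discrete_dgp_config()]), `replicates`, `seed`, optional `estimators`
#'   (character subset of sdr/gcomp/ipw), `v_folds`, `designs` (character
#'   vector), `truth_n_mc`.
#' @param out_dir Output directory for the report bundle, or `NULL` to skip
#'   writing.
#' @return Invisibly, a list with per-replicate estimates, design fits, the
#'   truth values, and summaries.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$dgp)) {
    stop("experiment config lacks a 'dgp' section", call. = FALSE)
  }
  reps <- config$replicates %||% 1L
  seed <- config$seed %||% 1L
  methods <- config$estimators %||% "sdr"
  v_folds <- config$v_folds %||% 2L
  designs <- config$designs %||% character(0)
  t0 <- proc.time()[["elapsed"]]

  dgp_args <- config$dgp
  discrete <- isTRUE(dgp_args$discrete)
  dgp_args$discrete <- NULL
  dgp_args <- lapply(dgp_args, function(e) {
    if (is.list(e) && all(vapply(e, is.numeric, logical(1)))) unlist(e) else e
  })
  cfg <- if (discrete) do.call(discrete_dgp_config, dgp_args)
         else do.call(dgp_config, dgp_args)

  truth <- list(
    dynamic = counterfactual_risk_mc(cfg, regime("dynamic"),
                                     n_mc = config$truth_n_mc %||% 100000L,
                                     seed = seed + 777L),
    never = counterfactual_risk_mc(cfg, regime("never"),
                                   n_mc = config$truth_n_mc %||% 100000L,
                                   seed = seed + 777L))
  rd_true <- truth$dynamic$risk - truth$never$risk

  est_rows <- list(); des_rows <- list(); errors <- list()
  for (r in seq_len(reps)) {
    res <- tryCatch({
      coh <- simulate_cohort(cfg, seed = seed + r)
      er <- lapply(methods, function(m) {
        em <- emulate_trial(coh, method = m, v_folds = v_folds)
        data.frame(replicate = r, method = m,
                   risk_dynamic = em$risk_dynamic$estimate,
                   risk_never = em$risk_never$estimate,
                   rd = em$risk_difference$estimate,
                   rd_se = em$risk_difference$se,
                   rd_ci_low = em$risk_difference$ci_low,
                   rd_ci_high = em$risk_difference$ci_high)
      })
      dr <- if (length(designs)) {
        cbind(replicate = r, as.data.frame(run_all_designs(coh, designs)))
      }
      list(est = do.call(rbind, er), des = dr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(replicate = r,
                                                  message = conditionMessage(res))
    } else {
      est_rows[[r]] <- res$est
      des_rows[[r]] <- res$des
    }
  }
  est <- do.call(rbind, est_rows)
  des <- do.call(rbind, des_rows)

  summ <- NULL
  if (!is.null(est)) {
    summ <- do.call(rbind, lapply(split(est, est$method), function(g) {
      data.frame(method = g$method[1], replicates = nrow(g),
                 mean_rd = mean(g$rd), bias_rd = mean(g$rd) - rd_true,
                 sd_rd = stats::sd(g$rd),
                 coverage = mean(g$rd_ci_low <= rd_true &
                                   rd_true <= g$rd_ci_high))
    }))
    rownames(summ) <- NULL
  }
  bundle <- list(config = config, truth = list(risk_dynamic = truth$dynamic$risk,
                                               risk_never = truth$never$risk,
                                               rd = rd_true),
                 estimates = est, designs = des, summary = summ,
                 errors = if (length(errors)) do.call(rbind, errors),
                 elapsed_s = proc.time()[["elapsed"]] - t0)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "results"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "logs"), recursive = TRUE,
               showWarnings = FALSE)
    cfg_path <- file.path(out_dir, "results", "config.yaml")
    yaml::write_yaml(config, cfg_path)
    if (!is.null(est)) utils::write.csv(est, file.path(out_dir, "results",
                                                       "estimates.csv"),
                                        row.names = FALSE)
    if (!is.null(des)) utils::write.csv(des, file.path(out_dir, "results",
                                                       "designs.csv"),
                                        row.names = FALSE)
    jsonlite::write_json(list(truth = bundle$truth, summary = summ),
                         file.path(out_dir, "results", "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(c(
      sprintf("seed: %d", seed),
      sprintf("replicates: %d", reps),
      sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
      sprintf("elapsed_s: %.1f", bundle$elapsed_s),
      sprintf("R: %s; ttesim: %s", R.version.string,
              as.character(utils::packageVersion("ttesim")))),
      file.path(out_dir, "logs", "run.log"))
  }
  invisible(bundle)
}
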