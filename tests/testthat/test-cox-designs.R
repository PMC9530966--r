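# hand-built long cohort for the design-construction rules
mk_cohort <- function(df) {
  df <- df[order(df$patient_id, df$day), ]
  rownames(df) <- NULL
  attr(df, "horizon") <- 28L
  attr(df, "treat_window") <- 6L
  class(df) <- c("long_cohort", "data.frame")
  df
}

pt <- function(id, hyp_day = NA, treat_days = integer(0), death_day = NA,
               last_day = 27L) {
  end <- min(last_day, if (!is.na(death_day)) death_day else last_day)
  days <- 0:end
  data.frame(patient_id = id, day = days, age = 0, sex = 0L, comorb = 0L,
             severity = as.numeric(!is.na(hyp_day) & days >= hyp_day),
             hypoxia = as.integer(!is.na(hyp_day) & days >= hyp_day),
             A = as.integer(days %in% treat_days),
             Y = as.integer(!is.na(death_day) & days == death_day),
             C = 0L)
}

test_that("design specs encode the ten study designs", {
  expect_error(cox_design_spec("K"), "A..J")
  a <- cox_design_spec("A")
  expect_equal(a$exposure_window, "any")
  expect_false(a$exclude_deaths_in_window)
  j <- cox_design_spec("J")
  expect_equal(j$time_zero, "admission")
  expect_equal(cox_design_spec("E")$post_window_treated_handling,
               "censor_at_treatment")
  expect_true(cox_design_spec("H")$exclude_pretreated)
})

test_that("exposure windows and exclusions follow the design rules", {
  coh <- mk_cohort(rbind(
    pt(1, hyp_day = 2, treat_days = 10:12),            # late treated
    pt(2, hyp_day = 3, death_day = 5),                 # died 2 d after hypoxia
    pt(3, hyp_day = 4, treat_days = 3:8),              # treated before hypoxia
    pt(4, hyp_day = 2, treat_days = 2:7),              # on-time treated
    pt(5)))                                            # never hypoxic
  # A: any treatment ever counts as exposed
  recA <- construct_design_dataset(coh, cox_design_spec("A"))
  expect_equal(recA$exposed[recA$patient_id == 1], 1L)
  expect_equal(attr(recA, "exclusions")[["no_hypoxia"]], 1)
  # B: only treatment up to 1 day after hypoxia counts
  recB <- construct_design_dataset(coh, cox_design_spec("B"))
  expect_equal(recB$exposed[recB$patient_id == 1], 0L)
  expect_equal(recB$exposed[recB$patient_id == 4], 1L)
  # G: deaths within the 5-day window are excluded and logged
  recG <- construct_design_dataset(coh, cox_design_spec("G"))
  expect_false(2 %in% recG$patient_id)
  expect_equal(attr(recG, "exclusions")[["died_in_window"]], 1)
  # H: pre-hypoxia treatment excludes the patient
  recH <- construct_design_dataset(coh, cox_design_spec("H"))
  expect_false(3 %in% recH$patient_id)
  expect_equal(attr(recH, "exclusions")[["pretreated"]], 1)
  # E: treated after the 1-day window is censored at treatment receipt
  recE <- construct_design_dataset(coh, cox_design_spec("E"))
  r1 <- recE[recE$patient_id == 1, ]
  expect_equal(r1$event, 0L)
  expect_equal(r1$time, 10 - 2 + 1)
})

test_that("patients in = analyzed + excluded for every point-treatment design", {
  coh <- simulate_cohort(dgp_config(n_patients = 600, seed = 12))
  n_all <- length(unique(coh$patient_id))
  for (dd in LETTERS[1:9]) {
    rec <- construct_design_dataset(coh, cox_design_spec(dd))
    expect_equal(nrow(rec) + sum(attr(rec, "exclusions")), n_all)
  }
})

test_that("counting-process expansion transcribes person-days", {
  coh <- mk_cohort(rbind(
    pt(1, last_day = 2),
    pt(2, hyp_day = 0, treat_days = 2:4, last_day = 5)))
  cp <- expand_time_varying(coh)
  expect_equal(nrow(cp), nrow(coh))
  expect_equal(cp$exposed[cp$patient_id == 1], rep(0L, 3))
  expect_equal(cp$exposed[cp$patient_id == 2], c(0L, 0L, 1L, 1L, 1L, 0L))
  ever <- expand_time_varying(coh, ever_exposed = TRUE)
  expect_equal(ever$exposed[ever$patient_id == 2], c(0L, 0L, 1L, 1L, 1L, 1L))
  expect_true(all(cp$stop == cp$start + 1L))
})

test_that("Cox fits maximise the partial likelihood", {
  rec <- data.frame(patient_id = 1:8,
                    time = c(2, 4, 5, 7, 9, 11, 12, 14),
                    event = c(1, 1, 0, 1, 1, 0, 1, 0),
                    exposed = c(1, 0, 1, 1, 0, 0, 1, 0))
  fit <- fit_cox(rec, covariates = character(0), ties = "breslow")
  # independent partial likelihood over the risk sets (distinct times)
  pl <- function(b) {
    ll <- 0
    for (i in which(rec$event == 1)) {
      rs <- rec$time >= rec$time[i]
      ll <- ll + b * rec$exposed[i] - log(sum(exp(b * rec$exposed[rs])))
    }
    -ll
  }
  bhat <- stats::optimize(pl, c(-5, 5))$minimum
  expect_equal(fit$coef, bhat, tolerance = 1e-5)
})

test_that("Cox fits recover a known hazard ratio and the null", {
  set.seed(31)
  hits <- sapply(1:50, function(r) {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, rate = 0.1 * 2^x)
    cens <- runif(n, 0, 15)
    rec <- data.frame(time = pmin(t_ev, cens),
                      event = as.integer(t_ev <= cens), exposed = x)
    f <- fit_cox(rec, covariates = character(0))
    f$ci_low <= 2 & 2 <= f$ci_high
  })
  expect_gte(mean(hits), 0.9)
  # identical groups: HR near 1, CI covering 1
  set.seed(8)
  n <- 3000
  rec0 <- data.frame(time = rexp(n, 0.1), event = 1L,
                     exposed = rbinom(n, 1, 0.5))
  f0 <- fit_cox(rec0, covariates = character(0))
  expect_true(f0$ci_low <= 1 & 1 <= f0$ci_high)
  expect_equal(f0$hr, 1, tolerance = 0.15)
  expect_error(fit_cox(data.frame(time = 1:3, event = 0L, exposed = 0:2)),
               "no events")
})

test_that("the forest run covers all designs and tolerates failures", {
  coh <- simulate_cohort(dgp_config(n_patients = 800, seed = 21))
  f <- run_all_designs(coh)
  expect_s3_class(f, "design_forest")
  expect_equal(f$design, LETTERS[1:10])
  expect_true(all(is.finite(f$hr[f$status == "ok"])))
  expect_true(sum(f$status == "ok") >= 8)
})
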