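test_that("estimators reproduce the exact g-formula on the enumerated law", {
  cfg <- tiny_cfg()
  ec <- enumerate_cohort(cfg)
  for (kind in c("dynamic", "never")) {
    rg <- regime(kind)
    truth <- enumerate_truth(cfg, rg)
    nu <- fit_nuisances(ec, rg, v_folds = 1, learners = sat_learner(),
                        trim = 1e-9)
    g <- gcomp_estimate(ec, rg, nuisances = nu, learners = sat_learner())
    s <- sdr_estimate(ec, rg, nuisances = nu, learners = sat_learner())
    expect_equal(g$estimate, truth, tolerance = 1e-8)
    expect_equal(s$estimate, truth, tolerance = 1e-8)
  }
})

test_that("treatment-mechanism fits recover a known randomized propensity", {
  cfg <- tiny_cfg(treat_propensity_coefs = c(intercept = 0))
  coh <- simulate_cohort(cfg, n_patients = 2000)
  nu <- fit_nuisances(coh, regime("never"), v_folds = 2)
  # d = 0 everywhere, so gA estimates P(A = 0) = 0.5
  se <- sqrt(0.25 / nrow(coh))
  expect_lt(abs(mean(nu$gA) - 0.5), 3 * se)
})

test_that("censoring fits honour structure: no censoring means gC = 1", {
  cfg <- tiny_cfg(discharge_hazard_coefs = c(intercept = -Inf))
  coh <- simulate_cohort(cfg, n_patients = 300)
  expect_equal(sum(coh$C), 0L)
  nu <- fit_nuisances(coh, regime("never"), v_folds = 1)
  expect_true(all(nu$gC == 1))
})

test_that("fitted probabilities respect the trim bounds", {
  coh <- simulate_cohort(tiny_cfg(), n_patients = 500)
  nu <- fit_nuisances(coh, regime("dynamic"), v_folds = 1, trim = 0.2)
  expect_true(all(nu$gA >= 0.2 & nu$gA <= 0.8))
  expect_true(all(nu$gC[coh$Y == 0] >= 0.2))
})

test_that("IPW reduces to the Horvitz-Thompson mean on a known fixture", {
  coh <- ht_fixture()
  cfg <- dgp_config(horizon = 1,
                    treat_propensity_coefs = c(intercept = 0),
                    discharge_hazard_coefs = c(intercept = -Inf))
  nu <- fit_nuisances(coh, regime("never"), v_folds = 1, truth = cfg)
  est <- ipw_estimate(coh, regime("never"), nuisances = nu, weight_cap_q = 1)
  # untreated deaths: patients 3 and 8; each weighted 1/0.5 over n = 10
  expect_equal(est$estimate, (1 / 0.5 + 1 / 0.5) / 10)
})

test_that("IPW with unit weights equals the raw mortality proportion", {
  cfg <- tiny_cfg(treat_propensity_coefs = c(intercept = -Inf),
                  discharge_hazard_coefs = c(intercept = -Inf))
  coh <- simulate_cohort(cfg, n_patients = 400)
  nu <- fit_nuisances(coh, regime("never"), v_folds = 1, truth = cfg,
                      trim = 1e-12)
  est <- ipw_estimate(coh, regime("never"), nuisances = nu, weight_cap_q = 1)
  expect_equal(est$estimate, mean(patient_flag(coh, "Y")), tolerance = 1e-10)
})

test_that("point-treatment g-computation marginalises the outcome model", {
  coh <- ht_fixture()
  nu <- fit_nuisances(coh, regime("never"), v_folds = 1,
                      learners = sat_learner(), trim = 1e-9)
  g <- gcomp_estimate(coh, regime("never"), nuisances = nu,
                      learners = sat_learner())
  # E_S[E[Y | S, A = 0]]: severity 0 cell mean 1/2, severity 1 cell mean 1/3
  expect_equal(g$estimate, 0.5 * (1 / 2) + 0.5 * (1 / 3), tolerance = 1e-10)
})

test_that("a null effect yields a null estimated risk difference", {
  cfg <- tiny_cfg(treatment_effect = 0)
  coh <- simulate_cohort(cfg, n_patients = 3000)
  em <- emulate_trial(coh, method = "gcomp", v_folds = 1)
  expect_lt(abs(em$risk_difference$estimate), 3 * em$risk_difference$se)
})

test_that("contrasts reproduce the printed effect-measure arithmetic", {
  # crafted estimates carrying the emulation's printed counterfactual risks
  mk <- function(p, lab) {
    structure(list(estimand_label = lab, method = "sdr", estimate = p,
                   se = 0.006, ci_low = p - 0.012, ci_high = p + 0.012,
                   n = 3298L, folds = 1L, eif = NULL, pw = rep(1, 10),
                   scale = "risk", warnings = character(0)),
              class = "tte_estimate")
  }
  trt <- mk(0.257, "risk_dynamic"); ctl <- mk(0.322, "risk_never")
  expect_equal(round(contrast(trt, ctl, "odds_ratio")$estimate, 2), 0.73)
  expect_equal(contrast(trt, ctl, "difference")$estimate, -0.065)
  eq <- contrast(mk(0.3, "risk_dynamic"), mk(0.3, "risk_never"), "ratio")
  expect_equal(eq$estimate, 1)
  expect_equal(contrast(mk(0.3, "a"), mk(0.3, "b"), "difference")$estimate, 0)
  expect_equal(contrast(mk(0.5, "a"), mk(0.25, "b"), "odds_ratio")$estimate, 3)
})

test_that("estimates are invariant to row shuffling and stable in fold seed", {
  cfg <- tiny_cfg()
  coh <- simulate_cohort(cfg, n_patients = 1500)
  s1 <- sdr_estimate(coh, regime("never"), v_folds = 2, seed = 1)
  perm <- coh[sample(nrow(coh)), ]
  perm <- perm[order(perm$patient_id, perm$day), ]
  attributes(perm)[c("horizon", "treat_window", "class")] <-
    attributes(coh)[c("horizon", "treat_window", "class")]
  s2 <- sdr_estimate(perm, regime("never"), v_folds = 2, seed = 1)
  expect_equal(s1$estimate, s2$estimate, tolerance = 1e-12)
  s3 <- sdr_estimate(coh, regime("never"), v_folds = 2, seed = 99)
  expect_lt(abs(s1$estimate - s3$estimate), s1$se)
})

test_that("SDR error shrinks with sample size", {
  cfg <- tiny_cfg()
  truth <- enumerate_truth(cfg, regime("dynamic")) -
    enumerate_truth(cfg, regime("never"))
  err <- sapply(c(1000, 10000), function(n) {
    e <- sapply(1:8, function(r) {
      coh <- simulate_cohort(cfg, n_patients = n, seed = 6000 + r)
      em <- emulate_trial(coh, method = "sdr", v_folds = 2, seed = r)
      em$risk_difference$estimate - truth
    })
    sqrt(mean(e^2))
  })
  expect_lt(err[2], err[1])
})

test_that("confidence intervals attain near-nominal coverage (scaled down)", {
  cfg <- tiny_cfg()
  truth <- enumerate_truth(cfg, regime("dynamic")) -
    enumerate_truth(cfg, regime("never"))
  cover <- sapply(1:50, function(r) {
    coh <- simulate_cohort(cfg, n_patients = 2000, seed = 7000 + r)
    em <- emulate_trial(coh, method = "sdr", v_folds = 2, seed = r)
    em$risk_difference$ci_low <= truth & truth <= em$risk_difference$ci_high
  })
  expect_gte(sum(cover), 42)
})
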