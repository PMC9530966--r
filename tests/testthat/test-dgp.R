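test_that("cohorts satisfy the person-day contract", {
  coh <- simulate_cohort(dgp_config(n_patients = 400, seed = 3))
  expect_s3_class(coh, "long_cohort")
  expect_false(any(coh$Y == 1L & coh$C == 1L))
  sp <- split(seq_len(nrow(coh)), coh$patient_id)
  for (ix in sp) {
    d <- coh$day[ix]
    expect_equal(d, seq(0L, length.out = length(d)))
    ev <- coh$Y[ix] + coh$C[ix]
    if (length(ev) > 1) expect_true(all(ev[-length(ev)] == 0L))
  }
  expect_true(all(coh$day >= 0 & coh$day < attr(coh, "horizon")))
})

test_that("fixed seeds reproduce cohorts and early patients survive n growth", {
  cfg <- dgp_config(seed = 9)
  c1 <- simulate_cohort(cfg, n_patients = 300)
  c2 <- simulate_cohort(cfg, n_patients = 300)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(cfg, n_patients = 500)
  expect_identical(as.data.frame(c1),
                   as.data.frame(c3[c3$patient_id <= 300, ]))
})

test_that("forced edge-case configurations behave as required", {
  # never-treat observational world
  cfg <- dgp_config(n_patients = 200, seed = 5,
                    treat_propensity_coefs = c(intercept = -Inf))
  expect_true(all(simulate_cohort(cfg)$A == 0L))
  # no absorbing events: every patient observed the full horizon, no deaths
  cfg2 <- dgp_config(n_patients = 100, horizon = 10, seed = 5,
                     death_hazard_coefs = c(intercept = -Inf),
                     discharge_hazard_coefs = c(intercept = -Inf))
  coh2 <- simulate_cohort(cfg2)
  expect_equal(nrow(coh2), 100 * 10)
  expect_true(all(coh2$Y == 0L))
  # invalid coefficients rejected
  expect_error(dgp_config(death_hazard_coefs = c(intercept = NaN)),
               "non-finite")
})

test_that("Monte-Carlo counterfactual risk agrees with exact enumeration", {
  cfg <- tiny_cfg()
  for (kind in c("dynamic", "never")) {
    rg <- regime(kind)
    truth <- enumerate_truth(cfg, rg)
    mc <- counterfactual_risk_mc(cfg, rg, n_mc = 500000, seed = 77)
    expect_lt(abs(mc$risk - truth), 3 * mc$mc_se)
  }
})

test_that("a null treatment effect equalises regimes under Monte Carlo", {
  cfg <- tiny_cfg(treatment_effect = 0)
  m1 <- counterfactual_risk_mc(cfg, regime("dynamic"), n_mc = 100000, seed = 3)
  m0 <- counterfactual_risk_mc(cfg, regime("never"), n_mc = 100000, seed = 3)
  expect_lt(abs(m1$risk - m0$risk), 3 * sqrt(m1$mc_se^2 + m0$mc_se^2))
})

test_that("a protective effect lowers risk under the dynamic regime", {
  cfg <- dgp_config(treatment_effect = -0.5)
  m1 <- counterfactual_risk_mc(cfg, regime("dynamic"), n_mc = 200000, seed = 4)
  m0 <- counterfactual_risk_mc(cfg, regime("never"), n_mc = 200000, seed = 5)
  expect_lt(m1$risk - m0$risk, -3 * sqrt(m1$mc_se^2 + m0$mc_se^2))
})

test_that("treatment is confounded: the naive contrast misstates the effect", {
  cfg <- dgp_config()
  r1 <- counterfactual_risk_mc(cfg, regime("dynamic"), n_mc = 100000, seed = 31)
  r0 <- counterfactual_risk_mc(cfg, regime("never"), n_mc = 100000, seed = 32)
  truth_rd <- r1$risk - r0$risk
  coh <- simulate_cohort(cfg, n_patients = 10000, seed = 33)
  ever <- patient_flag(coh, "A")
  died <- patient_flag(coh, "Y")
  naive <- mean(died[ever]) - mean(died[!ever])
  se <- sqrt(var(died[ever]) / sum(ever) + var(died[!ever]) / sum(!ever) +
               r1$mc_se^2 + r0$mc_se^2)
  # treatment goes to sicker patients, pushing the naive contrast upward
  expect_gt(naive - truth_rd, 3 * se)
})
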