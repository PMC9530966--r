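test_that("glucocorticoid doses convert on the standard equivalency table", {
  expect_equal(mpred_equivalent("methylprednisolone", 40), 40)
  expect_equal(mpred_equivalent("dexamethasone", 6), 32)
  expect_equal(mpred_equivalent("hydrocortisone", 100), 20)
  expect_equal(mpred_equivalent("prednisone", 50), 40)
  expect_error(mpred_equivalent("ibuprofen", 10), "unknown drug")
  expect_error(mpred_equivalent("prednisone", -1))
})

test_that("rolling 24-hour windows flag exposed days", {
  expect_equal(derive_daily_exposure(NULL, 80, 3), c(0L, 0L, 0L))
  rec <- data.frame(timestamp = c(0, 12), drug = "methylprednisolone",
                    dose_mg = c(20, 25))
  # 45 mg within one window vs the 0.5 mg/kg * 80 kg = 40 mg threshold
  expect_equal(derive_daily_exposure(rec, 80, 3)[1], 1L)
  low <- data.frame(timestamp = 5, drug = "methylprednisolone", dose_mg = 39)
  expect_equal(derive_daily_exposure(low, 80, 3), c(0L, 0L, 0L))
  # a window can end in the next calendar day
  late <- data.frame(timestamp = 23, drug = "methylprednisolone", dose_mg = 45)
  expect_equal(derive_daily_exposure(late, 80, 3), c(1L, 1L, 0L))
  expect_error(derive_daily_exposure(
    data.frame(timestamp = -1, drug = "prednisone", dose_mg = 10), 80, 3),
    "negative")
})

test_that("adding a dose never unflags an exposed day", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    rec <- data.frame(timestamp = runif(n, 0, 96),
                      drug = sample(c("prednisone", "dexamethasone",
                                      "methylprednisolone"), n, TRUE),
                      dose_mg = runif(n, 5, 60))
    base <- derive_daily_exposure(rec, 70, 5)
    extra <- rbind(rec, data.frame(timestamp = runif(1, 0, 96),
                                   drug = "hydrocortisone", dose_mg = 100))
    expect_true(all(derive_daily_exposure(extra, 70, 5) >= base))
  }
})

test_that("severe hypoxia derives from device and saturation criteria", {
  imv <- data.frame(timestamp = 3 * 24 + 2, mode = "imv",
                    o2_flow_lpm = 0, spo2_pct = 95)
  expect_equal(derive_daily_hypoxia(imv, 5), c(0L, 0L, 0L, 1L, 0L))
  nc92 <- data.frame(timestamp = 1, mode = "nasal_cannula",
                     o2_flow_lpm = 6, spo2_pct = 92)
  expect_equal(derive_daily_hypoxia(nc92, 2)[1], 1L)
  # boundary: saturation must be strictly below 93
  nc93 <- data.frame(timestamp = 1, mode = "nasal_cannula",
                     o2_flow_lpm = 6, spo2_pct = 93)
  expect_equal(derive_daily_hypoxia(nc93, 2), c(0L, 0L))
  ra <- data.frame(timestamp = 1, mode = "room_air",
                   o2_flow_lpm = 0, spo2_pct = 85)
  expect_equal(derive_daily_hypoxia(ra, 1), 0L)
})

test_that("eligibility exclusions are logged and idempotent", {
  pts <- data.frame(patient_id = 1:6,
                    chronic_steroids = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
                    transfer_in = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
  kept <- apply_eligibility(pts)
  expect_equal(kept$patient_id, c(1, 4, 6))
  log <- attr(kept, "exclusion_log")
  expect_equal(unname(log["chronic_steroids"]), 2)
  expect_equal(unname(log["transfer_in"]), 1)
  again <- apply_eligibility(kept)
  expect_equal(again$patient_id, kept$patient_id)
  expect_error(apply_eligibility(data.frame(patient_id = 1)), "missing")
})

test_that("regimes assign treatment from the first hypoxic day", {
  dyn <- regime("dynamic")
  expect_equal(assign_regime(dyn, c(0, 0, 1, 0, 1, 0, 0, 0, 0)),
               c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L, 0L))
  expect_equal(assign_regime(dyn, rep(0, 9)), rep(0L, 9))
  expect_equal(assign_regime(regime("never"), c(0, 1, 1)), rep(0L, 3))
  # truncation at the end of follow-up
  h <- c(rep(0, 26), 1, 0)
  expect_equal(sum(assign_regime(dyn, h)), 2L)
})

test_that("a cohort simulated under a forced regime is fully adherent", {
  cfg <- tiny_cfg()
  for (kind in c("dynamic", "never")) {
    rg <- regime(kind)
    coh <- simulate_cohort(cfg, n_patients = 500, regime = rg)
    expect_true(all(coh$C == 0L))
    sp <- split(seq_len(nrow(coh)), coh$patient_id)
    ok <- vapply(sp, function(ix) {
      all(coh$A[ix] == assign_regime(rg, coh$hypoxia[ix]))
    }, logical(1))
    expect_true(all(ok))
  }
})
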