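test_that("percent formatting follows the descriptive-table conventions", {
  expect_equal(ttesim:::fmt_count_pct(699, 3298), "699 (21)")
  expect_equal(ttesim:::fmt_count_pct(574, 2875), "574 (20)")
  expect_equal(ttesim:::fmt_count_pct(125, 423), "125 (30)")
  expect_equal(ttesim:::fmt_count_pct(1, 500), "1 (<1)")
  expect_equal(ttesim:::fmt_count_pct(0, 500), "0 (0)")
})

test_that("the descriptive table stratifies by any corticosteroid exposure", {
  coh <- simulate_cohort(dgp_config(n_patients = 800, seed = 6))
  tab <- describe_cohort(coh)
  expect_s3_class(tab, "descriptive_table")
  n <- as.integer(tab[tab$characteristic == "N", -1])
  expect_equal(n[1], n[2] + n[3])  # strata sum to overall
  expect_true(any(grepl("mortality", tab$characteristic)))
  expect_error(describe_cohort(NULL), "empty")
})

test_that("risk-to-odds-ratio conversion is exact and matches contrast()", {
  expect_equal(round(rates_to_or(0.257, 0.322), 2), 0.73)
  expect_equal(rates_to_or(0.4, 0.4), 1)
  expect_equal(rates_to_or(0.5, 0.25), 3)
  expect_error(rates_to_or(0, 0.5))
  coh <- simulate_cohort(tiny_cfg(), n_patients = 1500)
  e1 <- gcomp_estimate(coh, regime("dynamic"))
  e0 <- gcomp_estimate(coh, regime("never"))
  expect_equal(contrast(e1, e0, "odds_ratio")$estimate,
               rates_to_or(e1$estimate, e0$estimate), tolerance = 1e-12)
  expect_equal(contrast(e1, e0, "difference")$estimate,
               e1$estimate - e0$estimate, tolerance = 1e-12)
})

test_that("cohort and config files round-trip through delimited text", {
  cfg <- tiny_cfg()
  coh <- simulate_cohort(cfg, n_patients = 80)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f, horizon = attr(coh, "horizon"))
  expect_equal(as.data.frame(back), as.data.frame(coh))
  fy <- tempfile(fileext = ".yaml")
  write_dgp_config(cfg, fy)
  cfg2 <- read_dgp_config(fy)
  expect_equal(cfg2$treat_propensity_coefs, cfg$treat_propensity_coefs)
  expect_equal(cfg2$severity_mode, "binary")
  expect_identical(simulate_cohort(cfg2, n_patients = 50),
                   simulate_cohort(cfg, n_patients = 50))
})

test_that("cohort files violating the person-day contract are rejected", {
  coh <- simulate_cohort(tiny_cfg(), n_patients = 30)
  bad <- as.data.frame(coh)
  bad <- bad[bad$day != 1 | bad$patient_id != bad$patient_id[nrow(bad)], ]
  f <- tempfile(fileext = ".csv")
  # drop a middle day for the last patient if it has 3 rows
  df <- as.data.frame(coh)
  long <- names(which(table(df$patient_id) == 3))[1]
  if (!is.na(long)) {
    df2 <- df[!(df$patient_id == as.integer(long) & df$day == 1), ]
    utils::write.csv(df2, f, row.names = FALSE)
    expect_error(read_cohort(f), "consecutive")
  }
})

test_that("experiments validate their schema and reproduce exactly", {
  expect_error(run_experiment(list(replicates = 1)), "dgp")
  cfgl <- list(dgp = list(discrete = TRUE, n_patients = 400),
               replicates = 2, seed = 5, estimators = "gcomp",
               v_folds = 1, designs = c("A", "B"), truth_n_mc = 20000)
  b1 <- run_experiment(cfgl)
  b2 <- run_experiment(cfgl)
  expect_identical(b1$estimates, b2$estimates)
  expect_identical(b1$designs, b2$designs)
  expect_equal(nrow(b1$estimates), 2)
  expect_true(all(c("A", "B") %in% b1$designs$design))
  expect_true(is.finite(b1$summary$coverage))
  out <- tempfile()
  run_experiment(cfgl, out_dir = out)
  expect_true(file.exists(file.path(out, "results", "estimates.csv")))
  expect_true(file.exists(file.path(out, "results", "summary.json")))
  expect_true(file.exists(file.path(out, "logs", "run.log")))
})
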