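test_that("death risk is interval risk times 10-year case fatality", {
  expect_equal(death_risk(0.15, 0.89), 0.0165, tolerance = 1e-12)
  expect_equal(round_percent(death_risk(0.15, 0.89)), 2L)
  expect_equal(death_risk(0.06, 0.84), 0.0096, tolerance = 1e-12)
  expect_equal(round_percent(death_risk(0.06, 0.84)), 1L)
  expect_equal(death_risk(0, 0.5), 0)
  expect_error(death_risk(1.2, 0.9), "risk")
})

test_that("percent rounding is half away from zero", {
  expect_equal(round_percent(c(0.0165, 0.0096, 0, 0.005, 0.0049, 0.125)),
               c(2L, 1L, 0L, 1L, 0L, 13L))
  expect_equal(round_percent(-0.015), -2L)
})

test_that("a zero-hazard curve yields an all-zero table", {
  cv <- lynchrrs:::curve_from_hazards(
    setNames(rep(0, 10), seq(25, 70, 5)), gene = "PMS2", endpoint = "EC")
  tb <- build_gene_table(cv, 0.89)
  expect_equal(nrow(tb), 9)
  expect_true(all(tb$risk == 0))
  expect_true(all(tb$death_pct == 0L))
  expect_true(all(tb$survival_pct == 89L))
})

test_that("the calibrated MLH1 endometrial table reproduces published cells", {
  tb <- build_gene_table(calibrated_curve("MLH1", "EC"), 0.89)
  cell <- function(a, b, col) tb[tb$age_from == a & tb$age_to == b, col]
  expect_equal(cell(25, 50, "risk_pct"), 15L)
  expect_equal(cell(25, 50, "death_pct"), 2L)
  expect_equal(cell(25, 70, "risk_pct"), 35L)
  expect_equal(cell(25, 70, "death_pct"), 4L)
  expect_equal(cell(40, 70, "risk_pct"), 34L)
  expect_equal(cell(60, 70, "risk_pct"), 11L)
  ## death column always equals risk x (1 - survival) before rounding
  expect_equal(tb$death_risk, tb$risk * (1 - tb$survival10), tolerance = 1e-12)
  ## internal consistency: 25-50 row composes from 25-40 and 40-50
  expect_equal(cell(25, 50, "risk"),
               compose_interval_risks(cell(25, 40, "risk"),
                                      cell(40, 50, "risk")),
               tolerance = 1e-12)
})

test_that("table builders are pure functions", {
  cv <- calibrated_curve("MSH6", "EC")
  expect_identical(build_gene_table(cv, 0.89), build_gene_table(cv, 0.89))
})

test_that("combined tables interpolate survival by the endometrial fraction", {
  tb <- build_combined_table(calibrated_curve("MLH1", "EC"),
                             calibrated_curve("MLH1", "OC"))
  cell <- function(a, b, col) tb[tb$age_from == a & tb$age_to == b, col]
  expect_equal(cell(25, 50, "survival_pct"), 88L)  # 0.84 + 0.05 * 15/21
  expect_equal(cell(25, 50, "risk_pct"), 20L)
  expect_equal(cell(25, 50, "death_pct"), 2L)

  tb2 <- build_combined_table(calibrated_curve("MSH2", "EC"),
                              calibrated_curve("MSH2", "OC"))
  expect_equal(tb2[tb2$age_from == 25 & tb2$age_to == 50, "survival_pct"], 87L)

  ## PMS2 has no risk below 50: survival cell empty, death risk zero
  tb3 <- build_combined_table(calibrated_curve("PMS2", "EC"),
                              calibrated_curve("PMS2", "OC"))
  young <- tb3[tb3$age_from == 25 & tb3$age_to == 50, ]
  expect_equal(young$risk, 0)
  expect_true(is.na(young$survival_pct))
  expect_equal(young$death_pct, 0L)
})

test_that("combined risk lies between the larger single risk and their sum", {
  for (g in c("MLH1", "MSH2", "MSH6")) {
    ec <- calibrated_curve(g, "EC")
    oc <- calibrated_curve(g, "OC")
    tb <- build_combined_table(ec, oc)
    expect_true(all(tb$risk >= pmax(tb$ec_risk, tb$oc_risk) - 1e-12))
    expect_true(all(tb$risk <= tb$ec_risk + tb$oc_risk + 1e-12))
  }
})

test_that("a supplied combined curve overrides the independence fallback", {
  ec <- calibrated_curve("MLH1", "EC")
  oc <- calibrated_curve("MLH1", "OC")
  tb <- build_combined_table(ec, oc, combined_curve = ec)
  expect_equal(tb$risk, tb$ec_risk, tolerance = 1e-12)
  expect_true(all(tb$risk_source == "combined-curve"))
})

test_that("surgery benefit equals the counterfactual interval risk", {
  b <- rrs_benefit(calibrated_curve("MSH2", "EC"), 0.89, 40, 50,
                   "hysterectomy")
  expect_equal(round_percent(b$cancers_prevented), 16L)
  expect_equal(round_percent(b$deaths_prevented), 2L)
  expect_equal(b$deaths_prevented / b$cancers_prevented, 1 - 0.89,
               tolerance = 1e-12)
  expect_lte(b$deaths_prevented, b$cancers_prevented)
  expect_error(rrs_benefit(calibrated_curve("MSH2", "EC"), 0.89, 50, 50),
               "before")
})
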