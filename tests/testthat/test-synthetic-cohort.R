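test_that("default hazards reproduce every published cumulative-risk anchor", {
  anchors <- printed_interval_risks()
  for (g in c("MLH1", "MSH2", "MSH6", "PMS2")) {
    p <- default_params(g, n = 1)
    for (ep in c("EC", "OC")) {
      a <- anchors[anchors$gene == g & anchors$endpoint == ep, ]
      for (i in seq_len(nrow(a))) {
        expect_equal(analytic_interval_risk(p, ep, 25, a$to_age[i]),
                     a$risk[i], tolerance = 1e-12,
                     label = sprintf("%s %s 25-%d", g, ep, a$to_age[i]))
      }
    }
  }
})

test_that("PMS2 has no premenopausal endometrial or ovarian hazard", {
  p <- default_params("PMS2", n = 1)
  pre <- as.character(seq(25, 45, 5))
  expect_true(all(p$ec_hazard[pre] == 0))
  expect_true(all(p$oc_hazard[pre] == 0))
  expect_gt(p$ec_hazard[["50"]], 0)
})

test_that("default parameter sets are deterministic and survival-calibrated", {
  expect_identical(default_params("MSH6", n = 5, seed = 3),
                   default_params("MSH6", n = 5, seed = 3))
  for (ep in c("EC", "OC")) {
    m <- default_params("MLH1", n = 1)$survival_model[[ep]]
    s10 <- m$cure_fraction + (1 - m$cure_fraction) * exp(-10 / m$event_time_scale)
    expect_equal(s10, m$target10, tolerance = 1e-12)
  }
})

test_that("analytic_interval_risk matches direct products and edge identities", {
  h <- rep(0, 10); h[4:5] <- 0.02  # bins 40 and 45
  p <- params_with(ec = h)
  expect_equal(analytic_interval_risk(p, "EC", 25, 50), 1 - 0.98^10,
               tolerance = 1e-12)
  p2 <- params_with(ec = 0.037)
  expect_equal(analytic_interval_risk(p2, "EC", 25, 26), 0.037)
  p0 <- params_with(ec = 0, oc = 0)
  expect_equal(analytic_interval_risk(p0, "EC", 25, 75), 0)
  expect_error(analytic_interval_risk(p, "EC", 50, 50), "a < b")
  expect_error(analytic_interval_risk(p, "EC", 24, 50), "\\[25, 75\\]")
})

test_that("raising any hazard never decreases the analytic risk", {
  set.seed(404)
  for (k in 1:25) {
    h <- runif(10, 0, 0.05)
    bump <- sample(10, 1)
    h2 <- h; h2[bump] <- h2[bump] + runif(1, 0, 0.05)
    a <- sample(25:74, 1)
    bb <- (a + 1):75; b <- bb[sample.int(length(bb), 1)]
    expect_gte(analytic_interval_risk(params_with(ec = h2), "EC", a, b),
               analytic_interval_risk(params_with(ec = h), "EC", a, b))
  }
})

test_that("zero hazards give a cohort without cancer events", {
  co <- generate_cohort(params_with(ec = 0, oc = 0, n = 500, seed = 2))
  expect_true(all(is.na(co$records$age_ec_dx)))
  expect_true(all(is.na(co$records$age_oc_dx)))
  expect_true(all(is.na(co$records$age_death)))
})

test_that("the same seed yields a byte-identical cohort CSV", {
  p <- default_params("MLH1", n = 400, seed = 99)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(p), f1)
  write_cohort(generate_cohort(p), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("generated records satisfy the cohort invariants", {
  co <- generate_cohort(default_params("MSH2", n = 2000, seed = 5))
  r <- co$records
  expect_equal(nrow(r), 2000)
  expect_equal(nrow(co$rejected), 0)
  expect_true(all(r$age_inclusion >= 25 & r$age_inclusion <= 74))
  expect_true(all(r$age_last_obs - r$age_inclusion >= 1))
  ## treatment of a first cancer removes the other organ the same day
  ec <- !is.na(r$age_ec_dx)
  expect_true(all(r$age_bso[ec] == r$age_ec_dx[ec]))
  expect_false(any(!is.na(r$age_ec_dx) & !is.na(r$age_oc_dx)))
})

test_that("estimated AIRs recover the generating hazards (moderate n)", {
  p <- default_params("MSH2", n = 30000, seed = 8)
  co <- generate_cohort(p)
  r <- annual_incidence_rates(person_years(co, "EC", "MSH2"))
  truth <- unname(p$ec_hazard[as.character(r$bin_start)])
  keep <- r$person_years >= 100
  se <- sqrt(truth * (1 - truth) / r$person_years)
  expect_true(all(abs(r$air - truth)[keep] <= 3 * se[keep]))
})

test_that("simulated post-diagnosis records recover the survival targets", {
  p <- default_params("MLH1", n = 1)
  for (ep in c("EC", "OC")) {
    cases <- simulate_cases(2500, ep, p, seed = 31)
    km <- kaplan_meier(cases)
    expect_lt(abs(survival_at(km, 10) - survival_targets()[[ep]]), 0.02)
  }
})
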