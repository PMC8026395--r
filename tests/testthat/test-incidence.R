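test_that("person-years accumulate exact fractional bin overlaps", {
  co <- cohort_of(rec(age_inclusion = 25, age_last_obs = 30))
  py <- person_years(co, "EC")
  expect_equal(py$person_years[py$bin_start == 25], 5)
  expect_equal(sum(py$events), 0)

  ## censored at hysterectomy when counting endometrial incidence
  co2 <- cohort_of(rec(age_inclusion = 25, age_last_obs = 40,
                       age_hysterectomy = 27))
  py2 <- person_years(co2, "EC")
  expect_equal(py2$person_years[py2$bin_start == 25], 2)
  expect_equal(sum(py2$person_years), 2)
  ## but she remains at ovarian risk to the end of observation
  py2o <- person_years(co2, "OC")
  expect_equal(sum(py2o$person_years), 15)

  ## event bin and truncation at diagnosis
  co3 <- cohort_of(rec(age_inclusion = 38, age_last_obs = 50,
                       age_ec_dx = 43.5))
  py3 <- person_years(co3, "EC")
  expect_equal(py3$person_years[py3$bin_start == 35], 2)
  expect_equal(py3$person_years[py3$bin_start == 40], 3.5)
  expect_equal(py3$events[py3$bin_start == 40], 1)
  expect_equal(sum(py3$events), 1)
})

test_that("a cancer found at the surgery age counts as an event, then censors", {
  co <- cohort_of(rec(age_inclusion = 40, age_last_obs = 60,
                      age_hysterectomy = 52, age_bso = 52, age_ec_dx = 52))
  py <- person_years(co, "EC")
  expect_equal(sum(py$events), 1)
  expect_equal(py$events[py$bin_start == 50], 1)
  expect_equal(sum(py$person_years), 12)
})

test_that("previous cancers contribute neither time nor events", {
  co <- cohort_of(rec(age_inclusion = 40, age_last_obs = 55,
                      age_ec_dx = 40))
  expect_true(co$records$prev_ec)
  py <- person_years(co, "EC")
  expect_equal(sum(py$person_years), 0)
  expect_equal(sum(py$events), 0)
  ## the same woman still contributes ovarian observation time
  expect_equal(sum(person_years(co, "OC")$person_years), 15)
})

test_that("observation outside [25, 75) and events at 75+ are excluded", {
  co <- cohort_of(rec(age_inclusion = 70, age_last_obs = 79,
                      age_ec_dx = 76))
  py <- person_years(co, "EC")
  expect_equal(sum(py$person_years), 5)   # 70 to 75 only
  expect_equal(sum(py$events), 0)
})

test_that("total person-years are conserved across bins", {
  co <- generate_cohort(default_params("MLH1", n = 1500, seed = 13))
  r <- co$records
  for (ep in c("EC", "OC")) {
    py <- person_years(co, ep, "MLH1")
    censor <- if (ep == "EC") r$age_hysterectomy else r$age_bso
    dx <- if (ep == "EC") r$age_ec_dx else r$age_oc_dx
    end <- pmin(r$age_last_obs,
                ifelse(is.na(censor), Inf, censor),
                ifelse(is.na(dx), Inf, dx), 75)
    expected <- sum(pmax(0, end - pmax(r$age_inclusion, 25)))
    expect_equal(sum(py$person_years), expected, tolerance = 1e-9)
  }
})

test_that("removing a record never increases events or person-years", {
  co <- generate_cohort(default_params("MSH2", n = 300, seed = 21))
  py_all <- person_years(co, "EC", "MSH2")
  co_less <- co
  co_less$records <- co_less$records[-seq_len(50), ]
  py_less <- person_years(co_less, "EC", "MSH2")
  expect_true(all(py_less$events <= py_all$events))
  expect_true(all(py_less$person_years <= py_all$person_years + 1e-12))
})

test_that("combined-endpoint risk set follows the censoring mode", {
  ## hysterectomy only at 45: still at combined risk via the ovaries
  co <- cohort_of(rec(age_inclusion = 40, age_last_obs = 60,
                      age_hysterectomy = 45))
  both <- person_years(co, "EC_or_OC", combined_censoring = "both-organs")
  any_s <- person_years(co, "EC_or_OC", combined_censoring = "any-surgery")
  expect_equal(sum(both$person_years), 20)
  expect_equal(sum(any_s$person_years), 5)

  ## each combined event is exactly one first EC or OC event
  cog <- generate_cohort(default_params("MLH1", n = 4000, seed = 17))
  ev_comb <- sum(person_years(cog, "EC_or_OC", "MLH1")$events)
  ev_ec <- sum(person_years(cog, "EC", "MLH1")$events)
  ev_oc <- sum(person_years(cog, "OC", "MLH1")$events)
  expect_equal(ev_comb, ev_ec + ev_oc)  # treatment removes the other organ
})

test_that("annual incidence rates follow the events/person-years definition", {
  bins <- data.frame(gene = "MLH1", endpoint = "EC",
                     bin_start = seq(25, 70, 5),
                     events = c(2L, rep(0L, 9)),
                     person_years = c(100, 500, rep(0, 8)))
  r <- annual_incidence_rates(bins, min_py = 10)
  expect_equal(r$air[1], 0.02)
  expect_equal(r$air[2], 0)
  expect_true(all(is.na(r$air[3:10])))
  expect_true(all(r$unreliable[3:10]))
  expect_false(any(r$unreliable[1:2]))
})

test_that("exact Poisson intervals match the gamma-quantile oracle", {
  ci <- poisson_ci(10, 1000)
  expect_equal(unname(ci), c(qgamma(0.025, 10), qgamma(0.975, 11)) / 1000,
               tolerance = 1e-12)
  expect_equal(round(unname(ci), 4), c(0.0048, 0.0184))
  expect_equal(poisson_ci(0, 100)[["low"]], 0)
  ## interval always contains the point estimate
  set.seed(6)
  for (k in 1:20) {
    ev <- rpois(1, 5); py <- runif(1, 10, 2000)
    ci <- poisson_ci(ev, py)
    expect_lte(ci[["low"]], ev / py + 1e-12)
    expect_gte(ci[["high"]], ev / py - 1e-12)
  }
  expect_error(poisson_ci(1, 100, level = 1.2), "level")
})
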