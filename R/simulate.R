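#' @name synthetic_cohort
#' @title Synthetic prospective cohorts with known hazards
#'
#' @description The simulator draws one Bernoulli trial per woman, organ and
#' whole year of follow-up from gene-specific piecewise-constant annual
#' hazards on 5-year age bins. The discrete annual model is deliberately the
#' exact inverse of the annual cumulative-incidence recursion used downstream
#' ([cumulative_incidence()]), so [analytic_interval_risk()] is a closed-form
#' oracle for what the estimation pipeline should recover. First
#' gynecological cancer triggers treatment that removes both organs from
#' further risk; prophylactic surgery (hysterectomy + BSO) is an annual
#' uptake probability; death after diagnosis follows a mixture-cure model
#' calibrated so 10-year survival equals the configured targets.
NULL

#' Default simulation parameters for a mismatch-repair gene
#'
#' Builds the full parameter set for [generate_cohort()]. Annual EC and OC
#' hazards are solved from the published cumulative risks at ages 40/50/60/70
#' ([printed_interval_risks()]) so the analytic cumulative risk reproduces
#' each published anchor exactly; in particular PMS2 has zero hazard below
#' age 50 (no demonstrable premenopausal risk). The mixture-cure survival
#' model is calibrated to 10-year crude survival of 0.89 (EC) and 0.84 (OC).
#'
#' @param gene one of `"MLH1"`, `"MSH2"`, `"MSH6"`, `"PMS2"`.
#' @param n number of women to simulate.
#' @param seed integer seed; the generator is fully reproducible.
#' @return A `sim_params` list: `gene`; `ec_hazard`/`oc_hazard` (annual
#'   probability per 5-year bin 25..70, with a 70-75 continuation);
#'   `inclusion_age_dist` (weights over inclusion bins); `followup_dist`
#'   (`mean`, `max` additional observation years); `surgery_uptake` (annual
#'   probability of risk-reducing hysterectomy+BSO per bin);
#'   `hysterectomy_only` (logical); `survival_model` (per endpoint:
#'   `target10`, `event_time_scale`, `cure_fraction`);
#'   `background_mortality` (annual rate, 0 = off); `n`; `seed`.
#' @seealso [generate_cohort()], [analytic_interval_risk()]
#' @export
#' @examples
#' p <- default_params("MLH1", n = 1000, seed = 1)
#' analytic_interval_risk(p, "EC", 25, 50)  # 0.15 by construction
default_params <- function(gene, n = 10000L, seed = 1L) {
  gene <- match.arg(gene, GENES)
  anchors <- printed_interval_risks()
  pick <- function(ep) {
    a <- anchors[anchors$gene == gene & anchors$endpoint == ep, ]
    hazards_from_anchors(a$risk[order(a$to_age)])
  }
  bins <- as.character(BIN_STARTS)
  targets <- survival_targets()
  p <- list(
    gene = gene,
    ec_hazard = pick("EC"),
    oc_hazard = pick("OC"),
    ## inclusion ages skew young, as in prospective registries where most
    ## carriers are identified through family testing at reproductive ages
    inclusion_age_dist = setNames(
      c(0.16, 0.15, 0.14, 0.13, 0.11, 0.09, 0.08, 0.06, 0.05, 0.03), bins),
    followup_dist = list(mean = 10, max = 30),
    surgery_uptake = setNames(
      c(0, 0, 0, rep(0.01, 7)), bins),  # uptake from age 40, after childbearing
    hysterectomy_only = FALSE,
    survival_model = list(
      EC = list(target10 = unname(targets["EC"]), event_time_scale = 3,
                cure_fraction = cure_fraction_for_target(targets["EC"], 3)),
      OC = list(target10 = unname(targets["OC"]), event_time_scale = 3,
                cure_fraction = cure_fraction_for_target(targets["OC"], 3))
    ),
    background_mortality = 0,
    n = as.integer(n),
    seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params") || is.list(p))
  if (!p$gene %in% GENES) stop("unknown gene: ", p$gene, call. = FALSE)
  for (fld in c("ec_hazard", "oc_hazard", "surgery_uptake")) {
    h <- p[[fld]]
    if (!setequal(names(h)[seq_along(BIN_STARTS)], as.character(BIN_STARTS))) {
      stop(fld, " must be named by bin starts 25,30,...,70", call. = FALSE)
    }
    if (any(h < 0 | h > 1)) stop(fld, " outside [0,1]", call. = FALSE)
  }
  if (any(p$inclusion_age_dist < 0) || sum(p$inclusion_age_dist) <= 0) {
    stop("invalid inclusion age weights", call. = FALSE)
  }
  if (p$followup_dist$mean < 1 || p$followup_dist$max < 1) {
    stop("follow-up must allow at least one year", call. = FALSE)
  }
  for (ep in c("EC", "OC")) {
    m <- p$survival_model[[ep]]
    s10 <- m$cure_fraction +
      (1 - m$cure_fraction) * exp(-10 / m$event_time_scale)
    if (abs(s10 - m$target10) > 1e-9) {
      stop("survival model for ", ep,
           " does not reproduce its 10-year target", call. = FALSE)
    }
  }
  if (!is.null(p$n) && p$n <= 0) stop("n must be positive", call. = FALSE)
  invisible(p)
}

## annual hazard lookup for integer ages; zero outside the 25..74 window
## except that the 70-bin value extends over 70..74 (and the curve grid stops
## at 75 anyway)
hazard_at <- function(age, hazard) {
  h <- rep(0, length(age))
  in_range <- age >= 25 & age < 75
  bin <- as.character(pmin(70, 5 * (age %/% 5)))
  h[in_range] <- unname(hazard[bin[in_range]])
  h
}

#' Closed-form cancer risk oracle for simulation parameters
#'
#' Probability of a first cancer of the given organ in the age interval
#' \[a, b) for a woman with the organ intact throughout (surgery uptake is
#' ignored), under the discrete annual-hazard model:
#' `1 - prod(1 - hazard(t))` over integer years `t` in \[a, b). Because the
#' simulator draws exactly these annual Bernoulli trials, this is the exact
#' expectation the estimation pipeline should recover.
#'
#' @param params a `sim_params` list ([default_params()]).
#' @param endpoint `"EC"` or `"OC"`.
#' @param a,b integer ages with `25 <= a < b <= 75`.
#' @return Probability in \[0, 1\].
#' @export
analytic_interval_risk <- function(params, endpoint = c("EC", "OC"), a, b) {
  endpoint <- match.arg(endpoint)
  if (a >= b) stop("need a < b", call. = FALSE)
  if (a < 25 || b > 75 || a != round(a) || b != round(b)) {
    stop("ages must be integers in [25, 75]", call. = FALSE)
  }
  hz <- if (endpoint == "EC") params$ec_hazard else params$oc_hazard
  h <- hazard_at(seq(a, b - 1), hz)
  1 - prod(1 - h)
}

#' Generate a synthetic prospective follow-up cohort
#'
#' Simulates `params$n` women: inclusion age drawn from the configured bin
#' weights (whole years), follow-up duration in whole years
#' (`1 + Poisson(mean - 1)`, truncated at `max`), then one annual step per
#' year of observation. Within a year, cancer events are drawn first (EC and
#' OC independently from the bin hazard of the organ still intact; a
#' same-year double hit is resolved by a fair coin), then prophylactic
#' surgery. Events and surgeries are stamped at the end of the at-risk year
#' (`age + 0.99`), so an event year still contributes essentially a full
#' person-year before censoring — keeping the events/person-years estimator
#' an unbiased inverse of the generating hazard. A first cancer is treated
#' by hysterectomy + BSO at the diagnosis age, removing the other organ from
#' risk; death after diagnosis follows the mixture-cure model and, when it
#' precedes the scheduled last observation, terminates follow-up with the
#' death-cause flag set.
#'
#' @param params a `sim_params` list; see [default_params()].
#' @return A validated `lynch_cohort`; `provenance` records gene, n and seed.
#' @export
generate_cohort <- function(params) {
  validate_sim_params(params)
  n <- params$n
  if (is.null(n) || n <= 0) stop("n must be positive", call. = FALSE)
  set.seed(params$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  bins <- as.numeric(names(params$inclusion_age_dist))
  incl_bin <- sample(bins, n, replace = TRUE,
                     prob = params$inclusion_age_dist)
  width <- pmin(incl_bin + 4, 74) - incl_bin   # top bin is 70..74
  incl <- incl_bin + floor(runif(n) * (width + 1))
  fu <- pmin(params$followup_dist$max,
             1 + rpois(n, params$followup_dist$mean - 1))
  sched_last <- incl + fu

  uterus <- rep(TRUE, n)
  ovaries <- rep(TRUE, n)
  ec_age <- oc_age <- hyst_age <- bso_age <- rep(NA_real_, n)

  for (t in 0:(max(fu) - 1)) {
    active <- t < fu
    if (!any(active)) break
    age <- incl + t
    u_ec <- runif(n); u_oc <- runif(n); u_tie <- runif(n); u_s <- runif(n)
    ec_hit <- active & uterus & u_ec < hazard_at(age, params$ec_hazard)
    oc_hit <- active & ovaries & u_oc < hazard_at(age, params$oc_hazard)
    both <- ec_hit & oc_hit
    ec_hit[both] <- u_tie[both] < 0.5
    oc_hit[both] <- !ec_hit[both]
    ev <- age + 0.99
    ## first gynecological cancer: standard treatment removes both organs
    if (any(ec_hit)) {
      ec_age[ec_hit] <- ev[ec_hit]
      hyst_age[ec_hit & uterus] <- ev[ec_hit & uterus]
      bso_age[ec_hit & ovaries] <- ev[ec_hit & ovaries]
      uterus[ec_hit] <- FALSE; ovaries[ec_hit] <- FALSE
    }
    if (any(oc_hit)) {
      oc_age[oc_hit] <- ev[oc_hit]
      bso_age[oc_hit & ovaries] <- ev[oc_hit & ovaries]
      hyst_age[oc_hit & uterus] <- ev[oc_hit & uterus]
      uterus[oc_hit] <- FALSE; ovaries[oc_hit] <- FALSE
    }
    s_hit <- active & !ec_hit & !oc_hit & (uterus | ovaries) &
      u_s < hazard_at(age, params$surgery_uptake)
    if (any(s_hit)) {
      hyst_age[s_hit & uterus] <- ev[s_hit & uterus]
      uterus[s_hit] <- FALSE
      if (!isTRUE(params$hysterectomy_only)) {
        bso_age[s_hit & ovaries] <- ev[s_hit & ovaries]
        ovaries[s_hit] <- FALSE
      }
    }
  }

  ## post-diagnosis death from the mixture-cure model
  dx <- ifelse(!is.na(ec_age), ec_age, oc_age)
  ep <- ifelse(!is.na(ec_age), "EC", "OC")
  ca_death <- rep(NA_real_, n)
  has_ca <- !is.na(dx)
  for (e in c("EC", "OC")) {
    idx <- which(has_ca & ep == e)
    if (length(idx) == 0) next
    m <- params$survival_model[[e]]
    cured <- runif(length(idx)) < m$cure_fraction
    t_death <- rexp(length(idx), rate = 1 / m$event_time_scale)
    ca_death[idx[!cured]] <- dx[idx[!cured]] + t_death[!cured]
  }
  bg_death <- rep(NA_real_, n)
  if (params$background_mortality > 0) {
    bg_death <- incl + rexp(n, rate = params$background_mortality)
  }
  death_age <- pmin(ca_death, bg_death, na.rm = TRUE)
  death_age[is.infinite(death_age)] <- NA_real_
  died <- !is.na(death_age) & death_age < sched_last
  ## registry inclusion requires >= 1 year of follow-up; a death in the first
  ## observation year is recorded at inclusion + 1
  last_obs <- ifelse(died, pmax(round_age(death_age), incl + 1), sched_last)
  cancer_death <- died & !is.na(ca_death) &
    (is.na(bg_death) | ca_death <= bg_death)

  df <- data.frame(
    id = sprintf("%s-%06d", params$gene, seq_len(n)),
    gene = params$gene,
    age_inclusion = as.numeric(incl),
    age_last_obs = round_age(last_obs),
    age_hysterectomy = round_age(hyst_age),
    age_bso = round_age(bso_age),
    age_ec_dx = round_age(ec_age),
    age_oc_dx = round_age(oc_age),
    age_death = ifelse(died, round_age(last_obs), NA_real_),
    died_of_followup_cancer = ifelse(died & has_ca, cancer_death, NA),
    stringsAsFactors = FALSE
  )
  as_cohort(df, provenance = list(source = "generate_cohort",
                                  gene = params$gene, n = n,
                                  seed = params$seed))
}

#' Simulate post-diagnosis survival records
#'
#' Draws standalone cancer cases from the mixture-cure survival model with
#' independent censoring, for checking that Kaplan-Meier estimation recovers
#' the configured 10-year survival target. Censoring time after diagnosis is
#' `min(max, 1 + Exponential(mean - 1))` years.
#'
#' @param n number of cases.
#' @param endpoint `"EC"` or `"OC"`.
#' @param params a `sim_params` list supplying the survival model.
#' @param followup_mean,followup_max censoring distribution (years after
#'   diagnosis).
#' @param seed integer seed.
#' @return A data frame of cases: `gene`, `endpoint`, `age_dx`, `age_end`,
#'   `died` — the input format of [kaplan_meier()].
#' @export
simulate_cases <- function(n, endpoint = c("EC", "OC"), params,
                           followup_mean = 12, followup_max = 30,
                           seed = 1L) {
  endpoint <- match.arg(endpoint)
  stopifnot(n > 0)
  set.seed(seed, kind = "Mersenne-Twister")
  m <- params$survival_model[[endpoint]]
  age_dx <- round_age(runif(n, 40, 70))
  cens <- pmin(followup_max, 1 + rexp(n, rate = 1 / (followup_mean - 1)))
  cured <- runif(n) < m$cure_fraction
  t_death <- rexp(n, rate = 1 / m$event_time_scale)
  t_death[cured] <- Inf
  died <- t_death < cens
  time <- round_age(pmin(t_death, cens))
  data.frame(
    gene = params$gene, endpoint = endpoint,
    age_dx = age_dx, age_end = age_dx + time, died = died,
    stringsAsFactors = FALSE
  )
}
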