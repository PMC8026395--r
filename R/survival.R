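#' Crude Kaplan-Meier survival after cancer
#'
#' Product-limit estimate of crude survival from age at diagnosis until
#' death or last observation, computed with [survival::survfit()]. By
#' default every death is an event regardless of cause ("crude" survival);
#' `cancer_deaths_only = TRUE` restricts events to deaths attributed to the
#' followed cancer (sensitivity analysis), censoring other deaths. Deaths
#' tied with censorings at the same time are processed first (standard
#' convention). Survival is normally pooled across genes and diagnosis
#' ages; pass a per-gene subset for descriptive curves.
#'
#' @param cases data frame of cancer cases with columns `age_dx`, `age_end`,
#'   `died` (logical), and optionally `died_of_followup_cancer`; see
#'   [extract_cases()] and [simulate_cases()].
#' @param cancer_deaths_only logical; see above.
#' @return A `km_curve`: list with `endpoint`, `n`, `time` (years since
#'   diagnosis), `surv`, `n_risk`, `n_event`, `max_time`.
#' @export
kaplan_meier <- function(cases, cancer_deaths_only = FALSE) {
  stopifnot(all(c("age_dx", "age_end", "died") %in% names(cases)))
  if (nrow(cases) == 0) stop("no cancer cases supplied", call. = FALSE)
  time <- cases$age_end - cases$age_dx
  if (any(time < 0)) stop("age_end before age_dx", call. = FALSE)
  event <- as.logical(cases$died)
  if (cancer_deaths_only) {
    if (is.null(cases$died_of_followup_cancer)) {
      stop("cancer_deaths_only needs a died_of_followup_cancer column",
           call. = FALSE)
    }
    event <- event & !is.na(cases$died_of_followup_cancer) &
      cases$died_of_followup_cancer
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(
    list(endpoint = if (is.null(cases$endpoint)) NA_character_
                    else paste(unique(cases$endpoint), collapse = "+"),
         n = nrow(cases),
         time = fit$time, surv = fit$surv,
         n_risk = fit$n.risk, n_event = fit$n.event,
         max_time = max(time)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier crude survival (%s), n = %d cases\n",
              x$endpoint, x$n))
  for (t in c(1, 2, 5, 10)) {
    if (t <= x$max_time) {
      cat(sprintf("  S(%2d) = %.3f\n", t,
                  suppressWarnings(survival_at(x, t))))
    }
  }
  invisible(x)
}

#' Evaluate a survival curve at a follow-up time
#'
#' Right-continuous step-function value S(t). Beyond the longest observed
#' follow-up the last value is returned with an extrapolation warning.
#'
#' @param curve a `km_curve`.
#' @param t non-negative years since diagnosis.
#' @return Survival probability.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (t < 0) stop("t must be non-negative", call. = FALSE)
  if (t > curve$max_time) {
    warning(sprintf(
      "t = %g exceeds the longest follow-up (%.2f); returning the last value",
      t, curve$max_time), call. = FALSE)
  }
  c(1, curve$surv)[findInterval(t, curve$time) + 1]
}

#' Endometrial fraction of the combined gynecological risk
#'
#' `ec_risk / (ec_risk + oc_risk)` — the weight used to interpolate
#' survival for the combined EC/OC endpoint.
#'
#' @param ec_risk,oc_risk interval risks in \[0, 1\], not both zero.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' ec_fraction(0.15, 0.06)  # 0.7143
ec_fraction <- function(ec_risk, oc_risk) {
  if (ec_risk < 0 || oc_risk < 0) stop("risks must be >= 0", call. = FALSE)
  if (ec_risk + oc_risk == 0) {
    stop("undefined fraction; no combined risk", call. = FALSE)
  }
  ec_risk / (ec_risk + oc_risk)
}

#' Interpolated survival for the combined EC/OC endpoint
#'
#' Endometrial cancer survival exceeds ovarian cancer survival by a
#' constant difference across ages; survival after the combined endpoint is
#' interpolated between the two by the endometrial share of combined risk:
#' `oc_survival + (ec_survival - oc_survival) * ec_fraction`. The result
#' necessarily lies between the two single-endpoint survivals.
#'
#' @param ec_survival,oc_survival 10-year survival after EC and OC.
#' @param ec_fraction endometrial fraction from [ec_fraction()].
#' @return Interpolated survival probability.
#' @export
#' @examples
#' combined_survival(0.89, 0.84, 15 / 21)  # 0.8757 -> 88% rounded
combined_survival <- function(ec_survival, oc_survival, ec_fraction) {
  stopifnot(ec_survival >= 0, ec_survival <= 1,
            oc_survival >= 0, oc_survival <= 1,
            ec_fraction >= 0, ec_fraction <= 1)
  out <- oc_survival + (ec_survival - oc_survival) * ec_fraction
  lo <- min(ec_survival, oc_survival)
  hi <- max(ec_survival, oc_survival)
  stopifnot(out >= lo - 1e-12, out <= hi + 1e-12)
  out
}

#' Extract post-diagnosis cancer cases from a cohort
#'
#' One row per prospectively observed first cancer of the requested
#' endpoint: diagnosis age, end of follow-up (death or last observation)
#' and vital status — the input of [kaplan_meier()]. Previous cancers
#' (diagnosed at or before inclusion) are excluded.
#'
#' @param cohort a `lynch_cohort`.
#' @param endpoint `"EC"` or `"OC"`.
#' @param gene optional gene filter; default pools all genes.
#' @return Data frame with `gene`, `endpoint`, `age_dx`, `age_end`, `died`,
#'   `died_of_followup_cancer`.
#' @export
extract_cases <- function(cohort, endpoint = c("EC", "OC"), gene = NULL) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(cohort, "lynch_cohort"))
  r <- cohort$records
  if (!is.null(gene)) r <- r[r$gene == gene, , drop = FALSE]
  dx <- if (endpoint == "EC") r$age_ec_dx else r$age_oc_dx
  prev <- if (endpoint == "EC") r$prev_ec else r$prev_oc
  keep <- !is.na(dx) & !prev
  end <- ifelse(!is.na(r$age_death), pmin(r$age_death, r$age_last_obs),
                r$age_last_obs)
  data.frame(
    gene = r$gene[keep], endpoint = endpoint,
    age_dx = dx[keep], age_end = pmax(end[keep], dx[keep]),
    died = !is.na(r$age_death[keep]),
    died_of_followup_cancer = r$died_of_followup_cancer[keep],
    stringsAsFactors = FALSE
  )
}
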