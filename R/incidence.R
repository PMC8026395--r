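#' Person-years at risk and events in 5-year age bins
#'
#' Accumulates, for each 5-year age bin \[s, s+5) with s = 25, 30, ..., 70,
#' the exact fractional at-risk observation time and the number of first
#' cancer events for one gene and endpoint. Per record the at-risk interval
#' is `[max(age_inclusion, 25), min(age_last_obs, censor_age, 75, age_dx))`,
#' where the censoring age is the age at removal of the organ under study:
#' hysterectomy for EC, BSO for OC, and for the combined endpoint the age at
#' which the last at-risk organ is removed (`combined_censoring =
#' "both-organs"`, the default) or the first surgery of either kind
#' (`"any-surgery"`). Records flagged with a previous cancer for the
#' endpoint contribute no time. A diagnosis at the same age as surgery
#' counts as an event (occult cancer found at surgery) followed by
#' censoring; an event at exactly age 75 is out of range.
#'
#' @param cohort a validated `lynch_cohort`.
#' @param endpoint `"EC"`, `"OC"` or `"EC_or_OC"`.
#' @param gene gene to select, or `NULL` to pool all records.
#' @param combined_censoring censoring rule for the combined endpoint; a
#'   woman stays in the combined risk set while at least one organ is intact
#'   under `"both-organs"`.
#' @return A data frame of class `age_bin_incidence`: `gene`, `endpoint`,
#'   `bin_start`, `events`, `person_years`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_params("MLH1", n = 500, seed = 7))
#' py <- person_years(cohort, "EC", "MLH1")
#' annual_incidence_rates(py)
person_years <- function(cohort, endpoint = c("EC", "OC", "EC_or_OC"),
                         gene = NULL,
                         combined_censoring = c("both-organs",
                                                "any-surgery")) {
  endpoint <- match.arg(endpoint)
  combined_censoring <- match.arg(combined_censoring)
  stopifnot(inherits(cohort, "lynch_cohort"))
  r <- cohort$records
  if (!is.null(gene)) {
    gene <- match.arg(gene, GENES)
    r <- r[r$gene == gene, , drop = FALSE]
  }
  gene_label <- if (is.null(gene)) "all" else gene

  inf <- function(x) ifelse(is.na(x), Inf, x)
  if (endpoint == "EC") {
    censor <- inf(r$age_hysterectomy)
    dx <- r$age_ec_dx
    prev <- r$prev_ec
  } else if (endpoint == "OC") {
    censor <- inf(r$age_bso)
    dx <- r$age_oc_dx
    prev <- r$prev_oc
  } else {
    censor <- if (combined_censoring == "both-organs") {
      ## at risk while >= 1 organ intact: censored only when both removed
      ifelse(!is.na(r$age_hysterectomy) & !is.na(r$age_bso),
             pmax(r$age_hysterectomy, r$age_bso), Inf)
    } else {
      pmin(inf(r$age_hysterectomy), inf(r$age_bso))
    }
    dx <- pmin(inf(r$age_ec_dx), inf(r$age_oc_dx))
    dx[is.infinite(dx)] <- NA_real_
    prev <- r$prev_ec | r$prev_oc
  }

  start <- pmax(r$age_inclusion, AGE_MIN)
  end <- pmin(r$age_last_obs, censor, AGE_MAX, inf(dx))
  drop <- prev | end <= start
  start <- start[!drop]; end <- end[!drop]
  dx <- dx[!drop]; censor <- censor[!drop]
  ## event counted when diagnosed after inclusion, at or before organ
  ## removal (tie = occult cancer at surgery) and before age 75
  has_event <- !is.na(dx) & dx <= censor & dx < AGE_MAX

  out <- data.frame(
    gene = gene_label, endpoint = endpoint, bin_start = BIN_STARTS,
    events = 0L, person_years = 0, stringsAsFactors = FALSE
  )
  for (k in seq_along(BIN_STARTS)) {
    s <- BIN_STARTS[k]
    out$person_years[k] <-
      sum(pmax(0, pmin(end, s + 5) - pmax(start, s)))
    out$events[k] <- sum(has_event & dx >= s & dx < s + 5)
  }
  class(out) <- c("age_bin_incidence", class(out))
  out
}

#' Annual incidence rates from binned person-years
#'
#' Fills in the annual incidence rate `air = events / person_years` per bin
#' and flags bins whose observation time is too small to be reliable. A bin
#' with zero person-years gets `air = NA` and is treated as zero downstream
#' with a warning.
#'
#' @param bins output of [person_years()].
#' @param min_py bins with fewer person-years are flagged `unreliable`.
#' @param level confidence level for the exact Poisson interval.
#' @return The input with columns `air`, `ci_low`, `ci_high`, `unreliable`.
#' @export
annual_incidence_rates <- function(bins, min_py = 10, level = 0.95) {
  stopifnot(all(c("events", "person_years") %in% names(bins)))
  air <- ifelse(bins$person_years > 0,
                bins$events / bins$person_years, NA_real_)
  ci <- t(mapply(function(x, py) {
    if (py > 0) poisson_ci(x, py, level) else c(NA_real_, NA_real_)
  }, bins$events, bins$person_years))
  bins$air <- air
  bins$ci_low <- ci[, 1]
  bins$ci_high <- ci[, 2]
  bins$unreliable <- bins$person_years < min_py
  bins
}

#' Exact Poisson (Garwood) confidence interval for an incidence rate
#'
#' Chi-square/gamma quantile bounds on the rate `events / person_years`;
#' the lower bound is 0 when no events were observed. The interval always
#' contains the point estimate.
#'
#' @param events non-negative event count.
#' @param person_years positive observation time.
#' @param level confidence level in (0, 1).
#' @return Numeric vector `c(low, high)` on the rate scale (per year).
#' @export
#' @examples
#' poisson_ci(10, 1000)  # c(0.0048, 0.0184)
poisson_ci <- function(events, person_years, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  if (person_years <= 0) stop("person_years must be positive", call. = FALSE)
  if (events < 0) stop("events must be non-negative", call. = FALSE)
  alpha <- 1 - level
  low <- if (events == 0) 0 else qgamma(alpha / 2, events) / person_years
  high <- qgamma(1 - alpha / 2, events + 1) / person_years
  c(low = low, high = high)
}
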