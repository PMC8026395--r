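#' Cumulative incidence curve from annual incidence rates
#'
#' Builds Q(age) on the integer age grid 25..75 by the annual recursion
#' `Q(age) = Q(age - 1) + (1 - Q(age - 1)) * AIR(age)`, starting from
#' `Q(25) = 0` (incidence is taken as zero before age 25, the youngest age
#' at which prospective observation starts). The AIR for each annual step is
#' the rate of the 5-year bin containing the year, used uniformly within the
#' bin; no smoothing between bins. The recursion is algebraically identical
#' to `Q(b) = 1 - prod(1 - AIR(t))` over years t in \[25, b).
#'
#' @param rates output of [annual_incidence_rates()] covering all bins
#'   25..70; a missing bin is an error naming it. Bins with `NA` rate are
#'   treated as zero with a warning; bins flagged unreliable propagate into
#'   the curve's `warnings` field.
#' @return A `cuminc_curve`: list with `gene`, `endpoint`, `age` (25:75),
#'   `q`, and `warnings`.
#' @seealso [interval_risk()], [compose_interval_risks()]
#' @export
cumulative_incidence <- function(rates) {
  stopifnot(all(c("bin_start", "air") %in% names(rates)))
  missing_bins <- setdiff(BIN_STARTS, rates$bin_start)
  if (length(missing_bins) > 0) {
    stop("rates are missing bin(s): ",
         paste(missing_bins, collapse = ", "), call. = FALSE)
  }
  rates <- rates[match(BIN_STARTS, rates$bin_start), ]
  warnings <- character()
  air <- rates$air
  if (anyNA(air)) {
    na_bins <- rates$bin_start[is.na(air)]
    msg <- paste0("AIR undefined (no person-years) in bin(s) ",
                  paste(na_bins, collapse = ", "), "; treated as 0")
    warning(msg, call. = FALSE)
    warnings <- c(warnings, msg)
    air[is.na(air)] <- 0
  }
  if (!is.null(rates$unreliable) && any(rates$unreliable)) {
    warnings <- c(warnings, paste0(
      "low person-years in bin(s) ",
      paste(rates$bin_start[rates$unreliable], collapse = ", ")))
  }
  ages <- AGE_MIN:AGE_MAX
  q <- numeric(length(ages))
  for (i in seq_along(ages)[-1]) {
    step_air <- air[match(5 * ((ages[i] - 1) %/% 5), BIN_STARTS)]
    q[i] <- q[i - 1] + (1 - q[i - 1]) * step_air
  }
  structure(
    list(gene = if (is.null(rates$gene)) NA_character_ else rates$gene[1],
         endpoint = if (is.null(rates$endpoint)) NA_character_
                    else rates$endpoint[1],
         age = ages, q = q, warnings = warnings),
    class = "cuminc_curve"
  )
}

#' @export
print.cuminc_curve <- function(x, ...) {
  cat(sprintf("Cumulative incidence curve (%s, %s)\n", x$gene, x$endpoint))
  show <- x$age %% 5 == 0
  print(setNames(round(x$q[show], 4), x$age[show]))
  if (length(x$warnings) > 0) cat("warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}

q_at <- function(curve, age) {
  i <- match(age, curve$age)
  if (is.na(i)) {
    stop("age ", age, " is off the curve grid ", AGE_MIN, "..", AGE_MAX,
         call. = FALSE)
  }
  curve$q[i]
}

#' Conditional age-interval risk from a cumulative incidence curve
#'
#' Risk of a first cancer in \[a, b) for a woman who is cancer-free with the
#' organ(s) intact at age a: `(Q(b) - Q(a)) / (1 - Q(a))`.
#'
#' @param curve a `cuminc_curve`.
#' @param a,b integer ages on the grid, `25 <= a <= b <= 75`.
#' @return A one-row data frame: `gene`, `endpoint`, `a`, `b`, `risk`.
#' @export
interval_risk <- function(curve, a, b) {
  stopifnot(inherits(curve, "cuminc_curve"))
  if (a > b) stop("need a <= b", call. = FALSE)
  qa <- q_at(curve, a)
  qb <- q_at(curve, b)
  risk <- if (qa >= 1) {
    warning("Q(a) = 1: interval risk undefined, returning 0", call. = FALSE)
    0
  } else {
    (qb - qa) / (1 - qa)
  }
  data.frame(gene = curve$gene, endpoint = curve$endpoint,
             a = a, b = b, risk = risk, stringsAsFactors = FALSE)
}

#' Compose conditional risks over adjacent age intervals
#'
#' If p_ab is the risk in \[a, b) and p_bc the risk in \[b, c) conditional
#' on being cancer-free at b, the risk over \[a, c) is
#' `1 - (1 - p_ab) * (1 - p_bc)`.
#'
#' @param p_ab,p_bc probabilities in \[0, 1\].
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' compose_interval_risks(0.02, 0.16)  # 0.1768
compose_interval_risks <- function(p_ab, p_bc) {
  if (any(c(p_ab, p_bc) < 0) || any(c(p_ab, p_bc) > 1)) {
    stop("interval risks must be in [0,1]", call. = FALSE)
  }
  1 - (1 - p_ab) * (1 - p_bc)
}

## Build a cuminc_curve directly from known annual bin hazards (used for
## calibrated published-risk curves and in tests).
curve_from_hazards <- function(hazard, gene = NA_character_,
                               endpoint = NA_character_) {
  rates <- data.frame(gene = gene, endpoint = endpoint,
                      bin_start = BIN_STARTS,
                      air = unname(hazard[as.character(BIN_STARTS)]),
                      stringsAsFactors = FALSE)
  cumulative_incidence(rates)
}

#' Cumulative incidence curves calibrated to the published interval risks
#'
#' Convenience constructor: the gene's default annual hazards
#' ([default_params()]) are solved from the published cumulative risks, so
#' the returned curve satisfies, e.g. for MLH1 EC, Q(50) = 0.15 and
#' Q(70) = 0.35 exactly.
#'
#' @param gene gene symbol.
#' @param endpoint `"EC"` or `"OC"`.
#' @return A `cuminc_curve`.
#' @export
calibrated_curve <- function(gene, endpoint = c("EC", "OC")) {
  endpoint <- match.arg(endpoint)
  p <- default_params(gene, n = 1L)
  hz <- if (endpoint == "EC") p$ec_hazard else p$oc_hazard
  curve_from_hazards(hz, gene = gene, endpoint = endpoint)
}
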