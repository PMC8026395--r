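## The nine age intervals reported per gene: risk from 25 up to each cutoff
## (cancers preventable by surgery at 25), from 40/50/60 up to 70
## (preventable by surgery at those ages), and the two intermediate decades.
TABLE_ROWS <- list(
  c(25, 40), c(25, 50), c(25, 60), c(25, 70),
  c(40, 70), c(50, 70), c(60, 70),
  c(40, 50), c(50, 60)
)

#' Risk of dying of a cancer diagnosed in an age interval
#'
#' Probability of being diagnosed in the interval and dying of that cancer
#' within 10 years: `risk * (1 - survival10)`.
#'
#' @param risk interval cancer risk in \[0, 1\].
#' @param survival10 10-year crude survival after that cancer.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' death_risk(0.15, 0.89)  # 0.0165 -> 2% rounded
death_risk <- function(risk, survival10) {
  stopifnot(all(risk >= 0 & risk <= 1),
            all(survival10 >= 0 & survival10 <= 1))
  risk * (1 - survival10)
}

#' Round a probability to whole percent
#'
#' Display rounding used by the risk tables: half away from zero on the
#' percent scale. All table arithmetic is done on unrounded values;
#' rounding is applied only when rendering.
#'
#' @param x probability in \[-1, 1\].
#' @return Integer percent.
#' @export
#' @examples
#' round_percent(0.0165)  # 2
#' round_percent(0.0096)  # 1
round_percent <- function(x) {
  stopifnot(all(abs(x) <= 1 + 1e-12, na.rm = TRUE))
  as.integer(sign(x) * floor(100 * abs(x) + 0.5))
}

#' Per-gene risk table for one endpoint
#'
#' The nine-row table for one gene and organ: conditional interval risk
#' (from [interval_risk()]), the pooled 10-year survival, and the risk of
#' dying of a cancer diagnosed in the interval within 10 years
#' ([death_risk()]). Unrounded probabilities are kept alongside the
#' whole-percent display columns.
#'
#' @param curve a `cuminc_curve` on the full 25..75 grid.
#' @param survival10 pooled 10-year crude survival for the endpoint.
#' @return A `risk_table` data frame: `age_from`, `age_to`, `risk`,
#'   `survival10`, `death_risk` plus `*_pct` display columns.
#' @export
build_gene_table <- function(curve, survival10) {
  stopifnot(inherits(curve, "cuminc_curve"),
            survival10 >= 0, survival10 <= 1)
  rows <- lapply(TABLE_ROWS, function(ab) {
    r <- interval_risk(curve, ab[1], ab[2])$risk
    data.frame(age_from = ab[1], age_to = ab[2], risk = r,
               survival10 = survival10,
               death_risk = death_risk(r, survival10))
  })
  out <- do.call(rbind, rows)
  out$gene <- curve$gene
  out$endpoint <- curve$endpoint
  out$risk_pct <- round_percent(out$risk)
  out$survival_pct <- round_percent(out$survival10)
  out$death_pct <- round_percent(out$death_risk)
  class(out) <- c("risk_table", class(out))
  out
}

#' Combined endometrial and/or ovarian risk table
#'
#' The nine-row table for the combined gynecological endpoint. Per row the
#' endometrial fraction is computed from the unrounded EC and OC interval
#' risks, combined survival is interpolated with [combined_survival()], and
#' the death probability is combined risk times one minus combined
#' survival. The combined interval risk is taken from `combined_curve`
#' (estimated with the combined-endpoint risk set) when supplied; otherwise
#' a conservative independence fallback `1 - (1-EC)(1-OC)` is used and
#' flagged in `risk_source`. Rows where both single-organ risks are zero
#' have no defined combined survival (empty cell) and zero death risk.
#'
#' @param ec_curve,oc_curve per-organ `cuminc_curve`s.
#' @param combined_curve optional `cuminc_curve` for the combined endpoint.
#' @param ec_surv,oc_surv pooled 10-year survival after EC and OC.
#' @return A `risk_table` data frame with unrounded and `*_pct` columns.
#' @export
build_combined_table <- function(ec_curve, oc_curve, combined_curve = NULL,
                                 ec_surv = survival_targets()[["EC"]],
                                 oc_surv = survival_targets()[["OC"]]) {
  stopifnot(inherits(ec_curve, "cuminc_curve"),
            inherits(oc_curve, "cuminc_curve"))
  rows <- lapply(TABLE_ROWS, function(ab) {
    ec_r <- interval_risk(ec_curve, ab[1], ab[2])$risk
    oc_r <- interval_risk(oc_curve, ab[1], ab[2])$risk
    if (!is.null(combined_curve)) {
      comb_r <- interval_risk(combined_curve, ab[1], ab[2])$risk
      src <- "combined-curve"
    } else {
      comb_r <- 1 - (1 - ec_r) * (1 - oc_r)
      src <- "independence-fallback"
    }
    if (ec_r + oc_r > 0) {
      frac <- ec_fraction(ec_r, oc_r)
      surv <- combined_survival(ec_surv, oc_surv, frac)
      death <- death_risk(comb_r, surv)
    } else {
      frac <- NA_real_
      surv <- NA_real_   # no cancers in the interval: survival cell empty
      death <- 0
    }
    data.frame(age_from = ab[1], age_to = ab[2],
               ec_risk = ec_r, oc_risk = oc_r, risk = comb_r,
               ec_fraction = frac, survival10 = surv, death_risk = death,
               risk_source = src)
  })
  out <- do.call(rbind, rows)
  out$gene <- ec_curve$gene
  out$endpoint <- "EC_or_OC"
  out$risk_pct <- round_percent(out$risk)
  out$survival_pct <- ifelse(is.na(out$survival10), NA_integer_,
                             round_percent(out$survival10))
  out$death_pct <- round_percent(out$death_risk)
  class(out) <- c("risk_table", class(out))
  out
}

#' @export
print.risk_table <- function(x, ...) {
  needed <- c("age_from", "age_to", "risk_pct", "survival_pct", "death_pct")
  if (!all(needed %in% names(x))) {
    return(print.data.frame(x, ...))
  }
  hdr <- sprintf("Risk table (%s, %s): interval risk / 10-year survival / death risk",
                 x$gene[1], x$endpoint[1])
  cat(hdr, "\n")
  fmt <- function(p) ifelse(is.na(p), "", sprintf("%d%%", p))
  disp <- data.frame(
    interval = sprintf("%d to %d years", x$age_from, x$age_to),
    risk = fmt(x$risk_pct), survival = fmt(x$survival_pct),
    death = fmt(x$death_pct)
  )
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Benefit of risk-reducing surgery at a given age
#'
#' Counterfactual benefit of removing the organ(s) at `surgery_age`: the
#' cancers prevented equal the conditional risk the woman would otherwise
#' carry over \[surgery_age, horizon_age), and the deaths prevented are
#' those cancers times one minus the 10-year survival.
#'
#' @param curve a `cuminc_curve` for the endpoint the surgery removes.
#' @param survival10 pooled 10-year crude survival for the endpoint.
#' @param surgery_age,horizon_age integer ages with
#'   `25 <= surgery_age < horizon_age <= 75`.
#' @param surgery label: `"hysterectomy"`, `"BSO"` or `"both"`.
#' @return A `benefit_estimate`: list with `gene`, `endpoint`, `surgery`,
#'   `surgery_age`, `horizon_age`, `cancers_prevented`, `deaths_prevented`.
#' @export
#' @examples
#' curve <- calibrated_curve("MSH2", "EC")
#' rrs_benefit(curve, 0.89, 40, 50, "hysterectomy")
rrs_benefit <- function(curve, survival10, surgery_age, horizon_age,
                        surgery = c("both", "hysterectomy", "BSO")) {
  surgery <- match.arg(surgery)
  if (surgery_age >= horizon_age) {
    stop("surgery_age must be before horizon_age", call. = FALSE)
  }
  prevented <- interval_risk(curve, surgery_age, horizon_age)$risk
  structure(
    list(gene = curve$gene, endpoint = curve$endpoint, surgery = surgery,
         surgery_age = surgery_age, horizon_age = horizon_age,
         cancers_prevented = prevented,
         deaths_prevented = death_risk(prevented, survival10)),
    class = "benefit_estimate"
  )
}

#' @export
print.benefit_estimate <- function(x, ...) {
  cat(sprintf(
    "%s at age %d (%s, %s): prevents cancer before %d in %d%% and death in %d%%\n",
    x$surgery, x$surgery_age, x$gene, x$endpoint, x$horizon_age,
    round_percent(x$cancers_prevented), round_percent(x$deaths_prevented)))
  invisible(x)
}
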