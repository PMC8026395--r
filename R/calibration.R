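#' Published age-interval risks used to calibrate the default hazards
#'
#' Cumulative risks (probability, unrounded percent/100) of endometrial (EC)
#' and ovarian (OC) cancer from age 25 up to ages 40/50/60/70 in female
#' heterozygotes of each mismatch-repair gene, as reported by the Prospective
#' Lynch Syndrome Database, together with the pooled 10-year crude survival
#' after each cancer (EC 89%, OC 84%). These whole-percent figures anchor
#' [default_params()]: the generator's piecewise-constant annual hazards are
#' solved so that the analytic cumulative risk at each anchor age equals the
#' published value exactly.
#'
#' @return A data frame with columns `gene`, `endpoint`, `to_age`
#'   (40/50/60/70) and `risk` (probability of a first cancer of that organ in
#'   \[25, to_age) for a woman with the organ intact).
#' @seealso [default_params()], [analytic_interval_risk()]
#' @export
printed_interval_risks <- function() {
  anchor_age <- c(40, 50, 60, 70)
  ec <- list(
    MLH1 = c(0.02, 0.15, 0.27, 0.35),
    MSH2 = c(0.02, 0.18, 0.38, 0.47),
    MSH6 = c(0.02, 0.13, 0.28, 0.41),
    PMS2 = c(0.00, 0.00, 0.09, 0.13)
  )
  oc <- list(
    MLH1 = c(0.02, 0.06, 0.10, 0.11),
    MSH2 = c(0.02, 0.11, 0.13, 0.17),
    MSH6 = c(0.02, 0.02, 0.02, 0.11),
    PMS2 = c(0.00, 0.00, 0.03, 0.03)
  )
  rows <- lapply(GENES, function(g) {
    rbind(
      data.frame(gene = g, endpoint = "EC", to_age = anchor_age,
                 risk = ec[[g]], stringsAsFactors = FALSE),
      data.frame(gene = g, endpoint = "OC", to_age = anchor_age,
                 risk = oc[[g]], stringsAsFactors = FALSE)
    )
  })
  do.call(rbind, rows)
}

#' Pooled 10-year crude survival targets after gynecological cancer
#'
#' Ten-year Kaplan-Meier crude survival after endometrial (0.89) and ovarian
#' (0.84) cancer, pooled over genes and diagnosis ages. These are the default
#' calibration targets of the post-diagnosis survival model and the survival
#' column of the risk tables.
#'
#' @return Named numeric vector `c(EC = 0.89, OC = 0.84)`.
#' @export
survival_targets <- function() c(EC = 0.89, OC = 0.84)

## Solve piecewise-constant annual hazards on 5-year bins 25..70 (plus a
## 70-75 continuation bin) from cumulative-risk anchors at 40/50/60/70.
## Within each anchor segment the annual hazard h satisfies
## (1 - h)^years = (1 - Q_hi) / (1 - Q_lo), so the analytic cumulative risk
## reproduces every anchor exactly.
hazards_from_anchors <- function(anchors) {
  stopifnot(length(anchors) == 4, all(anchors >= 0), all(anchors < 1),
            !is.unsorted(anchors))
  q <- c(0, anchors)                      # Q at 25, 40, 50, 60, 70
  seg_years <- c(15, 10, 10, 10)
  h_seg <- 1 - ((1 - q[-1]) / (1 - q[-5]))^(1 / seg_years)
  bins <- c(rep(h_seg[1], 3),             # 25,30,35
            rep(h_seg[2], 2),             # 40,45
            rep(h_seg[3], 2),             # 50,55
            rep(h_seg[4], 2),             # 60,65
            h_seg[4])                     # 70-75 continues the 60-70 level
  setNames(bins, seq(25, 70, by = 5))
}

## Cure fraction making the mixture-cure survival model hit a 10-year
## survival target: S(t) = cure + (1 - cure) * exp(-t / scale).
cure_fraction_for_target <- function(target, scale = 3, horizon = 10) {
  stopifnot(target > 0, target < 1, scale > 0)
  e <- exp(-horizon / scale)
  cure <- unname((target - e) / (1 - e))
  if (cure < 0 || cure > 1) {
    stop("no cure fraction in [0,1] reaches the survival target; ",
         "adjust event_time_scale", call. = FALSE)
  }
  cure
}
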