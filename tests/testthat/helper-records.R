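## Build follow-up records in code; defaults give a valid uneventful record.
rec <- function(id = "W1", gene = "MLH1", age_inclusion = 30,
                age_last_obs = 40, age_hysterectomy = NA_real_,
                age_bso = NA_real_, age_ec_dx = NA_real_,
                age_oc_dx = NA_real_, age_death = NA_real_,
                died_of_followup_cancer = NA) {
  data.frame(id = id, gene = gene, age_inclusion = age_inclusion,
             age_last_obs = age_last_obs,
             age_hysterectomy = age_hysterectomy, age_bso = age_bso,
             age_ec_dx = age_ec_dx, age_oc_dx = age_oc_dx,
             age_death = age_death,
             died_of_followup_cancer = died_of_followup_cancer,
             stringsAsFactors = FALSE)
}

cohort_of <- function(...) {
  lynchrrs:::as_cohort(do.call(rbind, list(...)), strict = TRUE)
}

## params with hand-set hazards on top of the MLH1 defaults
params_with <- function(ec = NULL, oc = NULL, uptake = NULL, n = 100,
                        seed = 1, gene = "MLH1") {
  p <- default_params(gene, n = n, seed = seed)
  set_bins <- function(x) {
    stopifnot(length(x) %in% c(1, 10))
    stats::setNames(rep(x, length.out = 10), as.character(seq(25, 70, 5)))
  }
  if (!is.null(ec)) p$ec_hazard <- set_bins(ec)
  if (!is.null(oc)) p$oc_hazard <- set_bins(oc)
  if (!is.null(uptake)) p$surgery_uptake <- set_bins(uptake)
  p
}
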