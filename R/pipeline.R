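PIPELINE_KEYS <- c("genes", "n", "seed", "output_dir", "cohort_file",
                   "survival_source", "survival_targets",
                   "combined_censoring", "min_py")

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; format chosen by extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return A validated configuration list; see [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    x <- yaml::read_yaml(path)
    ## YAML 1.1 implicit typing turns a bare key `n` into boolean FALSE
    names(x)[names(x) == "FALSE"] <- "n"
    x
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  }
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(
    genes = GENES, n = 10000L, seed = 1L, output_dir = "lynchrrs-output",
    cohort_file = NULL, survival_source = "estimate",
    survival_targets = as.list(survival_targets()),
    combined_censoring = "both-organs", min_py = 10
  )
  cfg <- utils::modifyList(defaults, cfg)
  bad <- setdiff(cfg$genes, GENES)
  if (length(bad) > 0) {
    stop("unknown gene(s) in configuration: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!cfg$survival_source %in% c("estimate", "fixed")) {
    stop("survival_source must be 'estimate' or 'fixed'", call. = FALSE)
  }
  st <- unlist(cfg$survival_targets)
  if (!all(c("EC", "OC") %in% names(st)) || any(st <= 0 | st >= 1)) {
    stop("survival_targets must give EC and OC probabilities in (0,1)",
         call. = FALSE)
  }
  cfg$n <- as.integer(cfg$n)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full risk analysis pipeline
#'
#' Chains simulate (or load) -> person-years/rates -> cumulative incidence
#' -> crude survival -> risk and benefit tables, writing every intermediate
#' artifact as plain CSV/JSON plus a `manifest.json` listing each output
#' file with its MD5 hash. The run is fully deterministic for a fixed
#' configuration and seed.
#'
#' Configuration keys (all optional): `genes` (subset of
#' MLH1/MSH2/MSH6/PMS2), `n` (women simulated per gene), `seed`,
#' `output_dir`, `cohort_file` (CSV to load instead of simulating),
#' `survival_source` (`"estimate"` = Kaplan-Meier on the cohort's cases,
#' pooled over genes; `"fixed"` = use `survival_targets`),
#' `survival_targets` (list with `EC`, `OC`), `combined_censoring`
#' (see [person_years()]), `min_py`.
#'
#' @param config configuration list, or path to a YAML/JSON file.
#' @return Invisibly, the manifest: list with `files` (name, md5), `log`
#'   and the resolved `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else validate_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  outputs <- character()
  save_csv <- function(df, name) {
    path <- file.path(cfg$output_dir, name)
    write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
  }
  save_json <- function(x, name) {
    path <- file.path(cfg$output_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs <<- c(outputs, path)
  }

  ## stage 1: cohorts
  cohorts <- list()
  for (g in cfg$genes) {
    if (!is.null(cfg$cohort_file)) {
      if (!file.exists(cfg$cohort_file)) {
        stop("cohort file not found: ", cfg$cohort_file, call. = FALSE)
      }
      full <- read_cohort(cfg$cohort_file)
      full$records <- full$records[full$records$gene == g, , drop = FALSE]
      cohorts[[g]] <- full
    } else {
      p <- default_params(g, n = cfg$n,
                          seed = cfg$seed + match(g, GENES))
      cohorts[[g]] <- generate_cohort(p)
    }
    note("cohort %s: %d records, %d rejected", g,
         nrow(cohorts[[g]]$records), nrow(cohorts[[g]]$rejected))
    path <- file.path(cfg$output_dir, sprintf("cohort_%s.csv", g))
    write_cohort(cohorts[[g]], path)
    outputs <- c(outputs, path)
  }

  ## stage 2-3: rates and cumulative incidence
  curves <- list()
  for (g in cfg$genes) {
    curves[[g]] <- list()
    for (ep in ENDPOINTS) {
      py <- person_years(cohorts[[g]], ep, g,
                         combined_censoring = cfg$combined_censoring)
      rates <- annual_incidence_rates(py, min_py = cfg$min_py)
      save_csv(rates, sprintf("rates_%s_%s.csv", g, ep))
      curves[[g]][[ep]] <- cumulative_incidence(rates)
      if (any(rates$unreliable)) {
        note("rates %s/%s: unreliable bin(s) %s", g, ep,
             paste(rates$bin_start[rates$unreliable], collapse = ","))
      }
      save_json(list(gene = g, endpoint = ep,
                     age = curves[[g]][[ep]]$age, q = curves[[g]][[ep]]$q),
                sprintf("cuminc_%s_%s.json", g, ep))
    }
  }

  ## stage 4: crude survival pooled across genes
  surv10 <- unlist(cfg$survival_targets)[c("EC", "OC")]
  surv_info <- list()
  for (ep in c("EC", "OC")) {
    cases <- do.call(rbind, lapply(cohorts, extract_cases, endpoint = ep))
    n_cases <- if (is.null(cases)) 0 else nrow(cases)
    if (cfg$survival_source == "estimate" && n_cases >= 10 &&
        max(cases$age_end - cases$age_dx) >= 10) {
      km <- kaplan_meier(cases)
      surv10[ep] <- survival_at(km, 10)
      surv_info[[ep]] <- list(source = "kaplan-meier", n_cases = n_cases,
                              s10 = surv10[[ep]])
    } else {
      surv_info[[ep]] <- list(source = "configured-target",
                              n_cases = n_cases, s10 = surv10[[ep]])
    }
    note("survival %s: S(10) = %.3f (%s, %d cases)", ep, surv10[[ep]],
         surv_info[[ep]]$source, n_cases)
  }
  save_json(surv_info, "survival.json")

  ## stage 5: tables
  for (g in cfg$genes) {
    save_csv(build_gene_table(curves[[g]]$EC, surv10[["EC"]]),
             sprintf("table_EC_%s.csv", g))
    save_csv(build_gene_table(curves[[g]]$OC, surv10[["OC"]]),
             sprintf("table_OC_%s.csv", g))
    save_csv(build_combined_table(curves[[g]]$EC, curves[[g]]$OC,
                                  curves[[g]]$EC_or_OC,
                                  ec_surv = surv10[["EC"]],
                                  oc_surv = surv10[["OC"]]),
             sprintf("table_combined_%s.csv", g))
  }

  manifest <- list(
    files = data.frame(
      name = basename(outputs),
      md5 = unname(tools::md5sum(outputs)),
      stringsAsFactors = FALSE
    ),
    log = log,
    config = cfg[!vapply(cfg, is.null, logical(1))]
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
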