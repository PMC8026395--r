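#' @name cohort
#' @title Prospective follow-up cohorts
#'
#' @description A cohort is one row per female heterozygote carrying a
#' pathogenic mismatch-repair variant, describing her prospective observation
#' window, risk-reducing surgeries, gynecological cancer events and vital
#' status. Ages are fractional years at 0.01-year resolution; missing
#' optional ages are `NA` (empty CSV cells).
#'
#' CSV column order: `id, gene, age_inclusion, age_last_obs,
#' age_hysterectomy, age_bso, age_ec_dx, age_oc_dx, age_death,
#' died_of_followup_cancer` (boolean written as `true`/`false`).
#'
#' Record invariants enforced by validation:
#' \itemize{
#'   \item inclusion age within \[25, 74\] (prospective registration window);
#'   \item at least one year of follow-up after inclusion;
#'   \item surgery and death ages within the observation window, and no
#'     surgery before inclusion (women with prior risk-reducing surgery are
#'     not eligible);
#'   \item an EC diagnosis strictly after hysterectomy, or an OC diagnosis
#'     strictly after BSO, is an error (a diagnosis at exactly the surgery
#'     age is valid: occult cancer found at surgery);
#'   \item a cancer age at or before inclusion is retained but flagged as a
#'     previous cancer; the record contributes no information for that
#'     endpoint downstream.
#' }
NULL

COHORT_COLUMNS <- c(
  "id", "gene", "age_inclusion", "age_last_obs", "age_hysterectomy",
  "age_bso", "age_ec_dx", "age_oc_dx", "age_death", "died_of_followup_cancer"
)

new_cohort <- function(records, rejected = NULL, provenance = list()) {
  if (is.null(rejected)) {
    rejected <- data.frame(
      id = character(), reason = character(), message = character(),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(records = records, rejected = rejected, provenance = provenance),
    class = "lynch_cohort"
  )
}

#' @export
print.lynch_cohort <- function(x, ...) {
  cat("Prospective Lynch syndrome follow-up cohort\n")
  cat("  records: ", nrow(x$records), "\n", sep = "")
  if (nrow(x$records) > 0) {
    cat("  genes:   ",
        paste(names(table(x$records$gene)), table(x$records$gene),
              sep = "=", collapse = ", "), "\n", sep = "")
    py <- sum(x$records$age_last_obs - x$records$age_inclusion)
    cat("  observation years: ", format(round(py, 1)), "\n", sep = "")
  }
  if (nrow(x$rejected) > 0) {
    cat("  rejected rows: ", nrow(x$rejected), " (see $rejected)\n", sep = "")
  }
  if (length(x$provenance) > 0) {
    cat("  provenance: ",
        paste(names(x$provenance), unlist(lapply(x$provenance, format)),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

## Validate one batch of parsed records. Returns the accepted records with
## previous-cancer flags added, plus a rejection report with machine-readable
## reason codes. Validation is total: every row is accepted or rejected.
validate_records <- function(df) {
  stopifnot(all(COHORT_COLUMNS %in% names(df)))
  n <- nrow(df)
  reasons <- vector("list", n)
  add <- function(i, code, msg) {
    reasons[[i]] <<- rbind(
      reasons[[i]],
      data.frame(id = as.character(df$id[i]), reason = code, message = msg,
                 stringsAsFactors = FALSE)
    )
  }
  in_window <- function(x, i) {
    !is.na(x) && (x < df$age_inclusion[i] || x > df$age_last_obs[i])
  }
  for (i in seq_len(n)) {
    if (is.na(df$id[i]) || !nzchar(df$id[i])) {
      add(i, "missing_id", "record id is missing")
    }
    if (is.na(df$gene[i]) || !df$gene[i] %in% GENES) {
      add(i, "unknown_gene",
          sprintf("unknown gene symbol '%s'; expected one of %s",
                  df$gene[i], paste(GENES, collapse = "/")))
    }
    ai <- df$age_inclusion[i]
    al <- df$age_last_obs[i]
    if (is.na(ai) || ai < 25 || ai > 74) {
      add(i, "inclusion_out_of_range", "inclusion age out of range [25,74]")
    }
    if (is.na(al) || is.na(ai) || al - ai < 1 - 1e-9) {
      add(i, "followup_too_short",
          "follow-up shorter than one year after inclusion")
    }
    if (is.na(ai) || is.na(al)) {
      reasons_i <- reasons[[i]]
      next  # window undefined; remaining checks need it
    }
    for (fld in c("age_hysterectomy", "age_bso", "age_death")) {
      if (in_window(df[[fld]][i], i)) {
        add(i, paste0(sub("age_", "", fld), "_outside_window"),
            sprintf("%s %.2f outside observation window [%.2f, %.2f]",
                    fld, df[[fld]][i], ai, al))
      }
    }
    for (fld in c("age_ec_dx", "age_oc_dx")) {
      x <- df[[fld]][i]
      if (!is.na(x) && x > al) {
        add(i, paste0(sub("age_", "", fld), "_after_last_obs"),
            sprintf("%s %.2f after last observation %.2f", fld, x, al))
      }
    }
    if (!is.na(df$age_ec_dx[i]) && !is.na(df$age_hysterectomy[i]) &&
        df$age_ec_dx[i] > df$age_hysterectomy[i] + 1e-9) {
      add(i, "ec_after_hysterectomy",
          "endometrial cancer diagnosed after hysterectomy")
    }
    if (!is.na(df$age_oc_dx[i]) && !is.na(df$age_bso[i]) &&
        df$age_oc_dx[i] > df$age_bso[i] + 1e-9) {
      add(i, "oc_after_bso", "ovarian cancer diagnosed after BSO")
    }
    if (isTRUE(df$died_of_followup_cancer[i]) &&
        (is.na(df$age_death[i]) ||
         (is.na(df$age_ec_dx[i]) && is.na(df$age_oc_dx[i])))) {
      add(i, "death_flag_without_event",
          "death-cause flag set without both a cancer event and a death age")
    }
  }
  dup <- duplicated(df$id)
  for (i in which(dup)) add(i, "duplicate_id",
                            sprintf("duplicate record id '%s'", df$id[i]))
  bad <- !vapply(reasons, is.null, logical(1))
  rejected <- if (any(bad)) do.call(rbind, reasons[bad]) else NULL
  ok <- df[!bad, , drop = FALSE]
  ## previous-cancer flags: a diagnosis at or before inclusion is excluded
  ## from incidence for that endpoint but the woman stays in the cohort
  ok$prev_ec <- !is.na(ok$age_ec_dx) & ok$age_ec_dx <= ok$age_inclusion
  ok$prev_oc <- !is.na(ok$age_oc_dx) & ok$age_oc_dx <= ok$age_inclusion
  rownames(ok) <- NULL
  list(records = ok, rejected = rejected)
}

parse_bool <- function(x) {
  out <- rep(NA, length(x))
  x <- tolower(trimws(as.character(x)))
  out[x %in% c("true", "t", "1")] <- TRUE
  out[x %in% c("false", "f", "0")] <- FALSE
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("unparseable boolean in died_of_followup_cancer, row(s) %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read a prospective follow-up cohort from CSV
#'
#' Reads, parses and validates follow-up records. Format problems (missing
#' columns, unparseable ages) are always fatal and name the offending row
#' and field. Invariant violations are dropped with a reason in
#' `$rejected` when `strict = FALSE`, or fatal when `strict = TRUE`.
#'
#' @param path path to a CSV file with the documented header (see [cohort]).
#' @param strict logical; if `TRUE` any invalid row aborts the read.
#' @return A `lynch_cohort`: list with `records` (validated data frame,
#'   including logical `prev_ec`/`prev_oc` previous-cancer flags),
#'   `rejected` (id, reason code, message) and `provenance`.
#' @seealso [write_cohort()], [generate_cohort()]
#' @export
#' @examples
#' demo <- system.file("extdata", "demo_cohort.csv", package = "lynchrrs")
#' cohort <- read_cohort(demo)
#' cohort
read_cohort <- function(path, strict = FALSE) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character())
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[COHORT_COLUMNS]
  num_fields <- setdiff(COHORT_COLUMNS, c("id", "gene",
                                          "died_of_followup_cancer"))
  df <- data.frame(id = trimws(raw$id), gene = trimws(raw$gene),
                   stringsAsFactors = FALSE)
  for (fld in num_fields) {
    x <- trimws(raw[[fld]])
    val <- suppressWarnings(as.numeric(x))
    bad <- nzchar(x) & is.na(val)
    if (any(bad)) {
      stop(sprintf("unparseable age in field '%s', row(s) %s", fld,
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    df[[fld]] <- round_age(val)
  }
  df$died_of_followup_cancer <- parse_bool(raw$died_of_followup_cancer)
  v <- validate_records(df)
  if (strict && !is.null(v$rejected)) {
    stop("invalid cohort rows (strict mode): ",
         paste(unique(sprintf("[%s] %s", v$rejected$id, v$rejected$message)),
               collapse = "; "), call. = FALSE)
  }
  new_cohort(v$records, v$rejected,
             provenance = list(source = path, read_at = format(Sys.time())))
}

#' Write a cohort to CSV
#'
#' Writes the validated records with the documented header. Missing optional
#' ages become empty cells, booleans `true`/`false`; a read of the written
#' file round-trips all fields exactly.
#'
#' @param cohort a `lynch_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "lynch_cohort"))
  df <- cohort$records[intersect(COHORT_COLUMNS, names(cohort$records))]
  out <- df
  for (fld in names(out)) {
    x <- df[[fld]]
    if (is.numeric(x)) {
      s <- ifelse(is.na(x), "", format(round_age(x), trim = TRUE,
                                       scientific = FALSE, drop0trailing = TRUE))
      out[[fld]] <- s
    } else if (is.logical(x)) {
      out[[fld]] <- ifelse(is.na(x), "", ifelse(x, "true", "false"))
    } else {
      out[[fld]] <- ifelse(is.na(x), "", as.character(x))
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

## Wrap an already-validated in-memory data frame (used by the simulator).
as_cohort <- function(df, provenance = list(), strict = TRUE) {
  v <- validate_records(df)
  if (strict && !is.null(v$rejected)) {
    stop("internal: generated records failed validation: ",
         paste(unique(v$rejected$message), collapse = "; "), call. = FALSE)
  }
  new_cohort(v$records, v$rejected, provenance)
}
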