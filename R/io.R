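#' Read and validate a cohort from delimited text
#'
#' Reads the patient and patient-day tables (CSV, one row per patient /
#' patient-day), validates them against the column dictionary, and returns
#' a typed bundle. Missing values are encoded as empty fields on disk;
#' on reading, empty categorical fields become the explicit `Unknown`
#' level and empty numeric fields become `NA`. The `comorbidity_codes`
#' column uses `none` for a patient with no qualifying comorbidity and an
#' empty field for comorbidity data being unavailable.
#'
#' Required patient columns: `patient_id`, `race`, `ethnicity`, `sex`,
#' `language`, `income_band`, `insurer`, `age_years`, `comorbidity_codes`.
#' Required patient-day columns: `patient_id`, `date` (ISO-8601),
#' `hospital`, `covid_unit`, and either `sofa_score` or the physiology
#' columns of [sofa_score()].
#'
#' @param patients_path,days_path Paths to the two CSV files.
#' @param config A [triage_config()] stored alongside the data in the
#'   bundle.
#' @return List of class `cohort_bundle`: `patients`, `patient_days`,
#'   `config`, `provenance`.
#' @export
read_cohort <- function(patients_path, days_path, config = triage_config()) {
  for (p in c(patients_path, days_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  patients <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  days <- utils::read.csv(days_path, stringsAsFactors = FALSE)

  need_pat <- c("patient_id", "race", "ethnicity", "sex", "language",
                "income_band", "insurer", "age_years", "comorbidity_codes")
  miss <- setdiff(need_pat, names(patients))
  if (length(miss)) {
    stop("patient table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  need_day <- c("patient_id", "date", "hospital", "covid_unit")
  miss <- setdiff(need_day, names(days))
  if (length(miss)) {
    stop("patient-day table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  phys <- c("pao2_fio2_ratio", "platelets", "bilirubin", "map_mmHg",
            "vasopressor", "gcs", "creatinine", "urine_output_mL_day")
  if (!"sofa_score" %in% names(days) && !any(phys %in% names(days))) {
    stop("patient-day table needs a sofa_score column or physiology columns",
         call. = FALSE)
  }

  if (anyDuplicated(patients$patient_id)) {
    dup <- patients$patient_id[duplicated(patients$patient_id)][1]
    stop("duplicate patient_id: ", dup, call. = FALSE)
  }
  key <- paste(days$patient_id, days$date)
  if (anyDuplicated(key)) {
    stop("duplicate patient-day: ", key[duplicated(key)][1], call. = FALSE)
  }
  orphan <- setdiff(days$patient_id, patients$patient_id)
  if (length(orphan)) {
    stop("patient-day rows reference absent patient(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }

  for (v in names(covariate_levels())) {
    if (v %in% names(patients)) {
      x <- as.character(patients[[v]])
      x[is.na(x) | !nzchar(x)] <- "Unknown"
      bad <- setdiff(unique(x), covariate_levels()[[v]])
      if (length(bad)) {
        stop(sprintf("patient column %s has unknown level(s): %s", v,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      patients[[v]] <- x
    }
  }
  # "none" = no qualifying comorbidity; empty field = data unavailable
  orig <- as.character(patients$comorbidity_codes)
  cc <- orig
  cc[is.na(orig) | !nzchar(orig)] <- NA
  cc[!is.na(orig) & orig == "none"] <- ""
  patients$comorbidity_codes <- cc
  patients$age_years <- as.numeric(patients$age_years)
  days$covid_unit <- as.logical(days$covid_unit)
  bad_h <- setdiff(unique(days$hospital), c("tertiary", "quaternary"))
  if (length(bad_h)) {
    stop("unknown hospital level(s): ", paste(bad_h, collapse = ", "),
         call. = FALSE)
  }
  if ("sofa_score" %in% names(days)) {
    s <- days$sofa_score
    if (any(!is.na(s) & (s < 0 | s > 24))) {
      stop("sofa_score out of [0, 24]", call. = FALSE)
    }
  }

  structure(list(patients = patients, patient_days = days, config = config,
                 provenance = list(patients_path = patients_path,
                                   days_path = days_path)),
            class = "cohort_bundle")
}

#' Write cohort tables as CSV
#'
#' Inverse of [read_cohort()]: missing values become empty fields and a
#' patient with no comorbidities is written as `none`, so a write-read
#' round trip reproduces the tables.
#'
#' @param cohort A `cohort_bundle` or `synth_cohort` (anything with
#'   `patients` and `patient_days`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  patients <- cohort$patients
  cc <- patients$comorbidity_codes
  cc[!is.na(cc) & !nzchar(cc)] <- "none"
  patients$comorbidity_codes <- cc
  paths <- c(patients = file.path(dir, "patients.csv"),
             patient_days = file.path(dir, "patient_days.csv"))
  utils::write.csv(patients, paths["patients"], row.names = FALSE, na = "")
  utils::write.csv(cohort$patient_days, paths["patient_days"],
                   row.names = FALSE, na = "")
  invisible(paths)
}

format_irr_ci <- function(irr, lo, hi, reference) {
  ifelse(reference, "1 [Reference]",
         sprintf("%.2f (%.2f-%.2f)", irr, lo, hi))
}

irr_report_table <- function(fit) {
  tab <- irr_table(fit)
  data.frame(covariate = tab$covariate, level = tab$level,
             irr_ci = format_irr_ci(tab$irr, tab$ci_lo, tab$ci_hi,
                                    tab$reference),
             p_value = ifelse(tab$reference, "NA", format_p(tab$p_value)))
}

#' Write the audit report files
#'
#' Writes a deterministic file set for a completed audit: the descriptive
#' comparison tables, one formatted IRR table per fitted model (IRRs to 2
#' decimals with the interval in `1.00 (0.89-1.12)` style, p-values to 2-3
#' decimals), the reprioritization tables, the exclusion log and a
#' human-readable summary.
#'
#' @param audit A [csc_audit()] object.
#' @param dir Destination directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(audit, dir) {
  stopifnot(inherits(audit, "csc_audit"))
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create destination: ", dir, call. = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  wr(audit$exclusions, "exclusion_log.csv")
  wr(audit$descriptives_max, "descriptives_max.csv")
  wr(audit$descriptives_min, "descriptives_min.csv")
  for (nm in names(audit$irr_fits)) {
    wr(irr_report_table(audit$irr_fits[[nm]]), paste0("irr_", nm, ".csv"))
  }
  for (nm in names(audit$sensitivity_fits)) {
    wr(irr_report_table(audit$sensitivity_fits[[nm]]),
       paste0("irr_sensitivity_", nm, ".csv"))
  }
  wr(audit$reprioritization_max, "reprioritization_max.csv")
  wr(audit$reprioritization_min, "reprioritization_min.csv")

  rpt <- file.path(dir, "report.txt")
  con <- file(rpt, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(audit)), con)
  paths <- c(paths, rpt)
  invisible(paths)
}

#' Save or load a triage configuration as YAML
#'
#' @param config A [triage_config()].
#' @param path File path.
#' @return `read_config()` returns a [triage_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "csc_config"))
  yaml::write_yaml(list(sofa_band_edges = config$sofa_band_edges,
                        group_map = config$group_map,
                        catalog = lapply(seq_len(nrow(config$catalog)),
                                         function(i) as.list(config$catalog[i, ]))),
                   path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  catalog <- do.call(rbind, lapply(raw$catalog, as.data.frame))
  triage_config(sofa_band_edges = unlist(raw$sofa_band_edges),
                group_map = unlist(raw$group_map),
                catalog = catalog)
}

# Structured one-line run log: command, seed, config hash.
log_run <- function(dir, command, seed, config_path = NULL) {
  hash <- if (!is.null(config_path) && file.exists(config_path)) {
    unname(tools::md5sum(config_path))
  } else "none"
  line <- sprintf("time=%s command=%s seed=%s config_md5=%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), command,
                  as.character(seed), hash)
  cat(line, "\n", file = file.path(dir, "run.log"), append = TRUE, sep = "")
  invisible(line)
}
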