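#' Default comorbidity catalog
#'
#' The conditions that carry longer-term-mortality points in the allocation
#' algorithm, each assigned to exactly one tier: `FIVE_YEAR` (expected to
#' reduce 5-year survival, 2 points) or `ONE_YEAR` (expected to reduce
#' 1-year survival, 4 points). The default catalog holds the six 5-year and
#' nine 1-year conditions of the institutional policy.
#'
#' @return Data frame with columns `code`, `label`, `tier`.
#' @export
#' @examples
#' table(comorbidity_catalog()$tier)
comorbidity_catalog <- function() {
  rbind(
    data.frame(
      code = c("moderate_dementia", "malignancy_lt10yr_survival",
               "nyha_iii_heart_failure", "moderate_lung_disease",
               "end_stage_kidney_disease", "severe_inoperable_cad"),
      label = c("Moderate dementia",
                "Malignancy with <10-year expected survival",
                "NYHA class III heart failure", "Moderate lung disease",
                "End-stage kidney disease",
                "Severe (inoperable) coronary artery disease"),
      tier = "FIVE_YEAR"
    ),
    data.frame(
      code = c("severe_dementia", "metastatic_stage_iv_cancer",
               "nyha_iv_heart_failure", "severe_lung_disease",
               "cirrhosis_meld_gt20", "tbi_gcs_motor_1", "severe_burns",
               "cardiac_arrest", "severe_immunocompromise"),
      label = c("Severe dementia", "Metastatic or stage IV cancer",
                "NYHA class IV heart failure", "Severe lung disease",
                "Cirrhosis with MELD score >20",
                "Traumatic brain injury with best GCS motor response of 1",
                "Severe burns",
                "Cardiac arrest (unwitnessed, recurrent, or trauma-related)",
                "Severe immunocompromised state"),
      tier = "ONE_YEAR"
    )
  )
}

#' Triage configuration
#'
#' Bundles the tunable pieces of the allocation algorithm: the SOFA-score
#' band edges that define SOFA points, the priority-score to priority-group
#' consolidation, and the comorbidity catalog. The defaults encode the
#' institutional policy: SOFA <6 / 6-8 / 9-11 / >=12 map to points 1-4, and
#' scores 1-3 / 4-5 / 6-8 collapse to groups 1-3.
#'
#' @param sofa_band_edges Increasing integer vector of lower edges of SOFA
#'   points bands 2..4; default `c(6, 9, 12)`.
#' @param group_map Integer vector of length 8 mapping priority score 1..8 to
#'   priority group; must be non-decreasing with values in 1..3.
#' @param catalog Comorbidity catalog data frame (`code`, `tier`).
#' @return List of class `csc_config`.
#' @export
triage_config <- function(sofa_band_edges = c(6, 9, 12),
                          group_map = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L),
                          catalog = comorbidity_catalog()) {
  if (length(sofa_band_edges) != 3 || is.unsorted(sofa_band_edges, strictly = TRUE)) {
    stop("sofa_band_edges must be 3 strictly increasing values", call. = FALSE)
  }
  if (length(group_map) != 8 || is.unsorted(group_map) ||
      any(!group_map %in% 1:3)) {
    stop("group_map must be a non-decreasing length-8 map into 1..3",
         call. = FALSE)
  }
  if (anyDuplicated(catalog$code)) {
    stop("comorbidity catalog codes must be unique", call. = FALSE)
  }
  if (any(!catalog$tier %in% c("FIVE_YEAR", "ONE_YEAR"))) {
    stop("catalog tiers must be FIVE_YEAR or ONE_YEAR", call. = FALSE)
  }
  structure(list(sofa_band_edges = as.integer(sofa_band_edges),
                 group_map = as.integer(group_map),
                 catalog = catalog),
            class = "csc_config")
}

#' SOFA points: the 1-4 banding of the daily SOFA score
#'
#' @param sofa_score Integer vector of SOFA scores in 0-24.
#' @param config A [triage_config()].
#' @return Integer vector of SOFA points (1 = SOFA <6, 2 = 6-8, 3 = 9-11,
#'   4 = >=12 under the default bands).
#' @export
#' @examples
#' sofa_points(c(4, 10, 24))
sofa_points <- function(sofa_score, config = triage_config()) {
  if (any(is.na(sofa_score) | sofa_score < 0 | sofa_score > 24)) {
    stop("sofa_score must be in [0, 24]", call. = FALSE)
  }
  edges <- config$sofa_band_edges
  as.integer(1L + (sofa_score >= edges[1]) + (sofa_score >= edges[2]) +
               (sofa_score >= edges[3]))
}

#' Comorbidity points under the single-allotment rule
#'
#' A patient receives 4 points if they carry at least one condition in the
#' 1-year tier, otherwise 2 points for at least one condition in the 5-year
#' tier, otherwise 0. Points are never summed across comorbidities: only the
#' single worst tier counts.
#'
#' @param codes A character vector of comorbidity codes for one patient, or
#'   a list of such vectors (one element per patient).
#' @param config A [triage_config()]; its catalog must contain every code.
#' @return Integer vector (one per patient) with values in 0, 2, 4.
#' @export
#' @examples
#' comorbidity_points("moderate_dementia")
#' comorbidity_points(list(character(0), c("moderate_dementia", "severe_burns")))
comorbidity_points <- function(codes, config = triage_config()) {
  if (!is.list(codes)) codes <- list(codes)
  catalog <- config$catalog
  tier <- stats::setNames(catalog$tier, catalog$code)
  vapply(codes, function(cc) {
    cc <- cc[!is.na(cc) & nzchar(cc)]
    if (length(cc) == 0) return(0L)
    unknown <- setdiff(cc, names(tier))
    if (length(unknown)) {
      stop("unknown comorbidity code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    tt <- tier[cc]
    if (any(tt == "ONE_YEAR")) 4L else if (any(tt == "FIVE_YEAR")) 2L else 0L
  }, integer(1))
}

#' Priority score: SOFA points plus comorbidity points
#'
#' @param sofa_pts Integer vector in 1-4.
#' @param comorbidity_pts Integer vector with values in 0, 2, 4.
#' @return Integer vector in 1-8 (1 = highest priority for resources,
#'   8 = lowest).
#' @export
#' @examples
#' priority_score(4, 4)
priority_score <- function(sofa_pts, comorbidity_pts) {
  if (any(!sofa_pts %in% 1:4)) stop("sofa_pts must be in 1..4", call. = FALSE)
  if (any(!comorbidity_pts %in% c(0L, 2L, 4L))) {
    stop("comorbidity_pts must be 0, 2 or 4", call. = FALSE)
  }
  as.integer(sofa_pts + comorbidity_pts)
}

#' Priority group: 3-level consolidation of the priority score
#'
#' @param score Integer vector of priority scores in 1-8.
#' @param config A [triage_config()]; `config$group_map` holds the mapping
#'   (default 1-3 to group 1, 4-5 to group 2, 6-8 to group 3).
#' @return Integer vector of priority groups in 1-3.
#' @export
#' @examples
#' priority_group(1:8)
priority_group <- function(score, config = triage_config()) {
  if (any(is.na(score) | !score %in% 1:8)) {
    stop("priority score must be in [1, 8]", call. = FALSE)
  }
  config$group_map[score]
}

#' SOFA-points-only triage group
#'
#' The comparator grouping that ignores comorbidities: SOFA points 1 and 2
#' map to groups 1 and 2; points 3 and 4 are combined in a single group 3.
#'
#' @param sofa_pts Integer vector in 1-4.
#' @return Integer vector in 1-3.
#' @export
#' @examples
#' sofa_only_group(1:4)
sofa_only_group <- function(sofa_pts) {
  if (any(!sofa_pts %in% 1:4)) stop("sofa_pts must be in 1..4", call. = FALSE)
  as.integer(pmin(sofa_pts, 3L))
}

#' Score a cohort: per patient-day triage results
#'
#' Computes, for every patient-day, the SOFA score (from raw physiology via
#' [sofa_score()] unless a precomputed `sofa_score` column is present, which
#' mirrors hospitals whose electronic record auto-calculates it), SOFA
#' points, comorbidity points, priority score and priority group.
#'
#' @param patients Patient table; must have `patient_id` and
#'   `comorbidity_codes` (semicolon-separated codes, `""` = none,
#'   `NA` = comorbidity data unavailable).
#' @param patient_days Patient-day table with `patient_id` and either
#'   `sofa_score` or the physiology columns of [sofa_score()].
#' @param config A [triage_config()].
#' @return `patient_days` with columns `sofa_score`, `sofa_points`,
#'   `comorbidity_points`, `priority_score`, `priority_group` appended.
#' @export
score_cohort <- function(patients, patient_days, config = triage_config()) {
  stopifnot(is.data.frame(patients), is.data.frame(patient_days))
  missing_pat <- setdiff(patient_days$patient_id, patients$patient_id)
  if (length(missing_pat)) {
    stop("patient-day rows reference absent patient(s): ",
         paste(utils::head(missing_pat, 5), collapse = ", "), call. = FALSE)
  }
  days <- patient_days
  if (!"sofa_score" %in% names(days)) {
    days$sofa_score <- sofa_score(days)$sofa_score
  }
  ok <- !is.na(days$sofa_score)
  days$sofa_points <- NA_integer_
  days$sofa_points[ok] <- sofa_points(days$sofa_score[ok], config)
  cpts <- comorbidity_points(split_codes(patients$comorbidity_codes), config)
  cpts[is.na(patients$comorbidity_codes)] <- NA_integer_
  days$comorbidity_points <- cpts[match(days$patient_id, patients$patient_id)]
  ok2 <- ok & !is.na(days$comorbidity_points)
  days$priority_score <- NA_integer_
  days$priority_score[ok2] <- priority_score(days$sofa_points[ok2],
                                             days$comorbidity_points[ok2])
  days$priority_group <- NA_integer_
  days$priority_group[ok2] <- priority_group(days$priority_score[ok2], config)
  days
}

# "a;b;c" -> c("a","b","c"); "" -> character(0); NA -> NA marker kept by caller
split_codes <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}
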