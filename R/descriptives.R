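#' Closed level sets for audit covariates
#'
#' @return Named list of the level vectors used for the categorical audit
#'   covariates; the first level of each is the regression reference.
#' @export
covariate_levels <- function() {
  list(
    race = c("White", "Black", "Asian", "Multiracial", "Unknown"),
    ethnicity = c("NonHispanic", "Hispanic", "Unknown"),
    sex = c("male", "female", "Unknown"),
    language = c("English", "Spanish", "Other", "Unknown"),
    income_band = c("<25k", "25-<50k", "50-<75k", ">=75k", "Unknown"),
    insurer = c("Medicare/Medicaid", "Commercial", "None", "Unknown"),
    hospital = c("tertiary", "quaternary")
  )
}

#' Chi-squared homogeneity test on a contingency table
#'
#' Pearson chi-squared without continuity correction, as used for the
#' baseline-characteristics comparisons. All-zero rows and columns are
#' dropped first; a table left with fewer than two rows or columns is
#' flagged as degenerate rather than crashing.
#'
#' @param counts Numeric matrix of counts (levels x groups).
#' @return List with `statistic`, `df`, `p_value`, `degenerate` (logical).
#' @export
#' @examples
#' group_chisq(matrix(c(10, 10, 10, 10), 2))
group_chisq <- function(counts) {
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, degenerate = FALSE)
}

#' Baseline-characteristics comparisons across priority groups
#'
#' Compares each covariate across the maximum (or minimum) priority groups:
#' chi-squared tests for categorical rows (with `Unknown` retained as an
#' explicit level, matching how the cohort table is laid out) and
#' Kruskal-Wallis tests for continuous rows (age, days of data). A second
#' column restricts each test to groups 3 vs 1.
#'
#' @param summaries Output of [summarize_patients()].
#' @param covariates Patient-level covariate table (see
#'   [patient_covariates()]).
#' @param grouping `"max"` or `"min"`: which extremum of the priority group
#'   defines the columns.
#' @return Data frame with one row per characteristic: `characteristic`,
#'   `type`, `p_all_groups`, `p_group3_vs_1`, `degenerate`.
#' @export
descriptive_tests <- function(summaries, covariates, grouping = c("max", "min")) {
  grouping <- match.arg(grouping)
  dat <- merge(summaries, covariates, by = "patient_id")
  grp <- dat[[paste0(grouping, "_priority_group")]]
  if (length(unique(grp)) < 2) {
    stop("need at least 2 non-empty priority groups", call. = FALSE)
  }
  lv <- covariate_levels()
  cat_vars <- c(names(lv), "covid_unit", "comorb_5yr", "comorb_1yr")
  cat_vars <- intersect(cat_vars, names(dat))
  num_vars <- intersect(c("age_years", "n_days"), names(dat))

  rows <- lapply(cat_vars, function(v) {
    x <- dat[[v]]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    if (v %in% names(lv)) x <- factor(x, levels = lv[[v]])
    tab <- table(x, grp)
    all_g <- group_chisq(tab)
    sub <- tab[, colnames(tab) %in% c("1", "3"), drop = FALSE]
    pair <- if (ncol(sub) == 2) group_chisq(sub) else
      list(p_value = NA_real_, degenerate = TRUE)
    data.frame(characteristic = v, type = "categorical",
               p_all_groups = all_g$p_value, p_group3_vs_1 = pair$p_value,
               degenerate = all_g$degenerate || pair$degenerate)
  })
  rows_num <- lapply(num_vars, function(v) {
    x <- dat[[v]]
    ok <- !is.na(x)
    p_all <- tryCatch(stats::kruskal.test(x[ok], factor(grp[ok]))$p.value,
                      error = function(e) NA_real_)
    in13 <- ok & grp %in% c(1, 3)
    p_13 <- if (length(unique(grp[in13])) == 2) {
      tryCatch(stats::kruskal.test(x[in13], factor(grp[in13]))$p.value,
               error = function(e) NA_real_)
    } else NA_real_
    data.frame(characteristic = v, type = "continuous",
               p_all_groups = p_all, p_group3_vs_1 = p_13,
               degenerate = is.na(p_all))
  })
  out <- do.call(rbind, c(rows, rows_num))
  rownames(out) <- NULL
  out
}
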