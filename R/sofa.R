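#' Default SOFA cut-point table
#'
#' Returns the cut-points of the standard Sequential Organ Failure Assessment
#' (SOFA) score as an editable list, one element per organ system. Each
#' element is a data frame with columns `score` (the subscore awarded) and
#' the threshold(s) that trigger it. Passing a modified copy to
#' [sofa_score()] swaps in a different SOFA dialect without touching code.
#'
#' Conventions encoded here (the ones used at the bedside):
#' * respiratory: PaO2/FiO2 bands 400/300/200/100; subscores 3 and 4 are
#'   only awarded while the patient is on invasive or noninvasive
#'   respiratory support, otherwise a ratio below 200 caps at 2;
#' * coagulation: platelet bands at-or-below 150/100/50/20 (10^3/uL);
#' * liver: bilirubin bands 1.2/2.0/6.0/12.0 (mg/dL);
#' * cardiovascular: MAP < 70 mmHg scores 1; vasopressor categories score
#'   2-4 regardless of MAP;
#' * cns: Glasgow Coma Scale bands 13-14 / 10-12 / 6-9 / <6;
#' * renal: creatinine bands 1.2/2.0/3.5/5.0 (mg/dL), or urine output
#'   < 500 / < 200 mL/day; the worse of the two applies.
#'
#' @return Named list with elements `respiratory`, `coagulation`, `liver`,
#'   `cardiovascular`, `cns`, `renal`.
#' @export
#' @examples
#' cp <- sofa_cutpoints()
#' cp$coagulation
sofa_cutpoints <- function() {
  list(
    respiratory = data.frame(
      score = 1:4,
      pf_below = c(400, 300, 200, 100),
      support_required = c(FALSE, FALSE, TRUE, TRUE)
    ),
    coagulation = data.frame(score = 1:4, platelets_at_most = c(150, 100, 50, 20)),
    liver = data.frame(score = 1:4, bilirubin_at_least = c(1.2, 2, 6, 12)),
    cardiovascular = data.frame(
      score = 1:4,
      trigger = c("map_below_70", "vasopressor_low", "vasopressor_mid",
                  "vasopressor_high")
    ),
    cns = data.frame(score = 1:4, gcs_at_most = c(14, 12, 9, 5)),
    renal = data.frame(
      score = 1:4,
      creatinine_at_least = c(1.2, 2, 3.5, 5),
      urine_below = c(NA, NA, 500, 200)
    )
  )
}

#' @rdname sofa_score
#' @export
sofa_systems <- function() {
  c("respiratory", "coagulation", "liver", "cardiovascular", "cns", "renal")
}

#' Vasopressor intensity categories
#'
#' Levels of the vasopressor field accepted by the SOFA cardiovascular
#' subscore, in increasing intensity: `none`; `dopamine_low_or_dobutamine`
#' (dopamine <= 5 ug/kg/min or any dobutamine, subscore 2);
#' `dopamine_mid_or_epi_norepi_low` (dopamine > 5, or epinephrine or
#' norepinephrine <= 0.1, subscore 3); `dopamine_high_or_epi_norepi_high`
#' (dopamine > 15, or epinephrine or norepinephrine > 0.1, subscore 4).
#'
#' @return Character vector of the four levels.
#' @export
vasopressor_levels <- function() {
  c("none", "dopamine_low_or_dobutamine", "dopamine_mid_or_epi_norepi_low",
    "dopamine_high_or_epi_norepi_high")
}

# Ensure a SOFA input table has every expected column (filled with NA when
# absent) and passes range checks.
normalize_sofa_inputs <- function(inputs) {
  cols <- c("pao2_fio2_ratio", "on_respiratory_support", "platelets",
            "bilirubin", "map_mmHg", "vasopressor", "gcs", "creatinine",
            "urine_output_mL_day")
  inputs <- as.data.frame(inputs)
  for (col in cols) {
    if (!col %in% names(inputs)) inputs[[col]] <- NA
  }
  gcs <- inputs$gcs
  if (any(!is.na(gcs) & (gcs < 3 | gcs > 15))) {
    stop("gcs must be in [3, 15]", call. = FALSE)
  }
  for (col in c("pao2_fio2_ratio", "platelets", "bilirubin", "map_mmHg",
                "creatinine", "urine_output_mL_day")) {
    if (any(!is.na(inputs[[col]]) & inputs[[col]] < 0)) {
      stop(sprintf("%s must be non-negative", col), call. = FALSE)
    }
  }
  vp <- inputs$vasopressor
  if (is.character(vp)) {
    vp[!is.na(vp) & !nzchar(vp)] <- NA  # empty CSV field = not recorded
    inputs$vasopressor <- vp
  }
  if (any(!is.na(vp) & !vp %in% vasopressor_levels())) {
    bad <- unique(vp[!is.na(vp) & !vp %in% vasopressor_levels()])
    stop("unknown vasopressor level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  inputs
}

#' Compute one SOFA organ-system subscore
#'
#' @param system One of [sofa_systems()].
#' @param inputs Data frame (or list coercible to one) of physiologic inputs;
#'   see [sofa_score()] for the column dictionary. Absent columns are treated
#'   as missing.
#' @param cutpoints Cut-point table, default [sofa_cutpoints()].
#' @return Integer vector of subscores in 0-4, one per row of `inputs`.
#'   A row whose inputs for the system are all missing scores 0.
#' @export
#' @examples
#' sofa_subscore("coagulation", data.frame(platelets = 100))
sofa_subscore <- function(system, inputs, cutpoints = sofa_cutpoints()) {
  if (!system %in% sofa_systems()) {
    stop("unknown organ system: ", system, call. = FALSE)
  }
  inputs <- normalize_sofa_inputs(inputs)
  subscore_one_system(system, inputs, cutpoints)
}

subscore_one_system <- function(system, inputs, cutpoints) {
  n <- nrow(inputs)
  score <- integer(n)
  cp <- cutpoints[[system]]
  switch(system,
    respiratory = {
      pf <- inputs$pao2_fio2_ratio
      support <- !is.na(inputs$on_respiratory_support) &
        as.logical(inputs$on_respiratory_support)
      for (i in seq_len(nrow(cp))) {
        hit <- !is.na(pf) & pf < cp$pf_below[i] &
          (!cp$support_required[i] | support)
        score[hit] <- cp$score[i]
      }
    },
    coagulation = {
      plt <- inputs$platelets
      for (i in seq_len(nrow(cp))) {
        score[!is.na(plt) & plt <= cp$platelets_at_most[i]] <- cp$score[i]
      }
    },
    liver = {
      bili <- inputs$bilirubin
      for (i in seq_len(nrow(cp))) {
        score[!is.na(bili) & bili >= cp$bilirubin_at_least[i]] <- cp$score[i]
      }
    },
    cardiovascular = {
      map <- inputs$map_mmHg
      vp <- inputs$vasopressor
      score[!is.na(map) & map < 70] <- 1L
      vp_score <- c(none = 0L, dopamine_low_or_dobutamine = 2L,
                    dopamine_mid_or_epi_norepi_low = 3L,
                    dopamine_high_or_epi_norepi_high = 4L)
      has_vp <- !is.na(vp)
      score[has_vp] <- pmax(score[has_vp], vp_score[vp[has_vp]])
    },
    cns = {
      gcs <- inputs$gcs
      for (i in seq_len(nrow(cp))) {
        score[!is.na(gcs) & gcs <= cp$gcs_at_most[i]] <- cp$score[i]
      }
    },
    renal = {
      creat <- inputs$creatinine
      urine <- inputs$urine_output_mL_day
      cr_score <- integer(n)
      for (i in seq_len(nrow(cp))) {
        cr_score[!is.na(creat) & creat >= cp$creatinine_at_least[i]] <-
          cp$score[i]
      }
      uo_score <- integer(n)
      for (i in seq_len(nrow(cp))) {
        if (!is.na(cp$urine_below[i])) {
          uo_score[!is.na(urine) & urine < cp$urine_below[i]] <- cp$score[i]
        }
      }
      score <- pmax(cr_score, uo_score)
    }
  )
  as.integer(score)
}

# Columns that determine whether a system is observed at all. The
# respiratory support flag and urine output are modifiers, not primary
# measurements; vasopressor alone counts for cardiovascular.
system_primary_cols <- function() {
  list(
    respiratory = "pao2_fio2_ratio",
    coagulation = "platelets",
    liver = "bilirubin",
    cardiovascular = c("map_mmHg", "vasopressor"),
    cns = "gcs",
    renal = c("creatinine", "urine_output_mL_day")
  )
}

#' Compute daily SOFA scores
#'
#' Computes the six organ-system subscores and the total Sequential Organ
#' Failure Assessment score (0-24) for each row of a patient-day input table.
#' A system whose inputs are all missing contributes 0 (missingness is
#' counted, not imputed as worst case), so totals are conservative; callers
#' can filter on `n_missing_components`.
#'
#' Column dictionary for `inputs` (all optional; absent columns = missing):
#' `pao2_fio2_ratio` (mmHg ratio), `on_respiratory_support` (logical,
#' invasive or noninvasive ventilation), `platelets` (10^3/uL), `bilirubin`
#' (mg/dL), `map_mmHg` (mean arterial pressure), `vasopressor` (one of
#' [vasopressor_levels()]), `gcs` (Glasgow Coma Scale, 3-15), `creatinine`
#' (mg/dL), `urine_output_mL_day` (mL/24h).
#'
#' @inheritParams sofa_subscore
#' @return Data frame with one row per input row: the six subscore columns,
#'   `sofa_score` (their sum) and `n_missing_components` (0-6).
#' @export
#' @examples
#' sofa_score(data.frame(platelets = 100, gcs = 15))
sofa_score <- function(inputs, cutpoints = sofa_cutpoints()) {
  inputs <- normalize_sofa_inputs(inputs)
  systems <- sofa_systems()
  out <- data.frame(row.names = seq_len(nrow(inputs)))
  primary <- system_primary_cols()
  n_missing <- integer(nrow(inputs))
  for (sys in systems) {
    out[[sys]] <- subscore_one_system(sys, inputs, cutpoints)
    obs <- Reduce(`|`, lapply(primary[[sys]], function(col) !is.na(inputs[[col]])))
    n_missing <- n_missing + !obs
  }
  out$sofa_score <- as.integer(rowSums(out[systems]))
  out$n_missing_components <- n_missing
  rownames(out) <- NULL
  out
}
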