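#' Multivariable Poisson model for triage-priority disparities
#'
#' Fits a Poisson regression (log link) of one per-patient triage outcome on
#' race, ethnicity, sex, preferred language, zip-code income band, primary
#' insurer, age (continuous), COVID-unit admission and hospital, with race
#' and ethnicity in the same model so each is adjusted for the other.
#' Exponentiated coefficients are reported as incidence rate ratios (IRRs)
#' with Wald 95% confidence intervals.
#'
#' Three analysis variants are supported:
#' * `complete_case` (primary): patients with any `Unknown` or missing model
#'   covariate are dropped;
#' * `unknown_category`: no patients dropped; `Unknown` is retained as an
#'   explicit level of every categorical covariate (patients missing the
#'   continuous age are still dropped);
#' * `no_ses`: complete cases, but income band and insurer — covariates that
#'   may themselves track with race and ethnicity — are removed from the
#'   model.
#'
#' Because scores bounded in 1-8 are not true counts, model-based (Poisson
#' likelihood) standard errors can misstate uncertainty; a robust sandwich
#' variance is therefore always computed alongside and both flavors are kept
#' in the fitted object. `robust` selects which one the reported IRR table
#' uses.
#'
#' @param summaries Output of [summarize_patients()].
#' @param covariates Patient-level covariate table, see
#'   [patient_covariates()].
#' @param outcome One of the 8 outcome columns of `summaries`
#'   (`"max_priority_score"`, `"min_priority_score"`, `"max_priority_group"`,
#'   `"min_priority_group"`, `"max_sofa_score"`, `"min_sofa_score"`,
#'   `"max_sofa_points"`, `"min_sofa_points"`).
#' @param analysis Analysis variant, see above.
#' @param robust Logical: report sandwich (HC0) standard errors instead of
#'   model-based ones in the IRR table.
#' @return Object of class `csc_irr` (extending `glm`); see [irr_table()],
#'   `print()`, `summary()`, `coef()`, `confint()`.
#' @export
fit_irr <- function(summaries, covariates,
                    outcome = "max_priority_score",
                    analysis = c("complete_case", "unknown_category", "no_ses"),
                    robust = FALSE) {
  analysis <- match.arg(analysis)
  if (!outcome %in% names(summaries)) {
    stop("unknown outcome column: ", outcome, call. = FALSE)
  }
  dat <- merge(summaries, covariates, by = "patient_id")
  cat_vars <- c("race", "ethnicity", "sex", "language", "income_band",
                "insurer", "hospital")
  if (analysis == "no_ses") cat_vars <- setdiff(cat_vars, c("income_band", "insurer"))
  lv <- covariate_levels()

  for (v in cat_vars) {
    x <- as.character(dat[[v]])
    x[is.na(x)] <- "Unknown"
    dat[[v]] <- x
  }
  if (analysis == "unknown_category") {
    keep <- !is.na(dat$age_years)
  } else {
    unknown_any <- Reduce(`|`, lapply(cat_vars, function(v) dat[[v]] == "Unknown"))
    keep <- !unknown_any & !is.na(dat$age_years)
  }
  dropped <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  if (nrow(dat) == 0) stop("no patients left after filtering", call. = FALSE)

  for (v in cat_vars) {
    levels_v <- lv[[v]]
    if (analysis != "unknown_category") levels_v <- setdiff(levels_v, "Unknown")
    empty <- setdiff(intersect(levels_v, lv[[v]]), unique(dat[[v]]))
    empty <- setdiff(empty, "Unknown")
    if (length(empty)) {
      warning(sprintf("%s: level(s) %s empty after filtering; dropped", v,
                      paste(empty, collapse = ", ")), call. = FALSE)
    }
    dat[[v]] <- factor(dat[[v]], levels = intersect(levels_v, unique(dat[[v]])))
  }
  dat$covid_unit <- as.logical(dat$covid_unit)

  rhs <- c(cat_vars, "age_years", "covid_unit")
  fml <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- stats::glm(fml, data = dat, family = stats::poisson())

  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("perfectly collinear covariate terms: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  fit$robust_vcov <- sandwich::vcovHC(fit, type = "HC0")
  fit$analysis <- analysis
  fit$outcome <- outcome
  fit$robust <- robust
  fit$n_dropped <- dropped
  class(fit) <- c("csc_irr", class(fit))
  fit
}

#' IRR table of a fitted disparity model
#'
#' @param fit A [fit_irr()] object.
#' @param robust Logical; default is the flavor chosen at fit time.
#' @return Data frame with one row per covariate level: `covariate`,
#'   `level`, `reference` (logical), `irr`, `ci_lo`, `ci_hi`, `p_value`.
#'   Reference levels carry `irr = 1` and no interval.
#' @export
irr_table <- function(fit, robust = fit$robust) {
  stopifnot(inherits(fit, "csc_irr"))
  beta <- stats::coef(fit)
  vc <- if (robust) fit$robust_vcov else stats::vcov(fit)
  se <- sqrt(diag(vc))[names(beta)]
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  lo <- exp(beta - stats::qnorm(0.975) * se)
  hi <- exp(beta + stats::qnorm(0.975) * se)

  mf <- stats::model.frame(fit)
  rows <- list()
  for (v in attr(stats::terms(fit), "term.labels")) {
    x <- mf[[v]]
    if (is.factor(x)) {
      lvs <- levels(x)
      rows[[length(rows) + 1]] <- data.frame(
        covariate = v, level = lvs[1], reference = TRUE,
        irr = 1, ci_lo = NA_real_, ci_hi = NA_real_, p_value = NA_real_)
      for (l in lvs[-1]) {
        nm <- paste0(v, l)
        rows[[length(rows) + 1]] <- data.frame(
          covariate = v, level = l, reference = FALSE,
          irr = exp(beta[[nm]]), ci_lo = lo[[nm]], ci_hi = hi[[nm]],
          p_value = p[[nm]])
      }
    } else {
      nm <- if (is.logical(x)) paste0(v, "TRUE") else v
      rows[[length(rows) + 1]] <- data.frame(
        covariate = v, level = if (is.logical(x)) "TRUE" else "",
        reference = FALSE, irr = exp(beta[[nm]]), ci_lo = lo[[nm]],
        ci_hi = hi[[nm]], p_value = p[[nm]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.csc_irr <- function(x, ...) {
  cat(sprintf("Poisson disparity model (%s) for outcome '%s'\n",
              x$analysis, x$outcome))
  cat(sprintf("  n = %d patients (%d excluded by filtering); %s standard errors\n",
              stats::nobs(x), x$n_dropped,
              if (x$robust) "robust (HC0)" else "model-based"))
  tab <- irr_table(x)
  tab$irr <- sprintf("%.2f", tab$irr)
  tab$ci <- ifelse(tab$reference, "[Reference]",
                   sprintf("(%.2f-%.2f)", tab$ci_lo, tab$ci_hi))
  tab$p <- ifelse(tab$reference, "", format_p(tab$p_value))
  print(tab[c("covariate", "level", "irr", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.csc_irr <- function(object, ...) {
  out <- list(outcome = object$outcome, analysis = object$analysis,
              n = stats::nobs(object), n_dropped = object$n_dropped,
              irr_model_se = irr_table(object, robust = FALSE),
              irr_robust_se = irr_table(object, robust = TRUE))
  class(out) <- "summary.csc_irr"
  out
}

#' @export
print.summary.csc_irr <- function(x, ...) {
  cat(sprintf("Outcome '%s', %s analysis, n = %d (%d excluded)\n",
              x$outcome, x$analysis, x$n, x$n_dropped))
  cat("\nModel-based SEs:\n")
  print(x$irr_model_se, row.names = FALSE, digits = 3)
  cat("\nRobust (HC0) SEs:\n")
  print(x$irr_robust_se, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Wald confidence intervals on the IRR scale
#'
#' @param object A [fit_irr()] object.
#' @param parm Coefficient names (default all).
#' @param level Confidence level.
#' @param robust Use sandwich standard errors.
#' @param ... Unused.
#' @return Matrix of exponentiated Wald interval bounds.
#' @export
confint.csc_irr <- function(object, parm = NULL, level = 0.95,
                            robust = object$robust, ...) {
  beta <- stats::coef(object)
  vc <- if (robust) object$robust_vcov else stats::vcov(object)
  se <- sqrt(diag(vc))[names(beta)]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(exp(beta - zq * se), exp(beta + zq * se))
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "<.001",
                ifelse(p < 0.01, sub("^0", "", sprintf("%.3f", p)),
                       sub("^0", "", sprintf("%.2f", p)))))
}
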