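#' Tiebreak comparison between two candidates
#'
#' Implements the policy's cascade for ordering two candidates for a scarce
#' resource: priority group first, then absence of a comorbidity known to
#' affect short-term recovery, then age (younger first), then provision of
#' an essential function within health care, then the actual priority score
#' (1-8). A residual tie is returned as `"tie"`; the lottery that resolves
#' it belongs to the caller (see [allocate()]).
#'
#' @param a,b Lists (or one-row data frames) with fields `priority_group`,
#'   `priority_score`, and optionally `short_term_recovery_comorbidity`,
#'   `age_years`, `essential_function`. Missing flags default to `FALSE`;
#'   missing age compares as oldest.
#' @return `"a_first"`, `"b_first"` or `"tie"`.
#' @export
#' @examples
#' tiebreak_compare(list(priority_group = 1, priority_score = 2),
#'                  list(priority_group = 2, priority_score = 4))
tiebreak_compare <- function(a, b) {
  ka <- tiebreak_key(as.list(a))
  kb <- tiebreak_key(as.list(b))
  for (i in seq_along(ka)) {
    if (ka[i] < kb[i]) return("a_first")
    if (ka[i] > kb[i]) return("b_first")
  }
  "tie"
}

# Numeric sort key encoding the cascade; smaller = allocated earlier.
tiebreak_key <- function(p) {
  flag <- function(x) if (is.null(x) || is.na(x)) FALSE else as.logical(x)
  age <- p$age_years
  if (is.null(age) || is.na(age)) age <- Inf
  c(group = as.numeric(p$priority_group),
    short_term = as.numeric(flag(p$short_term_recovery_comorbidity)),
    age = as.numeric(age),
    essential = as.numeric(!flag(p$essential_function)),
    score = as.numeric(p$priority_score))
}

#' Allocate scarce resources across one cohort-day
#'
#' Produces a total allocation order consistent with [tiebreak_compare()],
#' breaking residual ties by a uniform lottery driven by `seed`, and
#' allocates the first `n_resources` patients.
#'
#' @param cohort_day Data frame with one row per candidate: `patient_id`,
#'   `priority_group`, `priority_score`, and optionally the tiebreak fields
#'   of [tiebreak_compare()].
#' @param n_resources Non-negative integer number of resources available.
#' @param seed Integer seed for the lottery; a fixed seed makes the
#'   allocation reproducible.
#' @return `cohort_day` reordered by allocation rank, with columns `rank`
#'   and `allocated` (logical) appended.
#' @export
allocate <- function(cohort_day, n_resources, seed = 1L) {
  stopifnot(is.data.frame(cohort_day))
  if (length(n_resources) != 1 || is.na(n_resources) || n_resources < 0) {
    stop("n_resources must be a non-negative integer", call. = FALSE)
  }
  n <- nrow(cohort_day)
  keys <- t(vapply(seq_len(n),
                   function(i) tiebreak_key(as.list(cohort_day[i, ])),
                   numeric(5)))
  lottery <- with_seed(as.integer(seed), stats::runif(n))
  ord <- do.call(order, c(lapply(seq_len(ncol(keys)), function(j) keys[, j]),
                          list(lottery)))
  out <- cohort_day[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  out$allocated <- out$rank <= n_resources
  rownames(out) <- NULL
  out
}

# Run code under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
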