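# Statin initiation strategies: threshold eligibility, annual screening,
# first-year discontinuation, treatment effects.

#' Define a statin initiation strategy
#'
#' A strategy initiates moderate-intensity statin therapy when an untreated,
#' event-free individual's 10-year ASCVD risk reaches the threshold
#' (inclusive `>=`), or when any optional direct-initiation rule fires.
#' Initiators face a one-off discontinuation draw at the end of their first
#' treated year (default 40%); survivors of that draw adhere for life, and
#' discontinuation is absorbing.
#'
#' @param name strategy label (unique within a comparison).
#' @param threshold 10-year-risk initiation threshold in `(0, 1]`, or `NULL`
#'   for the no-treatment strategy.
#' @param discontinuation probability of stopping at the end of the first
#'   treated year, in `[0, 1]`.
#' @param rules optional list of direct-initiation predicates, each a
#'   `function(cohort)` returning a logical vector (e.g. very high LDL-C).
#'   Default empty: the strategy is a pure risk threshold.
#' @param intensity treatment intensity tag; only `"moderate"` is modelled.
#' @return an object of class `strategy`.
#' @export
strategy <- function(name, threshold = NULL, discontinuation = 0.40,
                     rules = list(), intensity = "moderate") {
  if (!is.null(threshold)) {
    stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  }
  stopifnot(is.numeric(discontinuation),
            discontinuation >= 0, discontinuation <= 1,
            identical(intensity, "moderate"))
  structure(list(name = name, threshold = threshold,
                 discontinuation = discontinuation, rules = rules,
                 intensity = intensity),
            class = "strategy")
}

#' The four compared strategies
#'
#' No treatment and initiation at 10-year ASCVD risk thresholds of 15%,
#' 10% (the guideline threshold) and 7.5%, each with 40% first-year
#' discontinuation.
#'
#' @return named list of [strategy()] objects.
#' @export
preset_strategies <- function() {
  list(
    no_treatment  = strategy("no_treatment", threshold = NULL),
    threshold_15  = strategy("threshold_15", threshold = 0.15),
    guideline_10  = strategy("guideline_10", threshold = 0.10),
    threshold_7.5 = strategy("threshold_7.5", threshold = 0.075)
  )
}

#' Screen a cohort for statin eligibility
#'
#' An individual is eligible iff alive, event-free, never treated, and their
#' 10-year ASCVD risk is `>=` the strategy threshold or a direct-initiation
#' rule fires. The no-treatment strategy is never eligible. Rows outside the
#' screening population (dead, post-event, already treated or discontinued)
#' return `FALSE`.
#'
#' @param cohort a `cohort` data frame.
#' @param strategy a [strategy()].
#' @param coef a [risk_coefficients()] object.
#' @return logical vector, one element per row.
#' @export
is_eligible <- function(cohort, strategy, coef) {
  stopifnot(inherits(strategy, "strategy"))
  n <- nrow(cohort)
  screenable <- cohort$state == "event_free" & cohort$treat == "never"
  out <- logical(n)
  if (!any(screenable)) return(out)
  sub <- cohort[screenable, , drop = FALSE]
  elig <- logical(nrow(sub))
  if (!is.null(strategy$threshold)) {
    # inclusive threshold; epsilon keeps exact ties eligible despite
    # floating-point rounding in the risk equation
    elig <- ten_year_ascvd_risk(sub, coef) >= strategy$threshold - 1e-9
  }
  for (rule in strategy$rules) {
    elig <- elig | rule(sub)
  }
  out[screenable] <- elig
  out
}

#' Update treatment state for one cycle
#'
#' Never-treated, eligible individuals initiate (`on_statin`). Individuals
#' completing their first treated year (`treat_years == 1`) face the one-off
#' discontinuation draw: `u < discontinuation` moves them to `discontinued`
#' (absorbing, no further cost or effect); otherwise they stay on statins
#' for life. All other rows pass through unchanged.
#'
#' @param cohort a `cohort` data frame, all rows alive.
#' @param strategy a [strategy()].
#' @param u uniform draw(s) in `[0, 1)`, recycled to `nrow(cohort)`.
#' @param eligible logical vector from [is_eligible()] (or `FALSE` when the
#'   call is only resolving discontinuation).
#' @return the updated cohort.
#' @export
update_treatment_state <- function(cohort, strategy, u, eligible = FALSE) {
  stopifnot(inherits(strategy, "strategy"))
  if (any(cohort$state == "dead")) {
    stop("cannot update treatment state of a dead individual", call. = FALSE)
  }
  n <- nrow(cohort)
  u <- rep_len(u, n)
  eligible <- rep_len(eligible, n)
  start <- cohort$treat == "never" & eligible
  cohort$treat[start] <- "on_statin"
  cohort$treat_years[start] <- 0L
  ending_first_year <- cohort$treat == "on_statin" & cohort$treat_years == 1L
  stop_now <- ending_first_year & u < strategy$discontinuation
  cohort$treat[stop_now] <- "discontinued"
  # survivors of the draw are marked adherent-for-life by treat_years > 1
  cohort
}

#' Apply statin treatment effects to annual probabilities
#'
#' On-statin individuals have their annual CHD, stroke and incident-diabetes
#' probabilities adjusted on the odds scale by the configured odds ratios
#' (defaults 0.70, 0.81 and 1.21); everyone else is unchanged. Discontinued
#' individuals receive no effect.
#'
#' @param p_chd,p_stroke,p_diab annual probabilities (vectorised).
#' @param on_statin logical (vectorised).
#' @param params an [event_parameters()] object.
#' @return list with elements `p_chd`, `p_stroke`, `p_diab`.
#' @export
treated_event_probabilities <- function(p_chd, p_stroke, p_diab, on_statin,
                                        params = event_parameters()) {
  list(
    p_chd    = ifelse(on_statin, apply_odds_ratio(p_chd, params$or_chd), p_chd),
    p_stroke = ifelse(on_statin, apply_odds_ratio(p_stroke, params$or_stroke),
                      p_stroke),
    p_diab   = ifelse(on_statin, apply_odds_ratio(p_diab, params$or_diabetes),
                      p_diab)
  )
}
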