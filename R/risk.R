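# Annual event probabilities: Cox-form 10-year ASCVD risk, DEALE conversion,
# event-type split, case fatality, odds-ratio adjustments.

# covariates a coefficient file may reference, and how each is computed from
# a cohort row. `antihtn` splits SBP into treated / untreated terms, the
# usual Cox-equation device for treatment-status interaction.
covariate_registry <- list(
  age           = function(d) d$age,
  sbp           = function(d) d$sbp,
  sbp_untreated = function(d) d$sbp * as.numeric(!d$antihtn),
  sbp_treated   = function(d) d$sbp * as.numeric(d$antihtn),
  tc            = function(d) d$tc,
  hdl           = function(d) d$hdl,
  ldl           = function(d) d$ldl,
  wc            = function(d) d$wc,
  smoker        = function(d) as.numeric(d$smoker),
  # natural diabetes only: statin-induced diabetes affects cost and utility
  # accrual but never ASCVD risk
  diabetes      = function(d) as.numeric(d$diabetes & !d$statin_diabetes),
  antihtn       = function(d) as.numeric(d$antihtn)
)

#' Cox-form 10-year ASCVD risk coefficients
#'
#' Per-sex coefficient sets for a China-PAR-form composite ASCVD risk
#' equation: `risk = 1 - S0 ^ exp(LP - mean_lp)` where `LP` is the linear
#' predictor over named covariates, `S0` the baseline 10-year event-free
#' survival and `mean_lp` the population-mean linear predictor.
#'
#' @param male,female lists with elements `coefficients` (named numeric over
#'   covariates known to the engine), `s0` in `(0, 1]`, and `mean_lp`.
#' @return an object of class `risk_coefficients`.
#' @export
risk_coefficients <- function(male, female) {
  obj <- structure(list(male = male, female = female),
                   class = "risk_coefficients")
  for (sex in c("male", "female")) {
    blk <- obj[[sex]]
    if (!is.numeric(blk$s0) || blk$s0 <= 0 || blk$s0 > 1) {
      stop("risk coefficients: ", sex, " s0 must be in (0, 1]", call. = FALSE)
    }
    if (!is.numeric(blk$mean_lp) || !is.finite(blk$mean_lp)) {
      stop("risk coefficients: ", sex, " mean_lp must be finite",
           call. = FALSE)
    }
    b <- blk$coefficients
    if (is.null(names(b)) || !all(is.finite(b))) {
      stop("risk coefficients: ", sex,
           " coefficients must be a finite named vector", call. = FALSE)
    }
    unknown <- setdiff(names(b), names(covariate_registry))
    if (length(unknown)) {
      stop("risk coefficients: unknown covariate(s) ",
           paste(unknown, collapse = ", "),
           "; computable covariates are: ",
           paste(names(covariate_registry), collapse = ", "), call. = FALSE)
    }
  }
  obj
}

#' Load risk coefficients from a JSON or YAML file
#'
#' The file holds `male:` / `female:` blocks, each with `coefficients`
#' (covariate name -> value), `s0` and `mean_lp`. The schema is validated on
#' load and unknown covariate names are rejected.
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return a [risk_coefficients()] object.
#' @export
load_risk_coefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (sex in c("male", "female")) {
    if (is.null(raw[[sex]])) {
      stop("coefficient file must contain a '", sex, "' block", call. = FALSE)
    }
    raw[[sex]]$coefficients <- unlist(raw[[sex]]$coefficients)
  }
  risk_coefficients(male = raw$male, female = raw$female)
}

#' Packaged synthetic default coefficients
#'
#' Loads `risk_coefficients_synthetic.json` from the package: a
#' China-PAR-*form* coefficient set with synthetic, plausible values (the
#' published equation's coefficients are not redistributed here). Intended
#' as a working default for the workflow; substitute a transcription of the
#' published equation via [load_risk_coefficients()] for applied use.
#'
#' @return a [risk_coefficients()] object.
#' @export
default_risk_coefficients <- function() {
  load_risk_coefficients(
    system.file("extdata", "risk_coefficients_synthetic.json",
                package = "statinsim", mustWork = TRUE)
  )
}

linear_predictor_ <- function(cohort, blk) {
  b <- blk$coefficients
  lp <- numeric(nrow(cohort))
  for (nm in names(b)) {
    lp <- lp + b[[nm]] * covariate_registry[[nm]](cohort)
  }
  lp
}

#' 10-year composite ASCVD risk
#'
#' Evaluates the Cox-form primary-prevention equation
#' `1 - S0 ^ exp(LP - mean_lp)` per individual, using the sex-specific
#' coefficient block. Individuals must be alive and event-free (the equation
#' does not apply after a first event).
#'
#' @param cohort a `cohort` data frame (any number of rows).
#' @param coef a [risk_coefficients()] object.
#' @return numeric vector of 10-year risks in `[0, 1]`.
#' @export
ten_year_ascvd_risk <- function(cohort, coef) {
  stopifnot(inherits(coef, "risk_coefficients"))
  if (any(cohort$state != "event_free")) {
    stop("10-year ASCVD risk is defined for alive, event-free individuals",
         call. = FALSE)
  }
  risk <- numeric(nrow(cohort))
  for (s in c("M", "F")) {
    idx <- which(cohort$sex == s)
    if (!length(idx)) next
    blk <- if (s == "M") coef$male else coef$female
    lp <- linear_predictor_(cohort[idx, , drop = FALSE], blk)
    risk[idx] <- 1 - blk$s0^exp(lp - blk$mean_lp)
  }
  pmin(pmax(risk, 0), 1)
}

#' Convert a 10-year risk to an annual probability (DEALE)
#'
#' Constant-hazard (declining exponential) conversion:
#' `p1 = 1 - (1 - p10)^(1/10)`, equivalently rate `-log(1 - p10)/10`
#' exponentiated back to a one-year probability.
#'
#' @param p10 10-year probability (vectorised), in `[0, 1]`.
#' @return one-year probability, same length.
#' @export
deale_annual_probability <- function(p10) {
  if (any(!is.finite(p10) | p10 < 0 | p10 > 1)) {
    stop("p10 must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p10)^(1 / 10)
}

#' Adjust a probability by an odds ratio
#'
#' `p' = OR * odds / (1 + OR * odds)` with `odds = p/(1-p)`; `p = 1` maps
#' to 1. Self-inverse under `1/OR`.
#'
#' @param p probability (vectorised), in `[0, 1]`.
#' @param or_value odds ratio, `> 0`.
#' @return adjusted probability.
#' @export
apply_odds_ratio <- function(p, or_value) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(or_value) | or_value <= 0)) {
    stop("or_value must be > 0", call. = FALSE)
  }
  ifelse(p == 1, 1, or_value * p / (1 - p + or_value * p))
}

#' Event, mortality and treatment-effect parameters
#'
#' Bundles the composite-event type split (CHD 29.46% / stroke 70.54%),
#' case-fatality tables by event type, sex and age band, statin odds ratios
#' (CHD 0.70, stroke 0.81, incident diabetes 1.21), the post-event
#' background-mortality multiplier (2.0), the background all-cause mortality
#' table and the annual diabetes-incidence table.
#'
#' The packaged background-mortality and diabetes-incidence defaults are
#' synthetic (Gompertz-form mortality; age-banded incidence) and fully
#' replaceable via rate tables with columns `age_lo, age_hi, sex, value`
#' (see [read_rate_table()]).
#'
#' @param chd_share share of composite ASCVD events that are CHD.
#' @param or_chd,or_stroke,or_diabetes statin odds ratios on annual CHD,
#'   stroke and incident-diabetes probabilities.
#' @param post_event_mortality_multiplier multiplier on background mortality
#'   for survivors of a first event (applied from the cycle after the event).
#' @param case_fatality data frame `event, sex, age_lo, age_hi, value`.
#' @param background_mortality,diabetes_incidence rate tables
#'   (`age_lo, age_hi, sex, value`).
#' @param ascvd_death_fraction fraction of background mortality attributable
#'   to ASCVD, removed from the table to avoid double counting (default 0).
#' @return an object of class `event_parameters`.
#' @export
event_parameters <- function(chd_share = 0.2946,
                             or_chd = 0.70, or_stroke = 0.81,
                             or_diabetes = 1.21,
                             post_event_mortality_multiplier = 2.0,
                             case_fatality = default_case_fatality(),
                             background_mortality = default_mortality_table(),
                             diabetes_incidence = default_diabetes_incidence(),
                             ascvd_death_fraction = 0) {
  stopifnot(chd_share >= 0, chd_share <= 1,
            or_chd > 0, or_stroke > 0, or_diabetes > 0,
            post_event_mortality_multiplier >= 1,
            ascvd_death_fraction >= 0, ascvd_death_fraction < 1)
  validate_rate_table(background_mortality, "background_mortality")
  validate_rate_table(diabetes_incidence, "diabetes_incidence")
  if (min(background_mortality$age_lo) > 40 ||
      max(background_mortality$age_hi) < 89) {
    stop("background mortality table must cover ages 40-89", call. = FALSE)
  }
  stopifnot(all(c("event", "sex", "age_lo", "age_hi", "value") %in%
                  names(case_fatality)),
            all(case_fatality$value >= 0 & case_fatality$value <= 1))
  if (ascvd_death_fraction > 0) {
    background_mortality$value <-
      background_mortality$value * (1 - ascvd_death_fraction)
  }
  structure(list(chd_share = chd_share, or_chd = or_chd,
                 or_stroke = or_stroke, or_diabetes = or_diabetes,
                 post_event_mortality_multiplier =
                   post_event_mortality_multiplier,
                 case_fatality = case_fatality,
                 background_mortality = background_mortality,
                 diabetes_incidence = diabetes_incidence),
            class = "event_parameters")
}

#' Case-fatality proportions by event, sex and age band
#'
#' Fatality of an incident CHD or stroke event, in 10-year age bands from
#' 34–44 to 75–84; ages above the last band reuse its value.
#'
#' @return data frame `event, sex, age_lo, age_hi, value`.
#' @export
default_case_fatality <- function() {
  band_lo <- c(34, 45, 55, 65, 75)
  band_hi <- c(44, 54, 64, 74, 84)
  rbind(
    data.frame(event = "chd", sex = "M", age_lo = band_lo, age_hi = band_hi,
               value = c(0.12, 0.21, 0.29, 0.33, 0.48)),
    data.frame(event = "chd", sex = "F", age_lo = band_lo, age_hi = band_hi,
               value = c(0.18, 0.23, 0.27, 0.43, 0.51)),
    data.frame(event = "stroke", sex = "M", age_lo = band_lo, age_hi = band_hi,
               value = c(0.25, 0.18, 0.12, 0.20, 0.45)),
    data.frame(event = "stroke", sex = "F", age_lo = band_lo, age_hi = band_hi,
               value = c(0.18, 0.14, 0.15, 0.20, 0.45))
  )
}

#' Synthetic background all-cause mortality table
#'
#' Gompertz-form annual mortality `q(age) = a * exp(b * age)` by sex over
#' ages 40–89, shaped to resemble a contemporary Chinese period life table.
#' Synthetic stand-in; replace with an official life table for applied work.
#'
#' @return rate table `age_lo, age_hi, sex, value`.
#' @export
default_mortality_table <- function() {
  age <- 40:89
  rbind(
    data.frame(age_lo = age, age_hi = age, sex = "M",
               value = pmin(6.7e-5 * exp(0.085 * age), 1)),
    data.frame(age_lo = age, age_hi = age, sex = "F",
               value = pmin(3.5e-5 * exp(0.088 * age), 1))
  )
}

#' Synthetic annual diabetes incidence by age
#'
#' Age-banded annual probability of incident type 2 diabetes among the
#' non-diabetic, identical for both sexes. Synthetic default; replaceable.
#'
#' @return rate table `age_lo, age_hi, sex, value`.
#' @export
default_diabetes_incidence <- function() {
  lo <- c(40, 50, 60, 70, 80); hi <- c(49, 59, 69, 79, 89)
  v <- c(0.005, 0.008, 0.011, 0.012, 0.010)
  rbind(data.frame(age_lo = lo, age_hi = hi, sex = "M", value = v),
        data.frame(age_lo = lo, age_hi = hi, sex = "F", value = v))
}

validate_rate_table <- function(tab, what = "rate table") {
  if (!is.data.frame(tab) ||
      !all(c("age_lo", "age_hi", "sex", "value") %in% names(tab))) {
    stop(what, " must have columns age_lo, age_hi, sex, value", call. = FALSE)
  }
  if (any(tab$value < 0 | tab$value > 1)) {
    stop(what, ": values must be probabilities in [0,1]", call. = FALSE)
  }
  invisible(tab)
}

#' Read a rate table (CSV)
#'
#' Rate tables (background mortality, diabetes incidence, case fatality
#' without the `event` column) are CSVs with columns
#' `age_lo, age_hi, sex, value` and sex coded `"M"`/`"F"`.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_rate_table <- function(path) {
  validate_rate_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

# vectorised band lookup: age/sex -> value; ages above the top band reuse it,
# ages below the bottom band reuse that.
lookup_rate <- function(tab, age, sex) {
  out <- numeric(length(age))
  for (s in unique(sex)) {
    sub <- tab[tab$sex == s, , drop = FALSE]
    sub <- sub[order(sub$age_lo), , drop = FALSE]
    idx <- which(sex == s)
    band <- findInterval(age[idx], sub$age_lo)
    band[band < 1] <- 1
    out[idx] <- sub$value[band]
  }
  out
}

#' Classify a composite ASCVD event as CHD or stroke
#'
#' Deterministic split of a uniform draw at the CHD share of composite
#' events: `u < chd_share` is CHD, otherwise stroke.
#'
#' @param u uniform draw(s) in `[0, 1)`.
#' @param params an [event_parameters()] object (supplies the default share).
#' @param chd_share optional override of the cut point (the engine passes the
#'   treatment-adjusted conditional share for on-statin individuals).
#' @return character vector, `"chd"` or `"stroke"`.
#' @export
split_event_type <- function(u, params = event_parameters(),
                             chd_share = params$chd_share) {
  ifelse(u < chd_share, "chd", "stroke")
}

#' Case fatality of an incident event
#'
#' Table lookup by event type, sex and age band; ages above the last band
#' (85–89) reuse the 75–84 value.
#'
#' @param event `"chd"` or `"stroke"` (vectorised).
#' @param sex `"M"`/`"F"` (vectorised).
#' @param age years (vectorised).
#' @param params an [event_parameters()] object.
#' @return probability the event is fatal.
#' @export
case_fatality <- function(event, sex, age, params = event_parameters()) {
  if (!all(event %in% c("chd", "stroke"))) {
    stop("unknown event type; expected 'chd' or 'stroke'", call. = FALSE)
  }
  n <- max(length(event), length(sex), length(age))
  event <- rep_len(event, n); sex <- rep_len(sex, n); age <- rep_len(age, n)
  out <- numeric(n)
  for (e in c("chd", "stroke")) {
    idx <- which(event == e)
    if (!length(idx)) next
    tab <- params$case_fatality[params$case_fatality$event == e,
                                c("age_lo", "age_hi", "sex", "value")]
    out[idx] <- lookup_rate(tab, age[idx], sex[idx])
  }
  out
}
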