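# Synthetic baseline cohorts and risk-factor age trends.
#
# The generator stands in for restricted survey microdata: it reproduces the
# *statistical shape* the simulation needs (per-sex marginals, binary risk
# factor prevalences, linear age drift) rather than any real respondent data.

RISK_FACTORS <- c("sbp", "tc", "hdl", "ldl", "wc")

COHORT_COLUMNS <- c(
  "id", "age", "sex", "sbp", "antihtn", "tc", "hdl", "ldl", "wc",
  "smoker", "diabetes", "statin_diabetes", "state", "treat",
  "treat_years", "years_since_event"
)

#' Population configuration for the synthetic cohort generator
#'
#' Defines per-sex marginal distributions for age and the five continuous
#' ASCVD risk factors (SBP in mmHg; TC, HDL-C, LDL-C in mmol/L; waist
#' circumference in cm), prevalences of smoking, diabetes and
#' antihypertensive treatment, an optional correlation matrix among the
#' continuous factors, and the male fraction of the cohort.
#'
#' The packaged defaults are *synthetic*: literature-plausible values for a
#' Chinese middle-aged and elderly population, intended to emulate the
#' marginal structure of a national ageing survey. They are not estimates
#' from any microdata and every value can be overridden.
#'
#' @param sex_ratio_male proportion of males in `[0,1]`.
#' @param age_range two integers, inclusive sampling bounds for baseline age.
#'   The model itself accepts ages 40–89; the default cohort starts at 45.
#' @param male,female per-sex lists with elements `age`, `sbp`, `tc`, `hdl`,
#'   `ldl`, `wc` (each `list(mean=, sd=)`) and scalar prevalences `smoker`,
#'   `diabetes`, `antihtn`.
#' @param correlation optional symmetric positive semi-definite correlation
#'   matrix with dimnames over `c("sbp","tc","hdl","ldl","wc")`; `NULL`
#'   (default) means independent factors.
#' @param floors named vector of lower bounds applied to continuous factors,
#'   keeping the risk equation finite under long linear drift.
#' @return an object of class `population_config`.
#' @export
population_config <- function(sex_ratio_male = 0.47,
                              age_range = c(45L, 89L),
                              male = list(
                                age = list(mean = 59, sd = 10),
                                sbp = list(mean = 135, sd = 20),
                                tc  = list(mean = 4.70, sd = 0.95),
                                hdl = list(mean = 1.20, sd = 0.30),
                                ldl = list(mean = 2.75, sd = 0.85),
                                wc  = list(mean = 87, sd = 10),
                                smoker = 0.52, diabetes = 0.12, antihtn = 0.16
                              ),
                              female = list(
                                age = list(mean = 58, sd = 10),
                                sbp = list(mean = 132, sd = 21),
                                tc  = list(mean = 4.90, sd = 0.95),
                                hdl = list(mean = 1.32, sd = 0.32),
                                ldl = list(mean = 2.90, sd = 0.85),
                                wc  = list(mean = 85, sd = 10),
                                smoker = 0.05, diabetes = 0.13, antihtn = 0.18
                              ),
                              correlation = NULL,
                              floors = c(sbp = 80, tc = 2.0, hdl = 0.3,
                                         ldl = 0.5, wc = 50)) {
  cfg <- structure(
    list(sex_ratio_male = sex_ratio_male, age_range = age_range,
         male = male, female = female, correlation = correlation,
         floors = floors),
    class = "population_config"
  )
  validate_population_config(cfg)
  cfg
}

#' Validate a population configuration
#'
#' @param config a `population_config`.
#' @return `config`, invisibly, or an error naming the offending field.
#' @export
validate_population_config <- function(config) {
  stopifnot(inherits(config, "population_config"))
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid population config: field '%s' %s", field, what),
           call. = FALSE)
    }
  }
  chk(is.numeric(config$sex_ratio_male) &&
        config$sex_ratio_male >= 0 && config$sex_ratio_male <= 1,
      "sex_ratio_male", "must be a proportion in [0,1]")
  chk(length(config$age_range) == 2 && config$age_range[1] >= 40 &&
        config$age_range[2] <= 89 && config$age_range[1] <= config$age_range[2],
      "age_range", "must be within [40, 89] with lower <= upper")
  for (sex in c("male", "female")) {
    blk <- config[[sex]]
    for (f in c("age", RISK_FACTORS)) {
      d <- blk[[f]]
      chk(is.list(d) && is.finite(d$mean) && d$mean > 0 &&
            is.finite(d$sd) && d$sd >= 0,
          paste(sex, f, sep = "$"), "needs finite positive mean and sd >= 0")
    }
    for (f in c("smoker", "diabetes", "antihtn")) {
      chk(is.numeric(blk[[f]]) && blk[[f]] >= 0 && blk[[f]] <= 1,
          paste(sex, f, sep = "$"), "must be a prevalence in [0,1]")
    }
  }
  if (!is.null(config$correlation)) {
    R <- config$correlation
    chk(is.matrix(R) && nrow(R) == length(RISK_FACTORS) &&
          identical(rownames(R), RISK_FACTORS) &&
          identical(colnames(R), RISK_FACTORS),
        "correlation", "must be a 5x5 matrix with sbp/tc/hdl/ldl/wc dimnames")
    chk(isTRUE(all.equal(R, t(R))), "correlation", "must be symmetric")
    chk(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > -1e-8,
        "correlation", "must be positive semi-definite")
  }
  invisible(config)
}

# truncated-normal draws via inverse CDF; z optional pre-drawn standard normals
rtruncnorm_ <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic baseline cohort
#'
#' Draws `n` ASCVD-free individuals from the marginal distributions in
#' `config`. Continuous risk factors are sampled from (optionally correlated,
#' via a Gaussian copula) normal distributions and floored at the configured
#' clinical minima; baseline age is truncated-normal within `age_range`.
#' Everyone starts event-free, untreated and without statin-induced diabetes.
#'
#' @param n number of individuals (`n = 0` gives an empty cohort).
#' @param config a [population_config()].
#' @param seed integer seed; the cohort is a pure function of
#'   `(n, config, seed)`.
#' @return a `data.frame` of class `cohort`, one row per individual.
#' @export
generate_cohort <- function(n, config = population_config(), seed) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 0, n == floor(n))
  validate_population_config(config)
  if (missing(seed)) stop("generate_cohort() requires an explicit seed")
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    sex <- ifelse(stats::runif(n) < config$sex_ratio_male, "M", "F")
    out <- data.frame(
      id = seq_len(n), age = numeric(n), sex = sex,
      sbp = numeric(n), antihtn = logical(n),
      tc = numeric(n), hdl = numeric(n), ldl = numeric(n), wc = numeric(n),
      smoker = logical(n), diabetes = logical(n),
      statin_diabetes = logical(n),
      state = rep("event_free", n), treat = rep("never", n),
      treat_years = integer(n), years_since_event = rep(NA_integer_, n),
      stringsAsFactors = FALSE
    )
    for (s in c("M", "F")) {
      idx <- which(sex == s)
      if (!length(idx)) next
      blk <- if (s == "M") config$male else config$female
      m <- length(idx)
      out$age[idx] <- floor(rtruncnorm_(m, blk$age$mean, blk$age$sd,
                                        config$age_range[1],
                                        config$age_range[2] + 1 - 1e-9))
      # correlated standard normals for the five continuous factors
      Z <- matrix(stats::rnorm(m * length(RISK_FACTORS)), nrow = m)
      if (!is.null(config$correlation)) {
        Z <- Z %*% chol(config$correlation)
      }
      colnames(Z) <- RISK_FACTORS
      for (f in RISK_FACTORS) {
        x <- blk[[f]]$mean + blk[[f]]$sd * Z[, f]
        out[[f]][idx] <- pmax(x, config$floors[[f]])
      }
      out$smoker[idx]   <- stats::runif(m) < blk$smoker
      out$diabetes[idx] <- stats::runif(m) < blk$diabetes
      out$antihtn[idx]  <- stats::runif(m) < blk$antihtn
    }
    class(out) <- c("cohort", "data.frame")
    out
  })
}

#' Risk-factor age-trend model
#'
#' Per-sex linear drift of HDL-C, LDL-C, TC, SBP and waist circumference per
#' year of age, as obtained from cross-sectional regression of each factor on
#' age. Only the slope enters the annual projection; an optional residual SD
#' adds year-to-year noise (default 0: deterministic drift).
#'
#' Default slopes are synthetic, plausible for Chinese adults over the
#' simulated age range, and overridable.
#'
#' @param male,female named numeric vectors of slopes (factor units per year)
#'   covering exactly `hdl`, `ldl`, `tc`, `sbp`, `wc`.
#' @param residual_sd named numeric vector of residual SDs, or a single 0.
#' @return an object of class `age_trend_model`.
#' @export
age_trend_model <- function(male, female, residual_sd = 0) {
  need <- sort(RISK_FACTORS)
  for (v in list(male, female)) {
    if (!setequal(names(v), RISK_FACTORS) || !all(is.finite(v))) {
      stop("age trends must give finite slopes for exactly: ",
           paste(RISK_FACTORS, collapse = ", "), call. = FALSE)
    }
  }
  if (length(residual_sd) == 1) {
    residual_sd <- stats::setNames(rep(residual_sd, 5), RISK_FACTORS)
  }
  structure(list(male = male[RISK_FACTORS], female = female[RISK_FACTORS],
                 residual_sd = residual_sd[RISK_FACTORS]),
            class = "age_trend_model")
}

#' @rdname age_trend_model
#' @export
default_age_trends <- function() {
  age_trend_model(
    male   = c(sbp = 0.45, tc = -0.008, hdl = 0.002, ldl = -0.006, wc = 0.05),
    female = c(sbp = 0.60, tc =  0.006, hdl = 0.001, ldl =  0.004, wc = 0.10)
  )
}

#' Project risk factors forward one year
#'
#' Advances every (alive) individual by one annual cycle: each continuous
#' factor is incremented by its sex-specific slope (plus optional residual
#' noise), floored at the configured clinical minima, and age increases by 1.
#'
#' @param cohort a `cohort` data frame (one or more rows), all alive.
#' @param trends an [age_trend_model()].
#' @param floors named lower bounds for the continuous factors.
#' @return the updated cohort.
#' @export
project_risk_factors <- function(cohort, trends = default_age_trends(),
                                 floors = c(sbp = 80, tc = 2.0, hdl = 0.3,
                                            ldl = 0.5, wc = 50)) {
  stopifnot(inherits(trends, "age_trend_model"))
  if (any(cohort$state == "dead")) {
    stop("cannot project risk factors of a dead individual", call. = FALSE)
  }
  male <- cohort$sex == "M"
  for (f in RISK_FACTORS) {
    slope <- ifelse(male, trends$male[[f]], trends$female[[f]])
    x <- cohort[[f]] + slope
    if (trends$residual_sd[[f]] > 0) {
      x <- x + stats::rnorm(nrow(cohort), 0, trends$residual_sd[[f]])
    }
    cohort[[f]] <- pmax(x, floors[[f]])
  }
  cohort$age <- cohort$age + 1
  cohort
}

#' Read / write a baseline cohort as CSV
#'
#' The on-disk format has one row per individual with columns
#' `age, sex, sbp, tc, hdl, ldl, wc, smoker, diabetes, antihtn`
#' (sex coded `"M"`/`"F"`, binary flags 0/1). Simulation state columns are
#' reconstructed on read: everyone loads event-free and untreated.
#'
#' @param cohort a `cohort` data frame.
#' @param path file path.
#' @return `read_cohort` returns a `cohort`; `write_cohort` returns `path`
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(
    age = cohort$age, sex = cohort$sex, sbp = cohort$sbp, tc = cohort$tc,
    hdl = cohort$hdl, ldl = cohort$ldl, wc = cohort$wc,
    smoker = as.integer(cohort$smoker),
    diabetes = as.integer(cohort$diabetes),
    antihtn = as.integer(cohort$antihtn)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "sbp", "tc", "hdl", "ldl", "wc",
            "smoker", "diabetes", "antihtn")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(raw$sex %in% c("M", "F"))) {
    stop("cohort file: sex must be coded 'M'/'F'", call. = FALSE)
  }
  n <- nrow(raw)
  out <- data.frame(
    id = seq_len(n), age = as.numeric(raw$age), sex = raw$sex,
    sbp = as.numeric(raw$sbp), antihtn = as.logical(raw$antihtn),
    tc = as.numeric(raw$tc), hdl = as.numeric(raw$hdl),
    ldl = as.numeric(raw$ldl), wc = as.numeric(raw$wc),
    smoker = as.logical(raw$smoker), diabetes = as.logical(raw$diabetes),
    statin_diabetes = logical(n),
    state = rep("event_free", n), treat = rep("never", n),
    treat_years = integer(n), years_since_event = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort", "data.frame")
  out
}
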