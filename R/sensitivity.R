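# Deterministic (one-way) and probabilistic sensitivity analysis, and the
# model's internal / external validation procedures.

#' Distribution specification for a model parameter
#'
#' Describes the uncertainty assigned to a parameter for PSA: family
#' (`beta`, `gamma`, `lognormal`, `fixed`), point value, standard error and
#' optional explicit bounds for one-way analysis. Beta and gamma are
#' parameterised by the method of moments from `(value, se)`; the lognormal
#' (used for odds ratios) takes its log-scale sigma from the printed SE by
#' the delta method (`sigma = se / value`) with the log-mean chosen so the
#' distribution's mean equals `value`.
#'
#' @param family one of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param value point estimate.
#' @param se standard error (`NULL` for fixed, or when unknown).
#' @param low,high optional one-way analysis bounds.
#' @return an object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("fixed", "beta", "gamma", "lognormal"),
                      value, se = NULL, low = NULL, high = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(value), is.finite(value))
  if (!is.null(se)) stopifnot(se >= 0)
  if (family == "beta" && (value < 0 || value > 1)) {
    stop("beta-distributed parameters must lie in [0, 1]", call. = FALSE)
  }
  if (family %in% c("gamma", "lognormal") && value <= 0) {
    stop(family, "-distributed parameters must be positive", call. = FALSE)
  }
  structure(list(family = family, value = value, se = se,
                 low = low, high = high),
            class = "dist_spec")
}

#' Default PSA distribution assignments
#'
#' The uncertain parameters and their assigned families: beta for the four
#' utility decrements, lognormal for the CHD and stroke treatment odds
#' ratios (with their printed SEs), and the remaining scalars (the diabetes
#' odds ratio, which is listed without an SE, and the cost parameters) held
#' fixed. Any entry can be overridden, e.g. to give the diabetes OR a
#' lognormal spread.
#'
#' @return named list of [dist_spec()] objects, keyed by the parameter names
#'   understood by [set_parameter()].
#' @export
default_psa_specs <- function() {
  list(
    acute_chd       = dist_spec("beta", 0.439, 0.018),
    acute_stroke    = dist_spec("beta", 0.92, 0.04),
    longterm_chd    = dist_spec("beta", 0.107, 0.019),
    longterm_stroke = dist_spec("beta", 0.266, 0.02),
    or_chd          = dist_spec("lognormal", 0.70, 0.072),
    or_stroke       = dist_spec("lognormal", 0.81, 0.069),
    or_diabetes     = dist_spec("fixed", 1.21),
    statin_cost     = dist_spec("fixed", 1149.75),
    hosp_chd        = dist_spec("fixed", 22611),
    hosp_stroke     = dist_spec("fixed", 13983)
  )
}

sample_one_ <- function(spec, n) {
  v <- spec$value
  if (spec$family == "fixed") return(rep(v, n))
  if (is.null(spec$se) || spec$se == 0) {
    warning("no standard error for a '", spec$family,
            "' parameter; sampling as fixed", call. = FALSE)
    return(rep(v, n))
  }
  s <- spec$se
  switch(spec$family,
    beta = {
      if (s^2 >= v * (1 - v)) {
        stop("beta spec: se too large for mean ", v, call. = FALSE)
      }
      nu <- v * (1 - v) / s^2 - 1
      stats::rbeta(n, v * nu, (1 - v) * nu)
    },
    gamma = stats::rgamma(n, shape = v^2 / s^2, rate = v / s^2),
    lognormal = {
      sigma <- s / v
      stats::rlnorm(n, meanlog = log(v) - sigma^2 / 2, sdlog = sigma)
    }
  )
}

#' Sample parameter values from their distributions
#'
#' One PSA draw (or `n` draws) of every parameter in `specs`. Parameters
#' whose family needs an SE but lack one fall back to their point value with
#' a warning. Deterministic given the seed.
#'
#' @param specs named list of [dist_spec()]s.
#' @param seed integer seed.
#' @param n number of draws.
#' @return data frame with `n` rows, one column per parameter.
#' @export
sample_parameters <- function(specs, seed, n = 1) {
  stopifnot(n >= 1)
  withr::with_seed(as.integer(seed), {
    out <- lapply(specs, sample_one_, n = n)
    as.data.frame(out)
  })
}

apply_draw_ <- function(params, draw) {
  for (nm in names(draw)) {
    params <- set_parameter(params, nm, as.numeric(draw[[nm]]))
  }
  params
}

#' One-way deterministic sensitivity analysis of a single parameter
#'
#' Re-runs the model with the named parameter at its lower and upper bound
#' (all other parameters at base values, common random numbers) and returns
#' the target quantity at both bounds.
#'
#' @param params base [parameter_set()].
#' @param param_name a name understood by [set_parameter()].
#' @param low,high bounds, `low < high`.
#' @param runner `function(parameter_set)` returning the target scalar
#'   (typically an ICER extracted from [icer_ladder()] on a fixed-seed run).
#' @return list `low`, `high` (target at each bound) and `range`
#'   (`abs(high - low)`).
#' @export
one_way_dsa <- function(params, param_name, low, high, runner) {
  stopifnot(low < high)
  get_parameter(params, param_name)   # errors on unknown names
  v_low <- runner(set_parameter(params, param_name, low))
  v_high <- runner(set_parameter(params, param_name, high))
  list(low = v_low, high = v_high, range = abs(v_high - v_low))
}

#' Default one-way ranges
#'
#' Where a spec carries an SE, `value +/- 1.96 * se` clipped to the family
#' support; otherwise `value +/- 20%`.
#'
#' @param specs named list of [dist_spec()]s.
#' @return data frame `parameter, low, high`.
#' @export
default_dsa_ranges <- function(specs = default_psa_specs()) {
  rows <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    if (!is.null(sp$low) && !is.null(sp$high)) {
      lo <- sp$low; hi <- sp$high
    } else if (!is.null(sp$se) && sp$se > 0) {
      lo <- sp$value - 1.96 * sp$se
      hi <- sp$value + 1.96 * sp$se
    } else {
      lo <- 0.8 * sp$value; hi <- 1.2 * sp$value
    }
    if (sp$family == "beta") { lo <- max(lo, 0); hi <- min(hi, 1) }
    if (sp$family %in% c("gamma", "lognormal")) lo <- max(lo, 1e-9)
    data.frame(parameter = nm, low = lo, high = hi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tornado analysis over a set of parameters
#'
#' Runs [one_way_dsa()] for every row of `ranges` and orders parameters by
#' descending width of the induced target range (the tornado ordering).
#'
#' @param params base [parameter_set()].
#' @param ranges data frame `parameter, low, high`.
#' @param runner as in [one_way_dsa()].
#' @return data frame `parameter, low, high, value_low, value_high, range`,
#'   sorted by decreasing `range`.
#' @export
tornado <- function(params, ranges, runner) {
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- one_way_dsa(params, ranges$parameter[i], ranges$low[i],
                     ranges$high[i], runner)
    data.frame(parameter = ranges$parameter[i],
               low = ranges$low[i], high = ranges$high[i],
               value_low = r$low, value_high = r$high, range = r$range,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$range), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' For each of `n_draws` draws: sample one parameter vector from `specs`,
#' apply it to the base `parameter_set`, and run every strategy with common
#' random numbers. One simulation seed (derived from the master seed) is
#' shared by all draws and strategies, so the curves reflect parameter
#' uncertainty only — with all-fixed specs every draw reproduces the
#' deterministic base case exactly.
#'
#' @param cohort a nonempty `cohort`.
#' @param strategies list of [strategy()] objects.
#' @param specs named list of [dist_spec()]s.
#' @param n_draws number of PSA draws.
#' @param seed master seed (drives both parameter sampling and simulation
#'   seeds).
#' @param params base [parameter_set()].
#' @return an object of class `psa_result`: list with `draws` (data frame
#'   `draw, strategy, cost, qaly`), `parameters` (one row per draw),
#'   `n_draws`, `seed`.
#' @export
run_psa <- function(cohort, strategies, specs = default_psa_specs(),
                    n_draws = 1000, seed, params = parameter_set()) {
  stopifnot(n_draws >= 1)
  sampled <- sample_parameters(specs, seed = seed, n = n_draws)
  sim_seed <- as.integer(seed) + 1L
  rows <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    p_d <- apply_draw_(params, sampled[d, , drop = FALSE])
    res <- run_strategies(cohort, strategies, p_d, seed = sim_seed)
    rows[[d]] <- do.call(rbind, lapply(res, function(r)
      data.frame(draw = d, strategy = r$name, cost = r$mean_cost,
                 qaly = r$mean_qaly, stringsAsFactors = FALSE)))
  }
  structure(list(draws = do.call(rbind, rows), parameters = sampled,
                 n_draws = n_draws, seed = as.integer(seed)),
            class = "psa_result")
}

#' Probability each strategy is optimal at given willingness-to-pay values
#'
#' @param psa a `psa_result` from [run_psa()].
#' @param wtp willingness-to-pay value(s); defaults to the 1x and 3x
#'   GDP-per-capita decision thresholds.
#' @return data frame `wtp, strategy, probability`.
#' @export
probability_optimal <- function(psa, wtp = wtp_thresholds()) {
  ceac(psa$draws, wtp)
}

#' Internal validation: expected vs simulated event probabilities
#'
#' Least-squares R-squared of the regression of group-level simulated event
#' frequencies on the analytic (expected) 1-year probabilities, the model's
#' internal-validity statistic.
#'
#' @param expected analytic mean 1-year event probabilities per age-sex
#'   group (numeric, length >= 3).
#' @param simulated simulated event frequencies for the same groups.
#' @return list `r2` (NA with a warning when variance is degenerate) and
#'   `fit` (the `lm` object, or `NULL`).
#' @export
internal_validation <- function(expected, simulated) {
  stopifnot(length(expected) == length(simulated), length(expected) >= 3)
  if (stats::var(simulated) == 0 || stats::var(expected) == 0) {
    warning("degenerate variance; R-squared undefined", call. = FALSE)
    return(list(r2 = NA_real_, fit = NULL))
  }
  fit <- stats::lm(simulated ~ expected)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((simulated - mean(simulated))^2)
  list(r2 = r2, fit = fit)
}

#' Build internal-validation inputs from an untreated run
#'
#' Groups the cohort by sex and 10-year baseline age band, computes each
#' group's mean analytic 1-year composite event probability (risk equation +
#' DEALE at baseline) and its simulated first-cycle event frequency in an
#' untreated run, and regresses one on the other.
#'
#' @param cohort baseline `cohort`.
#' @param params a [parameter_set()].
#' @param seed simulation seed.
#' @return list `table` (per-group expected and simulated probabilities),
#'   `r2`, `fit`.
#' @export
validate_internal <- function(cohort, params = parameter_set(), seed) {
  p1 <- deale_annual_probability(
    ten_year_ascvd_risk(cohort, params$coefficients))
  res <- run_strategy(cohort, strategy("no_treatment"), params, seed,
                      keep_log = TRUE)
  first <- res$event_log[res$event_log$cycle == 0, ]
  had_event <- grepl("^(chd|stroke)", first$event[match(cohort$id, first$id)])
  band <- 10 * floor(cohort$age / 10)
  grp <- paste(cohort$sex, band, sep = "_")
  tab <- data.frame(
    group = sort(unique(grp)),
    expected = as.numeric(tapply(p1, grp, mean)[sort(unique(grp))]),
    simulated = as.numeric(tapply(had_event, grp, mean)[sort(unique(grp))])
  )
  iv <- internal_validation(tab$expected, tab$simulated)
  list(table = tab, r2 = iv$r2, fit = iv$fit)
}

#' External validation report
#'
#' Tabulates simulated incidence (and, when supplied, life expectancy)
#' against external reference values per age-sex band. Report only — no
#' pass/fail.
#'
#' @param simulated data frame `group, value` of simulated quantities.
#' @param reference data frame `group, value` of reference quantities (may
#'   be empty, giving an empty report with a warning).
#' @return data frame `group, simulated, reference, delta`.
#' @export
external_validation <- function(simulated, reference) {
  if (is.null(reference) || nrow(reference) == 0) {
    warning("no reference table supplied; external validation skipped",
            call. = FALSE)
    return(data.frame(group = character(), simulated = numeric(),
                      reference = numeric(), delta = numeric()))
  }
  m <- merge(simulated, reference, by = "group",
             suffixes = c("_sim", "_ref"))
  data.frame(group = m$group, simulated = m$value_sim,
             reference = m$value_ref, delta = m$value_sim - m$value_ref)
}
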