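# Annual-cycle microsimulation engine.
#
# Within-cycle order (fixed, config-locked):
#   1. screening / statin initiation
#   2. annual ASCVD probability (risk equation -> DEALE -> type-specific
#      treatment adjustment)
#   3. composite event draw; type split; case-fatality draw
#   4. diabetes-onset draw (statin-adjusted) for ASCVD survivors
#   5. background-mortality draw (doubled for survivors of an event in an
#      earlier cycle)
#   6. cost / utility accrual (undiscounted here; run_strategy discounts)
#   7. risk-factor projection, age + 1, year counters, end-of-first-treated-
#      year discontinuation draw

EVENT_LABELS <- c("none", "chd_fatal", "chd_nonfatal", "stroke_fatal",
                  "stroke_nonfatal", "background_death")

#' Advance a cohort by one annual cycle
#'
#' Runs the fixed within-cycle sequence on an all-alive cohort and returns
#' the updated cohort plus a per-individual cycle record with undiscounted
#' cost and utility. Uniform draws can be supplied explicitly (for forced
#' paths in testing) or are taken from the current RNG stream.
#'
#' @param cohort a `cohort` data frame; every row must be alive.
#' @param strategy a [strategy()].
#' @param params a [parameter_set()].
#' @param draws optional named list of uniform vectors (`u_event`, `u_type`,
#'   `u_fatal`, `u_diab`, `u_bg`, `u_disc`), each recycled to `nrow(cohort)`.
#' @return list with elements `cohort` (updated; fatalities marked dead) and
#'   `record` (data frame: `id`, `age` at cycle start, `event`,
#'   `diabetes_onset`, `treat` at end of cycle, `cost`, `utility`, `alive`
#'   at end of cycle).
#' @export
run_cycle <- function(cohort, strategy, params, draws = NULL) {
  stopifnot(inherits(params, "parameter_set"))
  if (any(cohort$state == "dead")) {
    stop("run_cycle() requires an all-alive cohort", call. = FALSE)
  }
  n <- nrow(cohort)
  dr <- list(u_event = NULL, u_type = NULL, u_fatal = NULL,
             u_diab = NULL, u_bg = NULL, u_disc = NULL)
  for (nm in names(dr)) {
    dr[[nm]] <- if (is.null(draws[[nm]])) stats::runif(n) else
      rep_len(draws[[nm]], n)
  }
  ev <- params$events
  entry_state <- cohort$state
  entry_years <- cohort$years_since_event
  entry_age <- cohort$age
  entry_sex <- cohort$sex

  # 1. screening / initiation (discontinuation is resolved at cycle end)
  elig <- is_eligible(cohort, strategy, params$coefficients)
  cohort <- update_treatment_state(cohort, strategy, u = 1, eligible = elig)
  on_statin <- cohort$treat == "on_statin"

  # 2. annual probabilities
  ef <- cohort$state == "event_free"
  at_risk <- if (params$allow_recurrence) rep(TRUE, n) else ef
  p1 <- numeric(n)
  if (any(at_risk)) {
    tmp <- cohort[at_risk, , drop = FALSE]
    tmp$state <- "event_free"          # recurrence reuses the same equation
    p1[at_risk] <- deale_annual_probability(
      ten_year_ascvd_risk(tmp, params$coefficients))
  }
  # natural-onset probability: zero only for natural diabetics — a
  # statin-induced diabetic can still convert naturally, which keeps the
  # natural-diabetes process (the risk-equation covariate) independent of
  # the statin pathway
  nat_diab <- cohort$diabetes & !cohort$statin_diabetes
  p_diab_base <- ifelse(nat_diab, 0,
                        lookup_rate(ev$diabetes_incidence, entry_age,
                                    entry_sex))
  adj <- treated_event_probabilities(p1 * ev$chd_share,
                                     p1 * (1 - ev$chd_share),
                                     p_diab_base, on_statin, ev)
  # the odds-ratio excess applies only to the fully non-diabetic
  adj$p_diab <- ifelse(cohort$diabetes, p_diab_base, adj$p_diab)
  p_comp <- adj$p_chd + adj$p_stroke

  # 3. composite event draw, type split, case fatality
  has_event <- dr$u_event < p_comp
  cond_share <- ifelse(p_comp > 0, adj$p_chd / p_comp, ev$chd_share)
  etype <- split_event_type(dr$u_type, ev, chd_share = cond_share)
  fatal <- has_event &
    dr$u_fatal < case_fatality(etype, entry_sex, entry_age, ev)
  event <- ifelse(has_event, etype, "none")

  # 4. diabetes onset among ASCVD survivors; an onset is *statin-induced*
  # only when the draw falls in the excess-probability band the odds ratio
  # adds (u in [p_base, p_adjusted)): onsets that would have happened
  # untreated are natural. A natural onset supersedes an earlier
  # statin-induced one (the excess attribution ends when the disease would
  # have arrived anyway).
  survived_ascvd <- !(has_event & fatal)
  nat_onset <- survived_ascvd & dr$u_diab < p_diab_base
  statin_onset <- survived_ascvd & dr$u_diab >= p_diab_base &
    dr$u_diab < adj$p_diab
  cohort$statin_diabetes[nat_onset] <- FALSE
  cohort$statin_diabetes[statin_onset] <- TRUE
  cohort$diabetes <- cohort$diabetes | nat_onset | statin_onset
  onset <- nat_onset | statin_onset

  # 5. background mortality; doubled for pre-existing post-event survivors
  q <- lookup_rate(ev$background_mortality, entry_age, entry_sex)
  q <- pmin(q * ifelse(entry_state %in% c("post_chd", "post_stroke"),
                       ev$post_event_mortality_multiplier, 1), 1)
  bg_death <- !(has_event & fatal) & dr$u_bg < q
  dead_end <- (has_event & fatal) | bg_death

  # 6. accrual (undiscounted); only statin-induced diabetes carries the
  # diabetes cost and disutility (the model tracks no consequences of
  # natural diabetes beyond its risk-equation covariate)
  cost <- accrue_cycle_cost(on_statin, event, entry_state, entry_years,
                            cohort$statin_diabetes, dead_end, params$costs)
  util <- accrue_cycle_utility(entry_age, entry_sex, event, entry_state,
                               entry_years, cohort$statin_diabetes, dead_end,
                               params$utilities)

  # 7. state updates, counters, projection, discontinuation draw
  new_post <- has_event & !fatal & !bg_death
  if (params$allow_recurrence) {
    # a second event never stacks decrements; stroke (larger long-term
    # decrement) takes precedence
    was_stroke <- entry_state == "post_stroke"
    cohort$state[new_post] <- ifelse(
      etype[new_post] == "stroke" | was_stroke[new_post],
      "post_stroke", "post_chd")
  } else {
    cohort$state[new_post] <- ifelse(etype[new_post] == "stroke",
                                     "post_stroke", "post_chd")
  }
  cohort$years_since_event[new_post] <- 0L
  cohort$state[dead_end] <- "dead"

  alive <- !dead_end
  post_now <- alive & cohort$state %in% c("post_chd", "post_stroke")
  cohort$years_since_event[post_now] <- cohort$years_since_event[post_now] + 1L
  cohort$treat_years[alive & on_statin] <-
    cohort$treat_years[alive & on_statin] + 1L
  if (any(alive)) {
    cohort[alive, ] <- update_treatment_state(
      cohort[alive, , drop = FALSE], strategy,
      u = dr$u_disc[alive], eligible = FALSE)
    cohort[alive, ] <- project_risk_factors(
      cohort[alive, , drop = FALSE], params$trends, params$floors)
  }

  record <- data.frame(
    id = cohort$id, age = entry_age,
    event = ifelse(event == "none" & bg_death, "background_death",
                   ifelse(event == "none", "none",
                          paste0(event, ifelse(fatal, "_fatal",
                                               "_nonfatal")))),
    diabetes_onset = onset, statin_diabetes_onset = statin_onset,
    treat = cohort$treat,
    cost = cost, utility = util, alive = alive,
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, record = record)
}

# core loop shared by run_strategy / run_individual; returns per-individual
# lifetime results. Draw streams are fixed-length per cycle so identical
# seeds give common random numbers across strategies.
simulate_cohort_ <- function(cohort, strategy, params, seed,
                             keep_log = FALSE) {
  n <- nrow(cohort)
  if (n == 0) stop("cohort is empty", call. = FALSE)
  rate <- params$utilities$discount_rate
  withr::with_seed(as.integer(seed), {
    cost <- qaly <- numeric(n)
    ly <- integer(n)
    n_chd <- n_stroke <- integer(n)
    ever_statin <- ever_statin_diab <- logical(n)
    death_age <- rep(NA_real_, n)
    log <- if (keep_log) vector("list", 64) else NULL
    cycle <- 0L
    active <- cohort$state != "dead" & cohort$age <= params$max_age
    while (any(active)) {
      draws <- list(u_event = stats::runif(n), u_type = stats::runif(n),
                    u_fatal = stats::runif(n), u_diab = stats::runif(n),
                    u_bg = stats::runif(n), u_disc = stats::runif(n))
      idx <- which(active)
      res <- run_cycle(cohort[idx, , drop = FALSE], strategy, params,
                       draws = lapply(draws, `[`, idx))
      cohort[idx, ] <- res$cohort
      rec <- res$record
      cost[idx] <- cost[idx] + discount(rec$cost, cycle, rate)
      qaly[idx] <- qaly[idx] + discount(rec$utility, cycle, rate)
      ly[idx] <- ly[idx] + as.integer(rec$alive)
      n_chd[idx] <- n_chd[idx] +
        as.integer(grepl("^chd", rec$event))
      n_stroke[idx] <- n_stroke[idx] +
        as.integer(grepl("^stroke", rec$event))
      ever_statin[idx] <- ever_statin[idx] | rec$treat != "never"
      ever_statin_diab[idx] <- ever_statin_diab[idx] |
        rec$statin_diabetes_onset
      died <- idx[!rec$alive]
      death_age[died] <- rec$age[!rec$alive]
      if (keep_log) {
        rec$cycle <- cycle
        log[[cycle + 1L]] <- rec
      }
      cycle <- cycle + 1L
      active <- cohort$state != "dead" & cohort$age <= params$max_age
    }
    out <- data.frame(
      id = cohort$id, cost = cost, qaly = qaly, life_years = ly,
      n_chd = n_chd, n_stroke = n_stroke,
      diabetes = cohort$diabetes, statin_diabetes = ever_statin_diab,
      ever_statin = ever_statin, death_age = death_age,
      exit_age = ifelse(is.na(death_age), cohort$age, death_age),
      stringsAsFactors = FALSE
    )
    attr(out, "event_log") <- if (keep_log) {
      do.call(rbind, log[!vapply(log, is.null, logical(1))])
    }
    out
  })
}

#' Simulate one individual's lifetime
#'
#' Runs annual cycles from baseline until death or the age cap and returns
#' summed discounted outcomes. Deterministic given the seed.
#'
#' @param profile one-row `cohort` data frame.
#' @param strategy a [strategy()].
#' @param params a [parameter_set()].
#' @param seed integer seed.
#' @return an object of class `lifetime_result`: list with `id`,
#'   `cost` and `qaly` (discounted totals), `life_years`, `events` (counts
#'   by type), `statin_diabetes`, `death_age` (`NA` if censored at the age
#'   cap) and `exit_age`.
#' @export
run_individual <- function(profile, strategy, params = parameter_set(),
                           seed) {
  stopifnot(nrow(profile) == 1)
  r <- simulate_cohort_(profile, strategy, params, seed)
  structure(list(id = r$id, cost = r$cost, qaly = r$qaly,
                 life_years = r$life_years,
                 events = c(chd = r$n_chd, stroke = r$n_stroke),
                 statin_diabetes = r$statin_diabetes,
                 death_age = r$death_age, exit_age = r$exit_age),
            class = "lifetime_result")
}

#' Simulate a cohort under one strategy
#'
#' Runs every individual to death or the age cap and aggregates. Random
#' draws are indexed by (individual, cycle, purpose) from the master seed,
#' so repeated calls with the same seed — including under different
#' strategies — consume identical streams: strategies are compared with
#' common random numbers.
#'
#' @param cohort a nonempty `cohort` data frame.
#' @param strategy a [strategy()].
#' @param params a [parameter_set()].
#' @param seed integer master seed.
#' @param keep_individuals if `TRUE`, attach the per-individual results
#'   (`$individuals`).
#' @param keep_log if `TRUE`, attach the full per-cycle event log
#'   (`$event_log`; large).
#' @return an object of class `strategy_result`: list with `name`, `n`,
#'   means (`mean_cost`, `mean_qaly`, `mean_life_years`, `life_expectancy`,
#'   `cvd_events_per_person`, `statin_diabetes_per_person`),
#'   `eligible_fraction` (fraction of the *baseline* cohort meeting the
#'   initiation rule), `initiated_fraction` (fraction ever starting statins
#'   over the lifetime, under annual rescreening), standard deviations
#'   (`sd_cost`, `sd_qaly`, `sd_life_years`), and the inputs' seed.
#' @export
run_strategy <- function(cohort, strategy, params = parameter_set(), seed,
                         keep_individuals = FALSE, keep_log = FALSE) {
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  ind <- simulate_cohort_(cohort, strategy, params, seed,
                          keep_log = keep_log)
  res <- list(
    name = strategy$name, n = nrow(ind), seed = as.integer(seed),
    mean_cost = mean(ind$cost), mean_qaly = mean(ind$qaly),
    mean_life_years = mean(ind$life_years),
    life_expectancy = mean(ind$exit_age),
    cvd_events_per_person = mean(ind$n_chd + ind$n_stroke),
    statin_diabetes_per_person = mean(ind$statin_diabetes),
    eligible_fraction =
      mean(is_eligible(cohort, strategy, params$coefficients)),
    initiated_fraction = mean(ind$ever_statin),
    sd_cost = stats::sd(ind$cost), sd_qaly = stats::sd(ind$qaly),
    sd_life_years = stats::sd(ind$life_years)
  )
  if (keep_individuals) res$individuals <- ind
  if (keep_log) res$event_log <- attr(ind, "event_log")
  structure(res, class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf(
    paste0("Strategy '%s' (n = %d)\n",
           "  mean discounted cost : %12.2f\n",
           "  mean discounted QALY : %12.4f\n",
           "  life expectancy      : %12.2f years\n",
           "  CVD events / person  : %12.4f\n",
           "  statin diabetes /pp  : %12.5f\n",
           "  ever statin-eligible : %12.1f%%\n"),
    x$name, x$n, x$mean_cost, x$mean_qaly, x$life_expectancy,
    x$cvd_events_per_person, x$statin_diabetes_per_person,
    100 * x$eligible_fraction))
  invisible(x)
}

#' Run several strategies with common random numbers
#'
#' Convenience wrapper running [run_strategy()] for each strategy with the
#' same master seed (common random numbers) and returning the list of
#' results, ready for [icer_ladder()].
#'
#' @param cohort a nonempty `cohort`.
#' @param strategies list of [strategy()] objects.
#' @param params a [parameter_set()].
#' @param seed master seed shared by all strategies.
#' @return named list of `strategy_result`s.
#' @export
run_strategies <- function(cohort, strategies, params = parameter_set(),
                           seed) {
  res <- lapply(strategies, function(s)
    run_strategy(cohort, s, params, seed))
  names(res) <- vapply(res, `[[`, "", "name")
  res
}

#' Strategy comparison table
#'
#' Flattens a list of `strategy_result`s into the standard comparison table
#' (eligible %, statin-induced diabetes cases and CVD events per person,
#' mean discounted QALYs, life expectancy, mean discounted costs).
#'
#' @param results list of `strategy_result`s.
#' @return data frame, one row per strategy.
#' @export
strategy_table <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    strategy = r$name, n = r$n,
    eligible_pct = 100 * r$eligible_fraction,
    initiated_pct = 100 * r$initiated_fraction,
    statin_diabetes_per_person = r$statin_diabetes_per_person,
    cvd_events_per_person = r$cvd_events_per_person,
    mean_qaly = r$mean_qaly, life_expectancy = r$life_expectancy,
    mean_cost = r$mean_cost, stringsAsFactors = FALSE)))
}
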