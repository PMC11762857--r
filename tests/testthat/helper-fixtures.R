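# Shared fixtures: toy coefficient sets, degenerate parameter sets with
# constant hazards, and an independent cohort-Markov oracle used to check
# the microsimulation engine.

# coefficient set with zero covariate effects: everyone has 10-year risk p10
flat_coefficients <- function(p10) {
  blk <- list(coefficients = c(age = 0), s0 = 1 - p10, mean_lp = 0)
  risk_coefficients(male = blk, female = blk)
}

zero_trends <- function() {
  z <- c(sbp = 0, tc = 0, hdl = 0, ldl = 0, wc = 0)
  age_trend_model(male = z, female = z)
}

const_table <- function(value) {
  rbind(data.frame(age_lo = 0, age_hi = 200, sex = "M", value = value),
        data.frame(age_lo = 0, age_hi = 200, sex = "F", value = value))
}

const_case_fatality <- function(chd = 0, stroke = chd) {
  rbind(data.frame(event = "chd", sex = c("M", "F"), age_lo = 0,
                   age_hi = 200, value = chd),
        data.frame(event = "stroke", sex = c("M", "F"), age_lo = 0,
                   age_hi = 200, value = stroke))
}

# parameter set with age-constant hazards throughout
constant_params <- function(p10 = 0, fatal_chd = 0, fatal_stroke = fatal_chd,
                            bg_mort = 0, diabetes_inc = 0, age_weight = 1,
                            discount_rate = 0.03, chd_share = 0.2946,
                            or_chd = 0.70, or_stroke = 0.81,
                            or_diabetes = 1.21, mult = 2,
                            costs = cost_parameters(),
                            allow_recurrence = FALSE) {
  parameter_set(
    coefficients = flat_coefficients(p10),
    trends = zero_trends(),
    events = event_parameters(
      chd_share = chd_share, or_chd = or_chd, or_stroke = or_stroke,
      or_diabetes = or_diabetes, post_event_mortality_multiplier = mult,
      case_fatality = const_case_fatality(fatal_chd, fatal_stroke),
      background_mortality = const_table(bg_mort),
      diabetes_incidence = const_table(diabetes_inc)),
    costs = costs,
    utilities = utility_parameters(age_weights = const_table(age_weight),
                                   discount_rate = discount_rate),
    allow_recurrence = allow_recurrence
  )
}

# a bare cohort of identical individuals
uniform_cohort <- function(n, age = 55, sex = "M") {
  data.frame(
    id = seq_len(n), age = age, sex = sex, sbp = 130, antihtn = FALSE,
    tc = 4.5, hdl = 1.2, ldl = 2.8, wc = 85, smoker = FALSE,
    diabetes = FALSE, statin_diabetes = FALSE,
    state = "event_free", treat = "never", treat_years = 0L,
    years_since_event = NA_integer_, stringsAsFactors = FALSE
  )
}

# Independent deterministic cohort-Markov recursion for identical
# individuals with age-constant hazards (no diabetes, no recurrence).
# `treated` is a logical vector over cycles: statin cost + odds-adjusted
# event probabilities in treated cycles. States: event-free, post-CHD /
# post-stroke in their first and in later post-event years.
markov_oracle <- function(age0, params, treated = FALSE,
                          max_age = params$max_age) {
  ev <- params$events
  cst <- params$costs
  ut <- params$utilities
  rate <- ut$discount_rate
  w <- ut$age_weights$value[1]
  p10 <- 1 - params$coefficients$male$s0
  p1 <- 1 - (1 - p10)^0.1
  q <- ev$background_mortality$value[1]
  q2 <- min(q * ev$post_event_mortality_multiplier, 1)
  f_c <- ev$case_fatality$value[ev$case_fatality$event == "chd"][1]
  f_s <- ev$case_fatality$value[ev$case_fatality$event == "stroke"][1]
  n_cycles <- max_age - age0 + 1
  treated <- rep_len(treated, n_cycles)

  odds_adj <- function(p, or) or * p / (1 - p + or * p)
  pi <- c(ef = 1, pc1 = 0, pc2 = 0, ps1 = 0, ps2 = 0)
  cost <- qaly <- ly <- 0
  for (t in seq_len(n_cycles) - 1) {
    tr <- treated[t + 1]
    pc <- p1 * ev$chd_share
    ps <- p1 * (1 - ev$chd_share)
    if (tr) { pc <- odds_adj(pc, ev$or_chd); ps <- odds_adj(ps, ev$or_stroke) }
    statin <- if (tr) cst$statin_annual else 0
    d <- 1 / (1 + rate)^t

    ef <- pi["ef"]
    # event-free branches
    chd_f  <- ef * pc * f_c
    chd_nf <- ef * pc * (1 - f_c)
    str_f  <- ef * ps * f_s
    str_nf <- ef * ps * (1 - f_s)
    none   <- ef * (1 - pc - ps)
    cost <- cost + d * (chd_f * cst$hosp_chd + str_f * cst$hosp_stroke +
      chd_nf * (1 - q) * (statin + cst$hosp_chd) +
      chd_nf * q * cst$hosp_chd +
      str_nf * (1 - q) * (statin + cst$hosp_stroke) +
      str_nf * q * cst$hosp_stroke +
      none * (1 - q) * statin)
    qaly <- qaly + d * (chd_nf * (1 - q) * max(w - ut$acute_chd, 0) +
      str_nf * (1 - q) * max(w - ut$acute_stroke, 0) +
      none * (1 - q) * w)
    ly <- ly + (chd_nf + str_nf + none) * (1 - q)

    # post-event states (doubled background mortality)
    for (st in c("pc1", "pc2", "ps1", "ps2")) {
      occ <- pi[st]
      if (occ == 0) next
      is_chd <- st %in% c("pc1", "pc2")
      run_cost <- if (st == "pc1") cst$first_year_chd else
        if (st == "pc2") cst$office_chd else
        if (st == "ps1") cst$first_year_stroke else cst$office_stroke
      lt <- if (is_chd) ut$longterm_chd else ut$longterm_stroke
      cost <- cost + d * occ * (1 - q2) * (statin + run_cost)
      qaly <- qaly + d * occ * (1 - q2) * max(w - lt, 0)
      ly <- ly + occ * (1 - q2)
    }

    pi <- c(
      ef  = unname(none * (1 - q)),
      pc1 = unname(chd_nf * (1 - q)),
      pc2 = unname((pi["pc1"] + pi["pc2"]) * (1 - q2)),
      ps1 = unname(str_nf * (1 - q)),
      ps2 = unname((pi["ps1"] + pi["ps2"]) * (1 - q2))
    )
  }
  list(cost = unname(cost), qaly = unname(qaly), life_years = unname(ly),
       life_expectancy = age0 + unname(ly))
}

# independent greedy convex-hull frontier: start from the cheapest
# non-dominated strategy, repeatedly move to the strategy with the smallest
# incremental ICER among strictly more effective ones
frontier_oracle <- function(df) {
  keep <- vapply(seq_len(nrow(df)), function(i) {
    !any(df$cost <= df$cost[i] & df$qaly >= df$qaly[i] &
           (df$cost < df$cost[i] | df$qaly > df$qaly[i]))
  }, logical(1))
  nd <- df[keep, , drop = FALSE]
  nd <- nd[order(nd$cost), , drop = FALSE]
  path <- nd$strategy[1]
  icers <- numeric(0)
  cur <- 1
  while (TRUE) {
    cand <- which(nd$qaly > nd$qaly[cur])
    if (!length(cand)) break
    ic <- (nd$cost[cand] - nd$cost[cur]) / (nd$qaly[cand] - nd$qaly[cur])
    nxt <- cand[which.min(ic)]
    path <- c(path, nd$strategy[nxt])
    icers <- c(icers, min(ic))
    cur <- nxt
  }
  list(strategies = path, icers = icers)
}
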