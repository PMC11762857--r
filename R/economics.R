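# Cost and QALY accrual, discounting, the ICER ladder with (extended)
# dominance, and cost-effectiveness acceptability curves.

#' Direct medical cost parameters (2022 CN¥)
#'
#' Healthcare-system perspective, ASCVD-related direct costs only: annual
#' statin treatment, event hospitalization (AMI / stroke), first-year
#' post-event care, subsequent annual office visits, and an annual diabetes
#' management cost (default 0 until supplied; it is not part of the core
#' parameter table).
#'
#' @param statin_annual annual statin cost.
#' @param hosp_chd,hosp_stroke hospitalization cost of an incident event.
#' @param first_year_chd,first_year_stroke first post-event-year cost.
#' @param office_chd,office_stroke annual office-visit cost in later years.
#' @param diabetes_annual annual diabetes management cost.
#' @param currency_year label only.
#' @return an object of class `cost_parameters`.
#' @export
cost_parameters <- function(statin_annual = 1149.75,
                            hosp_chd = 22611, hosp_stroke = 13983,
                            first_year_chd = 5255.85,
                            first_year_stroke = 2652,
                            office_chd = 585.87, office_stroke = 565,
                            diabetes_annual = 0,
                            currency_year = "2022 CN¥") {
  vals <- c(statin_annual, hosp_chd, hosp_stroke, first_year_chd,
            first_year_stroke, office_chd, office_stroke, diabetes_annual)
  if (any(!is.finite(vals) | vals < 0)) {
    stop("all costs must be finite and >= 0", call. = FALSE)
  }
  structure(list(statin_annual = statin_annual,
                 hosp_chd = hosp_chd, hosp_stroke = hosp_stroke,
                 first_year_chd = first_year_chd,
                 first_year_stroke = first_year_stroke,
                 office_chd = office_chd, office_stroke = office_stroke,
                 diabetes_annual = diabetes_annual,
                 currency_year = currency_year),
            class = "cost_parameters")
}

#' Health-utility parameters
#'
#' Age-specific utility weights (EQ-5D-style general-population norms;
#' packaged default is a synthetic declining table, replaceable) and
#' event-related utility decrements, applied additively and floored at 0:
#' acute decrements in the event cycle (CHD 0.439, stroke 0.92), long-term
#' decrements in every post-event cycle (AMI 0.107, stroke 0.266), and an
#' optional diabetes decrement (default 0). Costs and QALYs share one annual
#' discount rate (default 3%).
#'
#' @param age_weights rate table `age_lo, age_hi, sex, value` of utility
#'   weights in `[0, 1]`.
#' @param acute_chd,acute_stroke acute event-cycle decrements.
#' @param longterm_chd,longterm_stroke per-cycle post-event decrements.
#' @param diabetes annual decrement while diabetic.
#' @param discount_rate annual discount rate, `>= 0`.
#' @return an object of class `utility_parameters`.
#' @export
utility_parameters <- function(age_weights = default_age_weights(),
                               acute_chd = 0.439, acute_stroke = 0.92,
                               longterm_chd = 0.107, longterm_stroke = 0.266,
                               diabetes = 0, discount_rate = 0.03) {
  dec <- c(acute_chd, acute_stroke, longterm_chd, longterm_stroke, diabetes)
  if (any(dec < 0 | dec > 1)) {
    stop("utility decrements must lie in [0, 1]", call. = FALSE)
  }
  if (discount_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  validate_rate_table(age_weights, "age_weights")
  structure(list(age_weights = age_weights,
                 acute_chd = acute_chd, acute_stroke = acute_stroke,
                 longterm_chd = longterm_chd,
                 longterm_stroke = longterm_stroke,
                 diabetes = diabetes, discount_rate = discount_rate),
            class = "utility_parameters")
}

#' Synthetic age-specific utility weights
#'
#' Declining general-population utility norms by 10-year age band, identical
#' for both sexes. Synthetic stand-in for a national EQ-5D survey table.
#'
#' @return rate table `age_lo, age_hi, sex, value`.
#' @export
default_age_weights <- function() {
  lo <- c(40, 50, 60, 70, 80); hi <- c(49, 59, 69, 79, 89)
  v <- c(0.95, 0.93, 0.90, 0.86, 0.79)
  rbind(data.frame(age_lo = lo, age_hi = hi, sex = "M", value = v),
        data.frame(age_lo = lo, age_hi = hi, sex = "F", value = v))
}

#' Willingness-to-pay thresholds (CN¥ per QALY)
#'
#' 1x and 3x 2022 Chinese GDP per capita, the decision thresholds used to
#' judge cost-effectiveness.
#'
#' @return named numeric vector `c(gdp1 = 85700, gdp3 = 257100)`.
#' @export
wtp_thresholds <- function() c(gdp1 = 85700, gdp3 = 257100)

#' Undiscounted cost of one annual cycle
#'
#' Accrual rules: statin cost while on statins; event-cycle hospitalization;
#' first post-event year adds the first-year care cost; later post-event
#' years add the annual office visit; diabetes adds its annual management
#' cost. A cycle ending in death accrues only the event hospitalization (if
#' an event occurred that cycle).
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param on_statin logical, on statins this cycle.
#' @param event `"none"`, `"chd"` or `"stroke"`: incident event this cycle.
#' @param post_state `"event_free"`, `"post_chd"` or `"post_stroke"` — state
#'   *entering* the cycle.
#' @param years_post years since the first event at cycle start (`NA` if
#'   event-free).
#' @param diabetic logical.
#' @param dead_end logical, dead at the end of this cycle.
#' @param costs a [cost_parameters()] object.
#' @return numeric vector of undiscounted cycle costs.
#' @export
accrue_cycle_cost <- function(on_statin, event = "none",
                              post_state = "event_free", years_post = NA,
                              diabetic = FALSE, dead_end = FALSE,
                              costs = cost_parameters()) {
  n <- max(length(on_statin), length(event), length(post_state),
           length(years_post), length(diabetic), length(dead_end))
  on_statin <- rep_len(on_statin, n); event <- rep_len(event, n)
  post_state <- rep_len(post_state, n); years_post <- rep_len(years_post, n)
  diabetic <- rep_len(diabetic, n); dead_end <- rep_len(dead_end, n)

  hosp <- ifelse(event == "chd", costs$hosp_chd,
                 ifelse(event == "stroke", costs$hosp_stroke, 0))
  yp <- ifelse(is.na(years_post), -1, years_post)
  first_year <- ifelse(post_state == "post_chd" & yp == 1, costs$first_year_chd,
                ifelse(post_state == "post_stroke" & yp == 1,
                       costs$first_year_stroke, 0))
  office <- ifelse(post_state == "post_chd" & yp >= 2, costs$office_chd,
            ifelse(post_state == "post_stroke" & yp >= 2,
                   costs$office_stroke, 0))
  alive_cost <- costs$statin_annual * as.numeric(on_statin) + hosp +
    first_year + office + costs$diabetes_annual * as.numeric(diabetic)
  ifelse(dead_end, hosp, alive_cost)
}

#' Undiscounted utility of one annual cycle
#'
#' Age-specific weight minus applicable decrements (acute in the event
#' cycle; long-term in every post-event cycle; diabetes while diabetic),
#' floored at 0. A cycle ending in death contributes 0.
#'
#' @param age,sex age (years) and sex (`"M"`/`"F"`) at cycle start.
#' @inheritParams accrue_cycle_cost
#' @param utils a [utility_parameters()] object.
#' @return numeric vector of undiscounted cycle utilities.
#' @export
accrue_cycle_utility <- function(age, sex, event = "none",
                                 post_state = "event_free", years_post = NA,
                                 diabetic = FALSE, dead_end = FALSE,
                                 utils = utility_parameters()) {
  n <- max(length(age), length(sex), length(event), length(post_state),
           length(years_post), length(diabetic), length(dead_end))
  age <- rep_len(age, n); sex <- rep_len(sex, n); event <- rep_len(event, n)
  post_state <- rep_len(post_state, n); years_post <- rep_len(years_post, n)
  diabetic <- rep_len(diabetic, n); dead_end <- rep_len(dead_end, n)

  w <- lookup_rate(utils$age_weights, age, sex)
  acute <- ifelse(event == "chd", utils$acute_chd,
                  ifelse(event == "stroke", utils$acute_stroke, 0))
  yp <- ifelse(is.na(years_post), -1, years_post)
  longterm <- ifelse(post_state == "post_chd" & yp >= 1, utils$longterm_chd,
              ifelse(post_state == "post_stroke" & yp >= 1,
                     utils$longterm_stroke, 0))
  u <- pmax(w - acute - longterm - utils$diabetes * as.numeric(diabetic), 0)
  ifelse(dead_end, 0, u)
}

#' Discount a value to present value
#'
#' `value / (1 + rate)^cycle_index`; cycle 0 is undiscounted.
#'
#' @param value money or utility (vectorised).
#' @param cycle_index integer cycle index `>= 0` (vectorised).
#' @param rate annual discount rate `>= 0`.
#' @return discounted value(s).
#' @export
discount <- function(value, cycle_index, rate = 0.03) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0", call. = FALSE)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  value / (1 + rate)^cycle_index
}

as_ce_table <- function(results) {
  if (is.data.frame(results)) {
    stopifnot(all(c("strategy", "cost", "qaly") %in% names(results)))
    df <- results[, c("strategy", "cost", "qaly")]
  } else {
    df <- do.call(rbind, lapply(results, function(r) {
      data.frame(strategy = r$name, cost = r$mean_cost, qaly = r$mean_qaly,
                 stringsAsFactors = FALSE)
    }))
  }
  if (anyDuplicated(df$strategy)) {
    stop("duplicate strategy names", call. = FALSE)
  }
  df
}

#' Cost-effectiveness frontier with (extended) dominance
#'
#' Sorts strategies by ascending mean cost, removes dominated strategies
#' (another strategy has no higher cost and no lower QALY), then iteratively
#' removes extended-dominated strategies (whose incremental ICER exceeds
#' that of the next step) until ICERs are nondecreasing along the frontier.
#'
#' @param results list of `strategy_result` objects from [run_strategy()], or
#'   a data frame with columns `strategy`, `cost`, `qaly`.
#' @return an object of class `ce_frontier`: a data frame with columns
#'   `strategy`, `cost`, `qaly`, `status`
#'   (`on_frontier` / `dominated` / `extended_dominated`) and `icer`
#'   (vs the previous frontier step; `NA` for the anchor and for
#'   off-frontier strategies).
#' @export
icer_ladder <- function(results) {
  df <- as_ce_table(results)
  df <- df[order(df$cost, df$qaly), , drop = FALSE]
  n <- nrow(df)
  df$status <- "on_frontier"
  df$icer <- NA_real_

  # strict dominance: some other strategy is no worse on both axes and
  # better on at least one
  for (i in seq_len(n)) {
    others <- df[-i, , drop = FALSE]
    dom <- others$cost <= df$cost[i] & others$qaly >= df$qaly[i] &
      (others$cost < df$cost[i] | others$qaly > df$qaly[i])
    if (any(dom)) df$status[i] <- "dominated"
  }

  # extended dominance on the surviving ladder
  repeat {
    keep <- which(df$status == "on_frontier")
    if (length(keep) < 3) break
    sub <- df[keep, , drop = FALSE]
    ic <- diff(sub$cost) / diff(sub$qaly)
    # drop the first interior strategy whose step ICER exceeds the next step's
    bad <- which(utils::head(ic, -1) > utils::tail(ic, -1))
    if (!length(bad)) break
    df$status[keep[bad[1] + 1]] <- "extended_dominated"
  }

  keep <- which(df$status == "on_frontier")
  if (length(keep) > 1) {
    sub <- df[keep, , drop = FALSE]
    df$icer[keep[-1]] <- diff(sub$cost) / diff(sub$qaly)
  }
  structure(df, class = c("ce_frontier", "data.frame"))
}

#' @export
print.ce_frontier <- function(x, ...) {
  cat("Cost-effectiveness frontier\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability (over PSA draws) that
#' each strategy maximises net monetary benefit `wtp * QALY - cost`. Ties
#' within a draw are split equally, so probabilities sum to 1 at every
#' willingness-to-pay point.
#'
#' @param psa_draws data frame with columns `draw`, `strategy`, `cost`,
#'   `qaly` (one row per draw x strategy), e.g. `run_psa(...)$draws`.
#' @param wtp_grid numeric vector of willingness-to-pay values.
#' @return data frame `wtp, strategy, probability`.
#' @export
ceac <- function(psa_draws, wtp_grid) {
  stopifnot(is.data.frame(psa_draws),
            all(c("draw", "strategy", "cost", "qaly") %in% names(psa_draws)),
            length(wtp_grid) >= 1)
  if (nrow(psa_draws) == 0) stop("psa_draws is empty", call. = FALSE)
  strategies <- unique(psa_draws$strategy)
  draws <- unique(psa_draws$draw)
  cost <- matrix(NA_real_, length(draws), length(strategies),
                 dimnames = list(NULL, strategies))
  qaly <- cost
  for (s in strategies) {
    sub <- psa_draws[psa_draws$strategy == s, ]
    sub <- sub[match(draws, sub$draw), ]
    cost[, s] <- sub$cost
    qaly[, s] <- sub$qaly
  }
  out <- vector("list", length(wtp_grid))
  for (k in seq_along(wtp_grid)) {
    nmb <- wtp_grid[k] * qaly - cost
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best)            # ties split equally
    out[[k]] <- data.frame(wtp = wtp_grid[k], strategy = strategies,
                           probability = colMeans(share),
                           row.names = NULL)
  }
  do.call(rbind, out)
}
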