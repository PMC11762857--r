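test_that("parameter sampling recovers the configured moments", {
  n <- 1e5
  specs <- list(
    fx = dist_spec("fixed", 0.03),
    b1 = dist_spec("beta", 0.107, 0.019),
    g1 = dist_spec("gamma", 1149.75, 150),
    l1 = dist_spec("lognormal", 0.7, 0.072)
  )
  draws <- sample_parameters(specs, seed = 61, n = n)
  expect_equal(draws$fx, rep(0.03, n))
  for (nm in c("b1", "g1", "l1")) {
    x <- draws[[nm]]
    target_mean <- specs[[nm]]$value
    target_sd <- specs[[nm]]$se
    expect_lt(abs(mean(x) - target_mean), 3 * sd(x) / sqrt(n))
    # MC standard error of the sample SD from the fourth moment
    m4 <- mean((x - mean(x))^4)
    se_sd <- sqrt(max(m4 - var(x)^2, 0) / n) / (2 * sd(x))
    expect_lt(abs(sd(x) - target_sd), 3 * se_sd + 3e-4)
  }
  expect_true(all(draws$b1 >= 0 & draws$b1 <= 1))
  expect_true(all(draws$g1 > 0) && all(draws$l1 > 0))

  # determinism and the missing-SE fallback
  expect_identical(sample_parameters(specs, seed = 61, n = 10),
                   sample_parameters(specs, seed = 61, n = 10))
  expect_warning(
    out <- sample_parameters(list(g = dist_spec("gamma", 5)), seed = 1,
                             n = 3),
    "fixed")
  expect_equal(out$g, rep(5, 3))
})

test_that("one-way DSA: inert parameters have zero width, costs move ICERs monotonically", {
  params <- constant_params(p10 = 0.25, fatal_chd = 0.3, bg_mort = 0.02)
  co <- uniform_cohort(400)
  strategies <- list(strategy("none"),
                     strategy("treat", threshold = 0.05))
  runner <- function(p) {
    lad <- icer_ladder(run_strategies(co, strategies, p, seed = 71))
    lad$icer[lad$strategy == "treat"]
  }
  base_icer <- runner(params)
  expect_true(is.finite(base_icer) && base_icer > 0)

  # a parameter with no model influence here (no one has diabetes costs)
  inert <- one_way_dsa(params, "diabetes_cost", 0, 1000, runner)
  expect_equal(inert$range, 0)

  # statin price enters only the incremental numerator: ICER increases
  price <- vapply(c(0.8, 1.0, 1.2) * 1149.75, function(v)
    runner(set_parameter(params, "statin_cost", v)), numeric(1))
  expect_true(all(diff(price) > 0))

  # weakening the CHD effect (OR toward 1) raises the ICER
  or_sweep <- vapply(c(0.70, 0.85, 0.95), function(v)
    runner(set_parameter(params, "or_chd", v)), numeric(1))
  expect_true(all(diff(or_sweep) > 0))

  expect_error(one_way_dsa(params, "no_such_param", 0, 1, runner),
               "unknown parameter")

  ranges <- default_dsa_ranges()
  expect_equal(ranges$low[ranges$parameter == "or_chd"],
               0.70 - 1.96 * 0.072)
  expect_equal(ranges$high[ranges$parameter == "statin_cost"],
               1.2 * 1149.75)
})

test_that("tornado orders parameters by induced range", {
  params <- constant_params(p10 = 0.25, fatal_chd = 0.3, bg_mort = 0.02)
  co <- uniform_cohort(300)
  strategies <- list(strategy("none"), strategy("treat", threshold = 0.05))
  runner <- function(p) {
    lad <- icer_ladder(run_strategies(co, strategies, p, seed = 72))
    lad$icer[lad$strategy == "treat"]
  }
  ranges <- data.frame(
    parameter = c("statin_cost", "diabetes_cost"),
    low = c(0.8 * 1149.75, 0), high = c(1.2 * 1149.75, 500)
  )
  tor <- tornado(params, ranges, runner)
  expect_equal(tor$parameter[1], "statin_cost")
  expect_equal(tor$range[tor$parameter == "diabetes_cost"], 0)
  expect_true(all(diff(tor$range) <= 0))
})

test_that("PSA with all-fixed specs reproduces the base case and is deterministic", {
  params <- constant_params(p10 = 0.25, fatal_chd = 0.3, bg_mort = 0.02)
  co <- uniform_cohort(250)
  strategies <- list(strategy("none"), strategy("treat", threshold = 0.05))
  fixed_specs <- list(statin_cost = dist_spec("fixed", 1149.75),
                      or_chd = dist_spec("fixed", 0.70))
  psa <- run_psa(co, strategies, fixed_specs, n_draws = 2, seed = 81,
                 params = params)
  expect_equal(nrow(psa$draws), 4)
  rerun <- run_psa(co, strategies, fixed_specs, n_draws = 2, seed = 81,
                   params = params)
  expect_identical(psa$draws, rerun$draws)

  # with no parameter uncertainty every draw equals the base case exactly
  base <- run_strategies(co, strategies, params, seed = 82)
  d1 <- psa$draws[psa$draws$draw == 1, ]
  d2 <- psa$draws[psa$draws$draw == 2, ]
  expect_equal(d1[, c("cost", "qaly")], d2[, c("cost", "qaly")],
               ignore_attr = TRUE)
  expect_equal(d1$cost, vapply(base, `[[`, 0, "mean_cost"),
               ignore_attr = TRUE)
  expect_equal(d1$qaly, vapply(base, `[[`, 0, "mean_qaly"),
               ignore_attr = TRUE)

  # probability-optimal is degenerate 0/1 at any WTP under fixed specs
  po <- probability_optimal(psa, wtp = c(10000, 300000))
  expect_true(all(po$probability %in% c(0, 1)))
})

test_that("internal validation computes least-squares R-squared", {
  perfect <- internal_validation(c(0.01, 0.02, 0.03), c(0.01, 0.02, 0.03))
  expect_equal(perfect$r2, 1)

  iv <- internal_validation(c(0.01, 0.02, 0.03), c(0.012, 0.019, 0.031))
  # cross-check against the closed-form squared correlation
  r2_closed <- cor(c(0.01, 0.02, 0.03), c(0.012, 0.019, 0.031))^2
  expect_equal(iv$r2, r2_closed)

  expect_warning(flat <- internal_validation(c(0.01, 0.02, 0.03),
                                             c(0.02, 0.02, 0.02)),
                 "degenerate")
  expect_true(is.na(flat$r2))
})

test_that("untreated-run internal validation has strong group-level fit", {
  co <- generate_cohort(20000, seed = 91)
  params <- parameter_set()
  v <- validate_internal(co, params, seed = 92)
  expect_gte(nrow(v$table), 6)
  expect_gt(v$r2, 0.8)
})

test_that("external validation reports deltas or an empty report", {
  expect_warning(empty <- external_validation(
    data.frame(group = "M_50", value = 0.1),
    data.frame(group = character(), value = numeric())), "skipped")
  expect_equal(nrow(empty), 0)

  self <- external_validation(data.frame(group = c("a", "b"),
                                         value = c(1, 2)),
                              data.frame(group = c("a", "b"),
                                         value = c(1, 2)))
  expect_equal(self$delta, c(0, 0))

  # doubling all-cause mortality strictly lowers simulated life expectancy
  lo <- constant_params(bg_mort = 0.02)
  hi <- constant_params(bg_mort = 0.04)
  co <- uniform_cohort(2000)
  le_lo <- run_strategy(co, strategy("none"), lo, seed = 93)$life_expectancy
  le_hi <- run_strategy(co, strategy("none"), hi, seed = 93)$life_expectancy
  expect_lt(le_hi, le_lo)
})
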