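test_that("a cycle with all hazards zero is pure ageing", {
  params <- constant_params()
  co <- uniform_cohort(5)
  res <- run_cycle(co, strategy("none"), params)
  expect_true(all(res$record$event == "none"))
  expect_true(all(res$record$alive))
  expect_equal(res$cohort$age, rep(56, 5))
  expect_true(all(res$cohort$state == "event_free"))
  expect_equal(res$record$cost, rep(0, 5))
  expect_equal(res$record$utility, rep(1, 5))

  expect_error(run_cycle(res$cohort |> transform(state = "dead"),
                         strategy("none"), params), "all-alive")
})

test_that("a forced event with certain fatality is absorbing death", {
  params <- constant_params(p10 = 0.99, fatal_chd = 1)
  co <- uniform_cohort(1)
  res <- run_cycle(co, strategy("none"), params,
                   draws = list(u_event = 0, u_type = 0, u_fatal = 0,
                                u_diab = 1, u_bg = 1, u_disc = 1))
  expect_equal(res$record$event, "chd_fatal")
  expect_equal(res$cohort$state, "dead")
  expect_false(res$record$alive)
  expect_equal(res$record$utility, 0)
  expect_equal(res$record$cost, cost_parameters()$hosp_chd)
})

test_that("cycle event rate matches the configured constant hazard", {
  p1 <- 0.02
  p10 <- 1 - (1 - p1)^10
  params <- constant_params(p10 = p10)
  n <- 2e5
  co <- uniform_cohort(n)
  res <- withr::with_seed(31, run_cycle(co, strategy("none"), params))
  rate <- mean(res$record$event != "none")
  expect_lt(abs(rate - p1), 3 * sqrt(p1 * (1 - p1) / n))
  # type split among events honours the CHD share
  ev <- res$record$event[res$record$event != "none"]
  frac_chd <- mean(grepl("chd", ev))
  expect_lt(abs(frac_chd - 0.2946),
            3 * sqrt(0.2946 * 0.7054 / length(ev)))
})

test_that("individual lifetimes respect the age cap and determinism", {
  params <- constant_params()
  old <- uniform_cohort(1, age = 89)
  r <- run_individual(old, strategy("none"), params, seed = 5)
  expect_equal(r$life_years, 1)
  expect_equal(r$exit_age, 90)
  expect_true(is.na(r$death_age))

  # all hazards zero: survive to the cap from age 55
  r2 <- run_individual(uniform_cohort(1), strategy("none"), params, seed = 5)
  expect_equal(r2$life_years, 89 - 55 + 1)
  expect_equal(sum(r2$events), 0)

  # determinism under a fixed seed
  params_risky <- constant_params(p10 = 0.3, fatal_chd = 0.3, bg_mort = 0.02)
  a <- run_individual(uniform_cohort(1), strategy("none"), params_risky, 77)
  b <- run_individual(uniform_cohort(1), strategy("none"), params_risky, 77)
  expect_identical(a, b)
})

test_that("strategies are compared under common random numbers", {
  params <- constant_params(p10 = 0.3, fatal_chd = 0.3, bg_mort = 0.02,
                            diabetes_inc = 0.01)
  co <- uniform_cohort(300)
  s_a <- strategy("a", threshold = 0.10)
  s_b <- strategy("b", threshold = 0.10)
  ra <- run_strategy(co, s_a, params, seed = 9)
  rb <- run_strategy(co, s_b, params, seed = 9)
  for (f in c("mean_cost", "mean_qaly", "mean_life_years",
              "cvd_events_per_person", "statin_diabetes_per_person")) {
    expect_identical(ra[[f]], rb[[f]])
  }
  expect_error(run_strategy(co[0, ], s_a, params, seed = 1), "empty")
})

test_that("no-treatment strategy accrues no statin exposure or cost", {
  params <- constant_params(p10 = 0.2, bg_mort = 0.02,
                            costs = cost_parameters(
                              hosp_chd = 0, hosp_stroke = 0,
                              first_year_chd = 0, first_year_stroke = 0,
                              office_chd = 0, office_stroke = 0))
  res <- run_strategy(uniform_cohort(200), strategy("none"), params,
                      seed = 3)
  expect_equal(res$eligible_fraction, 0)
  expect_equal(res$initiated_fraction, 0)
  expect_equal(res$mean_cost, 0)
})

test_that("post-event survivors face the doubled background mortality", {
  # survivors of a cycle-0 event then face q2 = 2q; compare survival of a
  # post-event cohort against the Markov oracle's post-state row
  q <- 0.05
  params <- constant_params(bg_mort = q, mult = 2)
  co <- uniform_cohort(20000)
  co$state <- "post_chd"
  co$years_since_event <- 3L
  res <- withr::with_seed(41, run_cycle(co, strategy("none"), params))
  died <- mean(!res$record$alive)
  expect_lt(abs(died - 2 * q), 3 * sqrt(2 * q * (1 - 2 * q) / nrow(co)))

  # multiplier is configurable
  params3 <- constant_params(bg_mort = q, mult = 3)
  res3 <- withr::with_seed(41, run_cycle(co, strategy("none"), params3))
  died3 <- mean(!res3$record$alive)
  expect_lt(abs(died3 - 3 * q), 3 * sqrt(3 * q * (1 - 3 * q) / nrow(co)))
})

test_that("statin-induced diabetes affects accrual but never ASCVD risk", {
  # diabetes decrement/cost configured: only statin-attributable onsets carry
  # them; and CVD event probabilities are identical whether or not the
  # diabetes OR inflates onsets (risk equation uses the baseline flag only)
  p10 <- 0.15
  co <- uniform_cohort(5000)
  base <- constant_params(p10 = p10, diabetes_inc = 0.05, or_diabetes = 1.21)
  no_excess <- constant_params(p10 = p10, diabetes_inc = 0.05,
                               or_diabetes = 1)
  # give diabetes a real risk-equation coefficient so any leakage of the
  # statin-induced flag into the covariate would change event probabilities
  blk <- list(coefficients = c(diabetes = 0.6), s0 = 1 - p10, mean_lp = 0)
  base$coefficients <- risk_coefficients(blk, blk)
  no_excess$coefficients <- risk_coefficients(blk, blk)
  s <- strategy("treat_all", threshold = 0.01)
  r1 <- run_strategy(co, s, base, seed = 13, keep_individuals = TRUE)
  r2 <- run_strategy(co, s, no_excess, seed = 13, keep_individuals = TRUE)
  # same event stream under CRN: ASCVD outcomes unchanged by the diabetes OR
  expect_identical(r1$cvd_events_per_person, r2$cvd_events_per_person)
  # with OR 1 no onset is attributed to statins
  expect_equal(r2$statin_diabetes_per_person, 0)
  expect_gt(r1$statin_diabetes_per_person, 0)
})

test_that("microsimulation means match the deterministic Markov oracle", {
  p10 <- 0.25
  params <- constant_params(p10 = p10, fatal_chd = 0.3, fatal_stroke = 0.2,
                            bg_mort = 0.02, discount_rate = 0.03)
  n <- 20000
  co <- uniform_cohort(n, age = 55)
  res <- run_strategy(co, strategy("none"), params, seed = 17)
  oracle <- markov_oracle(55, params, treated = FALSE)

  expect_lt(abs(res$mean_life_years - oracle$life_years),
            3 * res$sd_life_years / sqrt(n))
  expect_lt(abs(res$mean_qaly - oracle$qaly), 3 * res$sd_qaly / sqrt(n))
  expect_lt(abs(res$mean_cost - oracle$cost), 3 * res$sd_cost / sqrt(n))
})

test_that("the treated arm matches the discontinuation-mixture oracle", {
  p10 <- 0.25
  params <- constant_params(p10 = p10, fatal_chd = 0.3, fatal_stroke = 0.2,
                            bg_mort = 0.02, discount_rate = 0.03)
  n <- 20000
  co <- uniform_cohort(n, age = 55)
  res <- run_strategy(co, strategy("treat", threshold = 0.05), params,
                      seed = 19)
  n_cycles <- 89 - 55 + 1
  adherent <- markov_oracle(55, params, treated = TRUE)
  stopper <- markov_oracle(55, params,
                           treated = c(TRUE, rep(FALSE, n_cycles - 1)))
  mix <- function(f) 0.6 * adherent[[f]] + 0.4 * stopper[[f]]
  expect_lt(abs(res$mean_qaly - mix("qaly")), 3 * res$sd_qaly / sqrt(n))
  expect_lt(abs(res$mean_cost - mix("cost")), 3 * res$sd_cost / sqrt(n))
  expect_lt(abs(res$mean_life_years - mix("life_years")),
            3 * res$sd_life_years / sqrt(n))
  # treatment prolongs life in the oracle too
  untreated <- markov_oracle(55, params, treated = FALSE)
  expect_gt(mix("life_years"), untreated$life_years)
})
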