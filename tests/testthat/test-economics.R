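test_that("cycle cost accrual follows the tabulated components", {
  costs <- cost_parameters()
  # on statins, event-free, no diabetes
  expect_equal(accrue_cycle_cost(TRUE, costs = costs), 1149.75)
  # untreated, event-free: nothing accrues
  expect_equal(accrue_cycle_cost(FALSE, costs = costs), 0)
  # non-fatal AMI cycle while on statins
  expect_equal(accrue_cycle_cost(TRUE, event = "chd", costs = costs),
               22611 + 1149.75)
  expect_equal(accrue_cycle_cost(TRUE, event = "chd", costs = costs),
               23760.75)
  # first post-event year, then subsequent years
  expect_equal(accrue_cycle_cost(FALSE, post_state = "post_chd",
                                 years_post = 1, costs = costs), 5255.85)
  expect_equal(accrue_cycle_cost(FALSE, post_state = "post_stroke",
                                 years_post = 4, costs = costs), 565)
  # fatal cycles: hospitalization only (statin cost does not accrue)
  expect_equal(accrue_cycle_cost(TRUE, event = "stroke", dead_end = TRUE,
                                 costs = costs), 13983)
  expect_equal(accrue_cycle_cost(TRUE, dead_end = TRUE, costs = costs), 0)
  # diabetes management cost once configured
  costs_d <- cost_parameters(diabetes_annual = 800)
  expect_equal(accrue_cycle_cost(FALSE, diabetic = TRUE, costs = costs_d),
               800)
  expect_error(cost_parameters(statin_annual = -1), ">= 0")
})

test_that("cycle utility is the age weight minus floored decrements", {
  ut <- utility_parameters(age_weights = const_table(0.90))
  # stroke event cycle: 0.90 - 0.92 floors at 0
  expect_equal(accrue_cycle_utility(70, "M", event = "stroke", utils = ut),
               0)
  ut85 <- utility_parameters(age_weights = const_table(0.85))
  expect_equal(accrue_cycle_utility(70, "M", post_state = "post_chd",
                                    years_post = 3, utils = ut85),
               0.85 - 0.107)
  expect_equal(accrue_cycle_utility(70, "M", post_state = "post_chd",
                                    years_post = 3, utils = ut85), 0.743)
  # event-free, non-diabetic: weight unchanged
  expect_equal(accrue_cycle_utility(70, "M", utils = ut85), 0.85)
  # death cycle contributes nothing
  expect_equal(accrue_cycle_utility(70, "M", dead_end = TRUE, utils = ut85),
               0)
  # acute decrement applies only in the event cycle, long-term thereafter
  expect_equal(accrue_cycle_utility(70, "M", event = "chd", utils = ut85),
               0.85 - 0.439)
  expect_error(utility_parameters(acute_chd = 1.5), "\\[0, 1\\]")
})

test_that("discounting is exponential in the cycle index", {
  expect_equal(discount(100, 0, 0.03), 100)
  expect_equal(discount(103, 1, 0.03), 100)
  expect_equal(discount(250, 7, 0), 250)
  expect_equal(discount(100, 10, 0.03), 100 / 1.03^10)
  expect_error(discount(100, -1, 0.03), ">= 0")
  # lifetime discounted totals shrink as the rate grows
  vals <- rep(1, 30)
  totals <- vapply(c(0, 0.01, 0.03, 0.05, 0.08),
                   function(r) sum(discount(vals, 0:29, r)), numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("icer_ladder reproduces hand-computed frontiers", {
  one <- icer_ladder(data.frame(strategy = "A", cost = 5, qaly = 2))
  expect_equal(one$status, "on_frontier")
  expect_true(is.na(one$icer))

  abc <- icer_ladder(data.frame(strategy = c("A", "B", "C"),
                                cost = c(0, 100, 150),
                                qaly = c(10, 11, 11.05)))
  expect_equal(abc$status, rep("on_frontier", 3))
  expect_equal(abc$icer, c(NA, 100, 1000))

  ext <- icer_ladder(data.frame(strategy = c("A", "B", "C"),
                                cost = c(0, 100, 120),
                                qaly = c(10, 10.2, 10.5)))
  expect_equal(ext$status[ext$strategy == "B"], "extended_dominated")
  expect_equal(ext$icer[ext$strategy == "C"], 120 / 0.5)

  dom <- icer_ladder(data.frame(strategy = c("A", "B"),
                                cost = c(10, 20), qaly = c(5, 4)))
  expect_equal(dom$status[dom$strategy == "B"], "dominated")

  expect_error(icer_ladder(data.frame(strategy = c("A", "A"),
                                      cost = 1:2, qaly = 1:2)),
               "duplicate")
})

test_that("icer_ladder agrees with the greedy convex-hull oracle", {
  set.seed(4711)
  for (trial in 1:300) {
    k <- sample(2:6, 1)
    df <- data.frame(strategy = paste0("s", 1:k),
                     cost = runif(k, 0, 1000), qaly = runif(k, 0, 10))
    lad <- icer_ladder(df)
    oracle <- frontier_oracle(df)
    on_front <- lad$strategy[lad$status == "on_frontier"]
    expect_equal(on_front, oracle$strategies)
    expect_equal(lad$icer[lad$status == "on_frontier"][-1], oracle$icers,
                 tolerance = 1e-10)
  }
})

test_that("the published strategy table yields a coherent frontier", {
  # rounded published aggregates: at printed precision the 10% and 7.5%
  # arms tie on QALYs, so the frontier keeps the cheaper 10% arm; the
  # ladder must stay monotone and anchored at no treatment
  tab <- data.frame(
    strategy = c("no_treatment", "threshold_15", "guideline_10",
                 "threshold_7.5"),
    cost = c(49360.91, 62236.63, 65128.64, 66866.81),
    qaly = c(12.17, 12.46, 12.47, 12.47)
  )
  lad <- icer_ladder(tab)
  expect_equal(lad$status[lad$strategy == "no_treatment"], "on_frontier")
  expect_equal(lad$status[lad$strategy == "guideline_10"], "on_frontier")
  expect_equal(lad$status[lad$strategy == "threshold_7.5"], "dominated")
  ic <- lad$icer[lad$status == "on_frontier"]
  ic <- ic[!is.na(ic)]
  expect_true(all(diff(ic) >= 0))
})

test_that("CEAC probabilities are NMB-consistent and sum to one", {
  # one strategy: probability 1 everywhere
  d1 <- data.frame(draw = 1:5, strategy = "A", cost = 1:5, qaly = 1)
  c1 <- ceac(d1, c(0, 50000))
  expect_equal(c1$probability, c(1, 1))

  # two degenerate strategies: step function at the breakeven ICER
  d2 <- rbind(data.frame(draw = 1:10, strategy = "A", cost = 0, qaly = 1),
              data.frame(draw = 1:10, strategy = "B", cost = 100,
                         qaly = 1.01))
  # breakeven at 100 / 0.01 = 10000
  cc <- ceac(d2, c(5000, 20000))
  expect_equal(cc$probability[cc$wtp == 5000 & cc$strategy == "A"], 1)
  expect_equal(cc$probability[cc$wtp == 5000 & cc$strategy == "B"], 0)
  expect_equal(cc$probability[cc$wtp == 20000 & cc$strategy == "B"], 1)

  # random draws: curves bounded in [0,1], summing to 1 at each WTP
  set.seed(88)
  d3 <- do.call(rbind, lapply(1:40, function(i)
    data.frame(draw = i, strategy = c("A", "B", "C"),
               cost = runif(3, 0, 100), qaly = runif(3, 0, 2))))
  c3 <- ceac(d3, seq(0, 200, by = 25))
  expect_true(all(c3$probability >= 0 & c3$probability <= 1))
  sums <- as.numeric(tapply(c3$probability, c3$wtp, sum))
  expect_equal(sums, rep(1, length(sums)))

  # exact ties split equally
  tie <- rbind(data.frame(draw = 1, strategy = "A", cost = 10, qaly = 1),
               data.frame(draw = 1, strategy = "B", cost = 10, qaly = 1))
  ct <- ceac(tie, 1000)
  expect_equal(ct$probability, c(0.5, 0.5))
})
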