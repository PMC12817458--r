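# Coverage metric and the scenario engine.

test_that("coverage flags match a naive double-loop check in both modes", {
  set.seed(21)
  alerts <- data.frame(id = 1:50, x = runif(50, 0, 2000),
                       y = runif(50, 0, 2000))
  aeds <- data.frame(id = 1:5, x = runif(5, 0, 2000), y = runif(5, 0, 2000),
                     always_available = TRUE)
  expect_equal(is_covered(alerts, aeds), naive_covered(alerts, aeds))

  coincident <- data.frame(x = aeds$x[1], y = aeds$y[1])
  expect_true(is_covered(coincident, aeds))
  near <- data.frame(x = aeds$x[1] + 299, y = aeds$y[1])
  expect_true(is_covered(near, aeds))
  far <- data.frame(x = aeds$x[1] + 301, y = aeds$y[1])
  covered_by_1 <- naive_covered(far, aeds)  # another AED may still be close
  expect_equal(is_covered(far, aeds), covered_by_1)

  # network mode on a line: third node is 400 m along the road
  net <- line_network(c(100, 300))
  aed <- data.frame(x = 0, y = 0, always_available = TRUE)
  expect_true(is_covered(data.frame(x = 100, y = 0), aed, net,
                         mode = "network_297"))
  expect_false(is_covered(data.frame(x = 400, y = 0), aed, net,
                          mode = "network_297"))
})

test_that("non-24/7 AEDs never participate in coverage", {
  alerts <- data.frame(x = 0, y = 0)
  aeds <- data.frame(x = c(0, 10), y = 0,
                     always_available = c(FALSE, FALSE))
  expect_false(is_covered(alerts, aeds))
})

test_that("coverage percentages reproduce the definitional arithmetic", {
  fake_aed <- data.frame(x = 0, y = 0, always_available = TRUE)
  # 1,098 of 5,076 alerts covered -> 21.6%; 2,962 -> 58.4%
  alerts <- data.frame(x = c(rep(0, 1098), rep(1e6, 5076 - 1098)), y = 0)
  cov <- coverage(alerts, fake_aed)
  expect_equal(cov$n_covered, 1098)
  expect_equal(cov$percent, 21.6)
  alerts <- data.frame(x = c(rep(0, 2962), rep(1e6, 5076 - 2962)), y = 0)
  expect_equal(coverage(alerts, fake_aed)$percent, 58.4)

  expect_equal(coverage(alerts, fake_aed[0, ])$percent, 0)
  expect_error(coverage(alerts[0, ], fake_aed), "empty")
})

test_that("coverage is monotone under AED-set inclusion", {
  set.seed(31)
  alerts <- data.frame(x = runif(200, 0, 3000), y = runif(200, 0, 3000))
  aeds <- data.frame(x = runif(10, 0, 3000), y = runif(10, 0, 3000),
                     always_available = TRUE)
  for (k in 1:9) {
    expect_lte(coverage(alerts, aeds[1:k, ])$percent,
               coverage(alerts, aeds[1:(k + 1), ])$percent)
  }
})

test_that("scenario specifications match the evaluation design", {
  s0 <- scenario_spec("0")
  expect_true(s0$consider_installed)
  expect_equal(s0$risk_source, "none")
  s1 <- scenario_spec("1"); s2 <- scenario_spec("2")
  expect_false(s1$consider_installed)
  expect_false(s2$consider_installed)
  expect_equal(s1$risk_source, "model")
  expect_equal(s2$risk_source, "historical")
  sB <- scenario_spec("B"); sC <- scenario_spec("C")
  expect_equal(sB$termination$min_risk, 5)
  expect_equal(sC$termination$min_risk, 3)
  expect_error(scenario_spec("X"), "unknown scenario")
})

test_that("scenario engine behaves on the synthetic city", {
  exp7 <- get_experiment(7)
  tab <- exp7$table
  expect_equal(nrow(tab), 6)
  expect_equal(tab$percent,
               round(100 * tab$n_covered / tab$n_alerts, 1))

  # adding devices to the installed base can only add coverage
  expect_gte(tab$percent[tab$scenario == "A"],
             tab$percent[tab$scenario == "0"])
  # risk threshold 3 is weaker than 5, so the greedy runs at least as long
  expect_gte(tab$n_aeds[tab$scenario == "C"],
             tab$n_aeds[tab$scenario == "B"])
  # scenarios 1/2 place exactly the installed count afresh
  expect_equal(tab$n_aeds[tab$scenario == "1"], nrow(exp7$existing))
  expect_equal(tab$n_aeds[tab$scenario == "2"], nrow(exp7$existing))
})

test_that("scenario 0 with no installed AEDs reports zero coverage", {
  alerts <- data.frame(x = c(0, 10), y = 0)
  none <- data.frame(id = integer(), x = numeric(), y = numeric(),
                     always_available = logical())
  res <- run_scenario("0", NULL, NULL, alerts, none)
  expect_equal(res$coverage$percent, 0)
  expect_null(res$placement)
})

test_that("model and historical sources coincide when the model is exact", {
  # when predicted risk equals the empirically binned risk, scenarios 1 and
  # 2 must produce identical placements and coverage
  exp7 <- get_experiment(7)
  feats <- exp7$features
  cand <- feats
  cand$risk <- bin_risk_area(cand$rate)
  cand$score <- cand$rate
  term <- termination("count", n = nrow(exp7$existing))
  direct <- greedy_place(cand, exp7$city$network, term)
  via_scenario <- run_scenario("2", exp7$city$network, feats, exp7$alerts,
                               exp7$existing)
  expect_identical(via_scenario$placement$selected$id, direct$selected$id)
})
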