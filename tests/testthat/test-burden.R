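test_that("monthly baseline is the four-factor product spread evenly over days", {
  # Pop 1e6, birth rate 0.01/yr, PTB rate 0.07, July share 0.09
  # -> July baseline 63 PTBs, 63/31 per day
  mp <- rep(0, 12); mp[7] <- 0.09; mp[12] <- 0.91
  demo <- demo_fixture(pop = 1e6, birth_rate = 0.01, ptb_rate = 0.07,
                       month_prop = mp, years = 2019L)
  base <- baseline_ptb(demo)
  expect_equal(base$monthly[1, 7, 1], 63)
  july <- format(base$dates, "%m") == "07"
  expect_equal(unique(base$daily[1, july]), 63 / 31, tolerance = 1e-12)
  # December is outside the warm season: no baseline accrues there
  expect_equal(sum(base$daily[1, format(base$dates, "%m") == "12"]), 0)
  # daily x days-in-month reconstitutes the monthly total
  expect_equal(sum(base$daily[1, july]), base$monthly[1, 7, 1],
               tolerance = 1e-9)
})

test_that("zero factors and uniform month shares behave as closed forms predict", {
  mp <- rep(1 / 12, 12)
  demo0 <- demo_fixture(pop = c(1e6, 0), birth_rate = 0.01, ptb_rate = 0.07,
                        month_prop = mp, years = 2019L)
  base0 <- baseline_ptb(demo0)
  expect_equal(sum(base0$daily[2, ]), 0)
  # uniform monthly shares: warm season (6 months) holds half the annual
  # expected PTBs
  expect_equal(sum(base0$monthly[1, , 1]), 1e6 * 0.01 * 0.07 / 2,
               tolerance = 1e-9)
  expect_error(baseline_ptb(demo0, years = 1999), "cover the requested")
})

test_that("attributable fraction is (RR-1)/RR when exposed and 0 otherwise", {
  expect_equal(attributable_fraction(risk_model(1.19), TRUE), 0.19 / 1.19)
  expect_equal(attributable_fraction(risk_model(1.19), TRUE), 0.159664,
               tolerance = 1e-6)
  expect_equal(attributable_fraction(risk_model(1.19), FALSE), 0)
  expect_equal(attributable_fraction(risk_model(1, c(1, 1)), TRUE), 0)
  expect_error(attributable_fraction(-2, TRUE), "positive")
  expect_error(risk_model(1.19, c(1.3, 1.4)), "low <= rr")
})

test_that("planted exposure recovers exposed-baseline x AF exactly", {
  mp <- rep(0, 12); mp[7] <- 1
  demo <- demo_fixture(pop = 1e6, birth_rate = 0.01, ptb_rate = 0.07,
                       month_prop = mp, years = 2019L)
  base <- baseline_ptb(demo)
  # plant exposure on 10 July days directly, bypassing detection
  exposed <- matrix(FALSE, 1, length(base$dates))
  july_days <- which(format(base$dates, "%m") == "07")[1:10]
  exposed[1, july_days] <- TRUE
  expo <- structure(list(exposed = exposed, dates = base$dates,
                         window_days = 7L), class = "exposure_field")
  risk <- risk_model(1.19)
  res <- attributable_ptb(base, expo, risk)
  daily_base <- 1e6 * 0.01 * 0.07 / 31
  want <- daily_base * 10 * (0.19 / 1.19)
  expect_equal(unname(res$annual["2019"]), want, tolerance = 1e-9)
  expect_equal(unname(res$exposed_base_annual["2019"]), daily_base * 10,
               tolerance = 1e-9)
  # spec-style round number: 2.0 baseline on each of 10 exposed days
  expect_equal(2.0 * 10 * (0.19 / 1.19), 3.19328, tolerance = 1e-5)
})

test_that("burden aggregates conserve mass, respect bounds and scale linearly", {
  cfg <- small_config(seed = 3L)
  g <- generate_temperature_grid(cfg, "observed")
  demo <- generate_demographics(cfg)
  base <- baseline_ptb(demo, cfg$years)
  mask <- detect_heatwaves(g, compute_threshold(g))
  expo <- exposure_window(mask)
  risk <- risk_model(1.19)
  res <- attributable_ptb(base, expo, risk)

  # conservation: national = sum over cell-days = sum over provinces
  yr <- as.integer(format(base$dates, "%Y"))
  for (y in c("2015", "2020")) {
    expect_equal(unname(res$annual[y]),
                 sum(res$aptb_daily[, yr == as.integer(y)]),
                 tolerance = 1e-9)
    expect_equal(unname(res$annual[y]), sum(res$annual_prov[, y]),
                 tolerance = 1e-9)
  }
  # bound: cell-day burden never exceeds its baseline; aggregate bounded
  # by baseline total x max AF
  expect_true(all(res$aptb_daily <= base$daily + 1e-12))
  expect_true(all(res$annual <= base$warm_base_annual * res$af + 1e-9))

  # doubling the baseline doubles every aggregate exactly
  demo2 <- demo
  demo2$population <- demo$population * 2
  base2 <- baseline_ptb(demo2, cfg$years)
  res2 <- attributable_ptb(base2, expo, risk)
  expect_equal(res2$annual, res$annual * 2, tolerance = 1e-12)
  expect_equal(res2$per_million, res$per_million, tolerance = 1e-12)

  # all-false exposure -> zero burden
  expo0 <- expo
  expo0$exposed[] <- FALSE
  expect_equal(sum(attributable_ptb(base, expo0, risk)$aptb_daily), 0)
})

test_that("scenario differencing is member-wise factual minus counterfactual", {
  cfg <- small_config(anthro_trend = 0)
  g <- generate_temperature_grid(cfg, "factual", 1)
  demo <- generate_demographics(cfg)
  base <- baseline_ptb(demo, cfg$years)
  expo <- exposure_window(detect_heatwaves(g, compute_threshold(g)))
  b <- attributable_ptb(base, expo, risk_model(1.19))

  # identical paired series -> zero anthropogenic burden
  cmp <- scenario_difference(list(b, b), list(b, b))
  expect_equal(unname(cmp$anthropogenic_mean),
               rep(0, length(cfg$years)))
  expect_equal(cmp$overall_proportion_pct, 0)

  # arithmetic contract: factual 100, counterfactual 74 -> anthro 26 (26%)
  f <- b; c2 <- b
  f$annual[] <- 100; c2$annual[] <- 74
  cmp2 <- scenario_difference(list(f), list(c2))
  expect_equal(unname(cmp2$anthropogenic_mean), rep(26, length(cfg$years)))
  expect_equal(unname(cmp2$proportion_pct), rep(26, length(cfg$years)))
  expect_equal(cmp2$overall_proportion_pct, 26)

  # zero factual burden -> proportion reported as missing
  z <- b; z$annual[] <- 0
  expect_true(all(is.na(scenario_difference(list(z),
                                            list(z))$proportion_pct)))
  expect_error(scenario_difference(list(b, b), list(b)), "pair")
})

test_that("burden results tabulate one row per year", {
  cfg <- small_config(years = 2019:2020)
  g <- generate_temperature_grid(cfg, "observed")
  demo <- generate_demographics(cfg)
  res <- attributable_ptb(
    baseline_ptb(demo),
    exposure_window(detect_heatwaves(g, compute_threshold(g))),
    risk_model())
  tab <- burden_table(res)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$aptb, unname(res$annual))
})
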