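test_that("generator is deterministic and scenario labels are validated", {
  cfg <- small_config()
  g1 <- generate_temperature_grid(cfg, "factual", 1)
  g2 <- generate_temperature_grid(cfg, "factual", 1)
  expect_identical(g1$tmax, g2$tmax)
  expect_error(generate_temperature_grid(cfg, "fictional"), "arg")
  expect_error(generate_temperature_grid(cfg, "factual", 99), "member")

  d2 <- generate_demographics(cfg)
  d3 <- generate_demographics(cfg)
  expect_identical(d2, d3)
})

test_that("zero anthropogenic trend makes paired scenario members identical", {
  cfg <- small_config(anthro_trend = 0)
  f <- generate_temperature_grid(cfg, "factual", 2)
  cf <- generate_temperature_grid(cfg, "counterfactual", 2)
  expect_identical(f$tmax, cf$tmax)
})

test_that("noiseless zero-trend series is the pure annual sinusoid", {
  cfg <- small_config(noise_sd = 0, anthro_trend = 0, years = 2017:2019)
  g <- generate_temperature_grid(cfg, "factual", 1)
  # identical across cells
  expect_equal(g$tmax[1, ], g$tmax[4, ])
  # repeats year over year on matching calendar days (compare two
  # non-leap years day by day)
  y <- as.integer(format(g$dates, "%Y"))
  expect_equal(g$tmax[1, y == 2017], g$tmax[1, y == 2018],
               tolerance = 1e-12)
  # peaks near the configured peak day-of-year
  doy <- as.integer(format(g$dates[which.max(g$tmax[1, y == 2017])], "%j"))
  expect_lt(abs(doy - cfg$peak_doy), 2)
  expect_equal(max(g$tmax), cfg$temp_mean + cfg$temp_amplitude,
               tolerance = 1e-3)
})

test_that("factual minus counterfactual recovers the injected linear trend", {
  # 0.5 degC/decade over 40 years: the last decade sits 3.0-4.0 decades
  # after the series start, so the scenario difference averaged over that
  # decade is 3.5 x 0.5 = 1.75 degC, member noise cancelling exactly
  # because paired members share their natural variability.
  cfg <- small_config(n_cells = 1L, n_provinces = 1L, years = 1981:2020,
                      anthro_trend = 0.5, n_members = 100L)
  last_decade <- seq(as.Date("2011-01-01"), as.Date("2020-12-31"), "day")
  diffs <- vapply(1:100, function(m) {
    f <- generate_temperature_grid(cfg, "factual", m)
    cf <- generate_temperature_grid(cfg, "counterfactual", m)
    idx <- f$dates %in% last_decade
    mean(f$tmax[1, idx] - cf$tmax[1, idx])
  }, numeric(1))
  expect_equal(mean(diffs), 1.75, tolerance = 0.01)
  expect_lt(stats::sd(diffs), 1e-12)  # trend is deterministic per member
})

test_that("counterfactual ensemble mean has no warm-season trend while the factual difference grows linearly", {
  cfg <- small_config(n_cells = 2L, n_provinces = 1L, years = 1991:2020,
                      anthro_trend = 0.4, n_members = 100L)
  years <- cfg$years
  cf_mean <- matrix(0, length(years), 1)
  gap <- matrix(0, cfg$n_members, length(years))
  for (m in seq_len(cfg$n_members)) {
    f <- generate_temperature_grid(cfg, "factual", m)
    cf <- generate_temperature_grid(cfg, "counterfactual", m)
    warm <- as.integer(format(f$dates, "%m")) %in% 5:10
    yr <- as.integer(format(f$dates, "%Y"))
    cfw <- vapply(years, function(y) mean(cf$tmax[, warm & yr == y]),
                  numeric(1))
    fw <- vapply(years, function(y) mean(f$tmax[, warm & yr == y]),
                 numeric(1))
    cf_mean <- cf_mean + cfw / cfg$n_members
    gap[m, ] <- fw - cfw
  }
  fit_cf <- stats::lm(cf_mean ~ years)
  ci <- stats::confint(fit_cf)["years", ]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
  # ensemble-mean gap slope ~ anthro_trend per decade
  fit_gap <- stats::lm(colMeans(gap) ~ years)
  expect_equal(unname(stats::coef(fit_gap)["years"]) * 10, 0.4,
               tolerance = 0.01)
})

test_that("synthetic PTB rates grow geometrically and proportions normalize", {
  cfg <- small_config(years = 2012:2020)
  demo <- generate_demographics(cfg, base_ptb_rate = 0.07,
                                ptb_growth = 1.013)
  # closed form: ratio over 8 years apart is 1.013^8
  expect_equal(demo$ptb_rate[, 9] / demo$ptb_rate[, 1],
               rep(1.013^8, cfg$n_provinces), tolerance = 1e-12)
  expect_equal(unname(rowSums(demo$birth_month_prop)),
               rep(1, cfg$n_provinces), tolerance = 1e-12)

  flat <- generate_demographics(cfg, ptb_growth = 1)
  expect_true(all(flat$ptb_rate == flat$ptb_rate[, 1]))

  expect_error(generate_demographics(cfg, base_ptb_rate = 0.9,
                                     ptb_growth = 1.2), "rates to 1")
  expect_error(generate_demographics(cfg, base_ptb_rate = 1.2), "0, 1")
})

test_that("demographic tables round-trip through CSV files", {
  demo <- generate_demographics(small_config())
  dir <- withr::local_tempdir()
  write_demographic_tables(demo, dir)
  pop <- read.csv(file.path(dir, "population.csv"))
  expect_equal(nrow(pop), nrow(demo$population) * length(demo$years))
  expect_equal(pop$population[pop$cell == 2 & pop$year == 2016],
               demo$population[2, match(2016, demo$years)])
  bmp <- read.csv(file.path(dir, "birth_month_prop.csv"))
  expect_equal(sum(bmp$proportion[bmp$province == 1]), 1, tolerance = 1e-9)
})

test_that("temperature grids round-trip through CSV", {
  g <- generate_temperature_grid(small_config(years = 2019:2019), "factual", 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_temperature_grid(g, path)
  g2 <- read_temperature_grid(path)
  expect_equal(g2$tmax, g$tmax, tolerance = 1e-9)
  expect_identical(g2$dates, g$dates)
  expect_identical(g2$scenario, "factual")
})
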