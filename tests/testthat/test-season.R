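test_that("a season is deterministic and physically sensible", {
  ws <- generate_weather(rr_site(), 3, seed = 41)
  cfg <- rr_config("rainfed")
  a <- simulate_season(cultivar_claire(), ws, 1, cfg)
  b <- simulate_season(cultivar_claire(), ws, 1, cfg)
  expect_identical(a, b)
  expect_gte(a$yield, 0)
  expect_true(a$hi >= 0 && a$hi <= 1)
  expect_true(a$anthesis_das < a$maturity_das)
  # sink cap: yield never exceeds grain number x maximum grain weight
  expect_lte(a$yield, a$grain_number * 0.045 * 0.01 + 1e-9)
  expect_lte(a$yield, a$biomass)
})

test_that("no radiation means no biomass and no yield", {
  ws <- const_weather(3, 10, 20, rad = 0)
  s <- simulate_season(cultivar_claire(), ws, 1, rr_config("rainfed"))
  expect_equal(s$biomass, 0)
  expect_equal(s$yield, 0)
})

test_that("cold weather that never reaches anthesis yields a flagged result", {
  ws <- const_weather(3, -2, 2)  # mean 0 degC: no development
  s <- simulate_season(cultivar_claire(), ws, 1, rr_config("rainfed"))
  expect_true(s$failed)
  expect_equal(s$yield, 0)
})

test_that("reference cultivar yields fall in the plausible band", {
  ws <- generate_weather(rr_site(), 9, seed = 42)
  e <- simulate_ensemble(cultivar_claire(), ws, rr_config("rainfed"))
  expect_gt(e$mean_yield, 8)
  expect_lt(e$mean_yield, 14)
  expect_gt(e$mean_hi, 0.40)
  expect_lt(e$mean_hi, 0.55)
  expect_gt(e$mean_lai_anthesis, 5)
  expect_lt(e$mean_lai_anthesis, 10)
})

test_that("ensemble statistics match textbook oracles", {
  ws <- generate_weather(rr_site(), 7, seed = 43)
  e <- simulate_ensemble(cultivar_claire(), ws, rr_config("rainfed"))
  y <- e$seasons$yield
  expect_equal(e$mean_yield, mean(y))
  expect_equal(e$sd_yield, sqrt(sum((y - mean(y))^2) / (length(y) - 1)))
  expect_equal(e$cv_yield, 100 * e$sd_yield / e$mean_yield)
  # percentile definition: linear interpolation between order statistics
  expect_equal(unname(e$yield_percentiles),
               unname(quantile(y, c(.05, .25, .5, .75, .95), type = 7)))
  # degenerate ensemble: identical weather every season
  cwe <- const_weather(4, 10, 20, rain = 2, rad = 12)
  ed <- simulate_ensemble(cultivar_claire(), cwe, rr_config("irrigated"))
  expect_equal(ed$cv_yield, 0, tolerance = 1e-10)
  expect_true(all(abs(ed$yield_percentiles - ed$mean_yield) < 1e-9))
  expect_error(simulate_ensemble(cultivar_claire(),
                                 generate_weather(rr_site(), 2, seed = 1),
                                 rr_config()), "sowing years")
})

test_that("irrigated yields are never below rainfed on the same weather", {
  ws <- generate_weather(rr_site(), 6, seed = 44)
  er <- simulate_ensemble(cultivar_claire(), ws, rr_config("rainfed"))
  ei <- simulate_ensemble(cultivar_claire(), ws, rr_config("irrigated"))
  expect_true(all(ei$seasons$yield - er$seasons$yield >= -1e-9))
})

test_that("CO2 enrichment raises yield at fixed weather", {
  ws <- generate_weather(rr_site(), 5, seed = 45)
  e364 <- simulate_ensemble(cultivar_claire(), ws, rr_config("rainfed", co2 = 364))
  e541 <- simulate_ensemble(cultivar_claire(), ws, rr_config("rainfed", co2 = 541))
  expect_true(all(e541$seasons$yield >= e364$seasons$yield - 1e-9))
  expect_gt(e541$mean_yield, e364$mean_yield)
})

test_that("longer grain filling never lowers unstressed yield", {
  ws <- generate_weather(rr_site(), 5, seed = 46)
  cfg <- rr_config("irrigated")
  e650 <- simulate_ensemble(cultivar_claire(), ws, cfg)
  e800 <- simulate_ensemble(cultivar_claire(TT_BGFEGF = 800), ws, cfg)
  expect_true(all(e800$seasons$yield >= e650$seasons$yield - 1e-9))
})

test_that("the 2050 scenario accelerates phenology and shrinks the season", {
  base <- rr_site()
  w0 <- generate_weather(base, 6, seed = 47)
  w5 <- generate_weather(apply_scenario(base, scenario_2050("UK")), 6,
                         seed = 47)
  cfg <- rr_config("rainfed")
  e0 <- simulate_ensemble(cultivar_claire(), w0, cfg)
  e5 <- simulate_ensemble(cultivar_claire(), w5, cfg)
  expect_lt(e5$mean_anthesis_das, e0$mean_anthesis_das)
  expect_lt(e5$mean_maturity_das, e0$mean_maturity_das)
  expect_lt(e5$mean_maturity_das - e5$mean_anthesis_das,
            e0$mean_maturity_das - e0$mean_anthesis_das + 1e-9)
})
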