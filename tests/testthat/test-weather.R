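test_that("generated series is deterministic, physical and gap-free", {
  rr <- rr_site()
  a <- generate_weather(rr, 3, seed = 5)
  b <- generate_weather(rr, 3, seed = 5)
  expect_identical(a, b)
  c <- generate_weather(rr, 3, seed = 6)
  expect_false(identical(a$rain_mm, c$rain_mm))
  expect_equal(nrow(a), 3 * 365)
  expect_true(all(a$tmax_c >= a$tmin_c))
  expect_true(all(a$rain_mm >= 0))
  expect_true(all(a$rad_mj >= 0))
  expect_identical(a$doy, rep.int(1:365, 3))
})

test_that("long-run statistics recover the annual site normals", {
  ws <- generate_weather(site_from_annual("X", 51.8, 9.8, 700, 9.8), 100,
                         seed = 12)
  s <- summarize_weather(ws)
  expect_lt(abs(s$mean_temp - 9.8), 0.3)
  expect_lt(abs(s$annual_precip - 700) / 700, 0.05)
  expect_lt(abs(s$mean_rad - 9.8) / 9.8, 0.05)
})

test_that("zero wet-day probabilities give exactly zero precipitation", {
  site <- site_climate("DRY", 45, flat_normals(0, 0, 2, 3))
  ws <- generate_weather(site, 5, seed = 1)
  expect_identical(sum(ws$rain_mm), 0)
})

test_that("wet-day amounts match a Monte-Carlo gamma oracle", {
  site <- site_climate("WET", 45, flat_normals(1, 1, 2, 3))
  ws <- generate_weather(site, 100, seed = 2)
  expect_true(all(ws$rain_mm > 0))  # chain forced wet
  set.seed(99)
  oracle <- mean(rgamma(1e6, shape = 2, scale = 3))
  expect_lt(abs(mean(ws$rain_mm) - oracle), 0.06)
})

test_that("scenario morphing shifts the generated series as prescribed", {
  rr <- rr_site()
  base <- summarize_weather(generate_weather(rr, 30, seed = 3))
  uk <- apply_scenario(rr, scenario_2050("UK"))
  s2 <- summarize_weather(generate_weather(uk, 30, seed = 3))
  expect_lt(abs((s2$mean_temp - base$mean_temp) - 2.1), 0.2)
  expect_lt(abs(s2$mean_rad / base$mean_rad - 1.067), 0.01)
  expect_equal(uk$co2, 541)

  ident <- climate_scenario(0, 1, 1, co2 = rr$co2)
  expect_equal(apply_scenario(rr, ident)$monthly, rr$monthly)

  dry <- apply_scenario(rr, climate_scenario(0, precip_mult = 0, co2 = 364))
  expect_identical(sum(generate_weather(dry, 3, seed = 4)$rain_mm), 0)
})

test_that("temperature offsets compose linearly", {
  rr <- rr_site()
  once <- apply_scenario(rr, climate_scenario(dtemp = 3, co2 = 364))
  twice <- apply_scenario(apply_scenario(rr, climate_scenario(dtemp = 1.5, co2 = 364)),
                          climate_scenario(dtemp = 1.5, co2 = 364))
  expect_equal(once$monthly$tmin_mean, twice$monthly$tmin_mean)
  expect_equal(once$monthly$tmax_mean, twice$monthly$tmax_mean)
})

test_that("series summaries behave like means", {
  cw <- const_weather(2, 10, 10, rain = 2, rad = 12)
  s <- summarize_weather(cw)
  expect_equal(s$mean_temp, 10)
  expect_equal(s$annual_precip, 730)
  expect_equal(s$mean_rad, 12)

  a <- generate_weather(rr_site(), 2, seed = 7)
  b <- generate_weather(rr_site(), 3, seed = 8)
  pool <- rbind(as.data.frame(a), as.data.frame(b))
  class(pool) <- c("weather_series", "data.frame")
  sp <- summarize_weather(pool)
  # brute-force pooled mean
  expect_equal(sp$mean_temp,
               mean(c((a$tmin_c + a$tmax_c) / 2, (b$tmin_c + b$tmax_c) / 2)))
  expect_equal(sp$mean_rad, mean(c(a$rad_mj, b$rad_mj)))
  expect_error(summarize_weather(a[0, ]), "empty")
})

test_that("weather CSV round-trips and is validated", {
  ws <- generate_weather(rr_site(), 2, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_weather_csv(ws, f)
  back <- read_weather_csv(f)
  expect_equal(back$rain_mm, ws$rain_mm, tolerance = 1e-12)
  bad <- as.data.frame(ws); bad$tmax_c[1] <- bad$tmin_c[1] - 5
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  expect_error(read_weather_csv(f2), "tmax")
})

test_that("site and scenario configs round-trip through YAML", {
  rr <- rr_site()
  f <- tempfile(fileext = ".yaml")
  write_site_config(rr, f)
  back <- read_site_config(f)
  expect_equal(back$latitude, rr$latitude)
  expect_equal(back$monthly$gamma_scale, rr$monthly$gamma_scale)
  f2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(site = "X", latitude = 51.8,
                        annual = list(t_ann = 9.8, p_ann = 700, r_ann = 9.8),
                        co2 = 364), f2)
  s2 <- read_site_config(f2)
  expect_s3_class(s2, "site_climate")
  f3 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(dtemp = 2.1, precip_mult = 0.98, rad_mult = 1.067,
                        co2 = 541, lue = 1.1), f3)
  sc <- read_scenario_config(f3)
  expect_equal(sc$co2, 541)
  expect_equal(sc$dtemp, rep(2.1, 12))
})

test_that("malformed normals are rejected with the field named", {
  m <- flat_normals(0.5, 0.3, 2, 3)
  m2 <- m; m2$p_ww[3] <- 1.4
  expect_error(site_climate("S", 45, m2), "p_ww")
  m3 <- m; m3$gamma_shape[1] <- 0
  expect_error(site_climate("S", 45, m3), "gamma_shape")
  m4 <- m; m4$tmax_mean[2] <- m4$tmin_mean[2] - 1
  expect_error(site_climate("S", 45, m4), "tmax")
  expect_error(generate_weather(site_climate("S", 45, m), 0, 1), "positive")
})
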