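test_that("daily thermal time clips at the base temperature", {
  expect_equal(daily_thermal_time(0, 0, 0), 0)
  expect_equal(daily_thermal_time(-5, 3, 0), 0)
  expect_equal(daily_thermal_time(10, 20, 0), 15)
  expect_equal(daily_thermal_time(10, 20, 5), 10)
  expect_error(daily_thermal_time(5, 2), "tmax")
})

test_that("emergence follows the cumulative thermal-time ceiling oracle", {
  cw <- const_weather(2, 20, 20)
  ph <- compute_phenology(cw$tmin_c, cw$tmax_c, cw$doy, cultivar_claire(),
                          51.8)
  expect_equal(ph$d_em, ceiling(150 / 20))  # day 8
})

test_that("day length matches an independent astronomical oracle", {
  # equatorial symmetry
  expect_true(all(abs(day_length(0, c(1, 80, 172, 265, 355)) - 12) < 0.2))
  # CBM model (Forsythe et al. 1995, geometric sunrise) as independent
  # formula
  cbm <- function(lat, doy) {
    theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
    phi <- asin(0.39795 * cos(theta))
    24 - 24 / pi * acos(sin(lat * pi / 180) * sin(phi) /
                          (cos(lat * pi / 180) * cos(phi)))
  }
  for (d in c(1, 100, 172, 250, 355))
    expect_lt(abs(day_length(51.8, d) - cbm(51.8, d)), 0.25)
  # hemispheric antisymmetry: opposite latitudes sum to 24 h on the same
  # day, and a half-year shift swaps hemispheres
  for (d in c(20, 150, 300)) {
    expect_lt(abs(day_length(51.8, d) + day_length(-51.8, d) - 24), 1e-9)
    expect_lt(abs(day_length(51.8, d) -
                    day_length(-51.8, (d + 182) %% 365 + 1)), 0.3)
  }
  expect_error(day_length(70, 100), "polar")
})

test_that("vernalization accumulates linearly in temperature and saturates", {
  expect_equal(vernalization_rate(0, 0.0012, 0.012), 0.012)
  expect_equal(vernalization_rate(10, 0.0012, 0.012), 0.024)
  expect_equal(vernalization_rate(-20, 0.0012, 0.012), 0)  # clipped
  # saturation after ceil(1/0.012) = 84 days at constant 0 degC
  inc <- vernalization_rate(0, 0.0012, 0.012)
  expect_equal(which(cumsum(rep(inc, 120)) >= 1)[1], ceiling(1 / 0.012))
  # null rates never vernalize -> FLN defaults to L_Max
  cw <- const_weather(2, 20, 20)
  cv0 <- cultivar_claire(VAI = 1e-12, VBEE = 1e-12)
  ph <- compute_phenology(cw$tmin_c, cw$tmax_c, cw$doy, cv0, 51.8)
  expect_true(is.na(ph$d_vsat))
  expect_equal(ph$fln, cv0$L_Max)
})

test_that("final leaf number responds to day length with slope P_p", {
  cl <- cultivar_claire()
  expect_equal(final_leaf_number(cultivar_claire(P_p = 1e-9), 10), cl$L_Min,
               tolerance = 1e-6)
  # Claire: one extra leaf per 2 h shorter day at P_p = 0.5
  d14 <- final_leaf_number(cl, 14)
  d16 <- final_leaf_number(cl, 16)
  expect_equal(d14 - d16, 1.0)
  expect_equal(d14, 8 + 0.5 * (20 - 14))
  # bounds hold for any day length
  for (dl in seq(0, 24, by = 2)) {
    f <- final_leaf_number(cl, dl)
    expect_gte(f, cl$L_Min); expect_lte(f, cl$L_Max)
  }
})

test_that("grain-fill duration matches the thermal-time division oracle", {
  cw <- const_weather(3, 17.1, 17.1)
  ph <- compute_phenology(cw$tmin_c, cw$tmax_c, cw$doy, cultivar_claire(),
                          51.8)
  # brute-force oracle: count days to accumulate G_f = 650 degC day
  # between the two window boundaries at 17.1 degC day per day
  cum <- cumsum(rep(17.1, 3 * 365))
  oracle <- which(cum >= ph$tt_egf)[1] - which(cum >= ph$tt_bgf)[1]
  expect_equal(ph$d_egf - ph$d_bgf, oracle)
  expect_lte(abs(oracle - 650 / 17.1), 1)  # the 38-day fill
})

test_that("stage dates are ordered and respond correctly to parameters", {
  cw <- const_weather(3, 8, 16)
  cl <- cultivar_claire()
  ph <- compute_phenology(cw$tmin_c, cw$tmax_c, cw$doy, cl, 51.8)
  expect_true(ph$d_em < ph$d_anth && ph$d_anth < ph$d_bgf &&
                ph$d_bgf < ph$d_egf && ph$d_egf < ph$d_mat)
  # zero development
  expect_equal(daily_thermal_time(-3, 0), 0)
  # doubling the phyllochron strictly delays anthesis (thermal time)
  ph2 <- compute_phenology(cw$tmin_c, cw$tmax_c, cw$doy,
                           cultivar_claire(P_h = 220), 51.8)
  expect_gt(ph2$tt_anth, ph$tt_anth)
})

test_that("uniform warming never delays any stage", {
  ws <- generate_weather(rr_site(), 3, seed = 21)
  cl <- cultivar_claire()
  i0 <- which(ws$year == 1 & ws$doy == 293)
  idx <- i0:(i0 + 399)
  ph0 <- compute_phenology(ws$tmin_c[idx], ws$tmax_c[idx], ws$doy[idx],
                           cl, 51.8)
  ph2 <- compute_phenology(ws$tmin_c[idx] + 2, ws$tmax_c[idx] + 2,
                           ws$doy[idx], cl, 51.8)
  for (f in c("d_em", "d_anth", "d_bgf", "d_egf", "d_mat"))
    expect_lte(ph2[[f]], ph0[[f]])
})
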