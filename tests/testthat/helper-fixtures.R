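# Synthetic fixtures built in code.

# Constant-weather series: every day identical. Useful for closed-form
# phenology and carbon oracles.
const_weather <- function(n_years, tmin, tmax, rain = 0, rad = 10,
                          latitude = 51.8, co2 = 364) {
  n <- n_years * 365L
  ws <- data.frame(year = rep(seq_len(n_years), each = 365L),
                   doy = rep.int(1:365, n_years),
                   tmin_c = rep(tmin, n), tmax_c = rep(tmax, n),
                   rain_mm = rep(rain, n), rad_mj = rep(rad, n))
  attr(ws, "site") <- "CONST"
  attr(ws, "latitude") <- latitude
  attr(ws, "co2") <- co2
  attr(ws, "seed") <- 0L
  class(ws) <- c("weather_series", "data.frame")
  ws
}

# Rothamsted-like site and short weather records shared across tests.
rr_site <- function(co2 = 364) builtin_site("RR", co2 = co2)

rr_config <- function(water_mode = "rainfed", ...) {
  sim_config(sowing_doy = 293, latitude = 51.80, soil = "rothamsted_210",
             water_mode = water_mode, ...)
}

# Uniform monthly normals helper for generator distribution checks.
flat_normals <- function(p_ww, p_wd, shape, scale, tmin = 5, tmax = 12,
                         rad = 10) {
  monthly_normals(month = 1:12, tmin_mean = rep(tmin, 12),
                  tmax_mean = rep(tmax, 12), t_sd = rep(2, 12),
                  p_ww = rep(p_ww, 12), p_wd = rep(p_wd, 12),
                  gamma_shape = rep(shape, 12), gamma_scale = rep(scale, 12),
                  rad_dry = rep(rad, 12), rad_wet = rep(0.6 * rad, 12),
                  rad_sd = rep(1.5, 12))
}
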