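#' @importFrom stats rnorm rgamma runif quantile sd setNames
#' @importFrom utils read.csv write.csv
NULL

MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_OF_DOY <- rep.int(1:12, MONTH_DAYS)

#' Monthly climate normals
#'
#' One row per calendar month with the parameters consumed by the daily
#' weather generator: mean daily minimum/maximum temperature and their
#' between-day SD, the two wet-day transition probabilities of a first-order
#' Markov chain (wet after wet, wet after dry), the gamma shape/scale of
#' wet-day precipitation (mm), and the mean global radiation on dry and wet
#' days (MJ m-2 day-1) with its SD.
#'
#' @param month integer 1..12.
#' @param tmin_mean,tmax_mean mean daily Tmin/Tmax (degC).
#' @param t_sd between-day temperature SD (degC).
#' @param p_ww,p_wd P(wet | previous day wet) and P(wet | previous day dry).
#' @param gamma_shape,gamma_scale gamma parameters of wet-day amounts (mm).
#' @param rad_dry,rad_wet mean global radiation on dry / wet days
#'   (MJ m-2 day-1).
#' @param rad_sd between-day radiation SD (MJ m-2 day-1).
#' @return data.frame of class `monthly_normals` (12 rows).
#' @export
monthly_normals <- function(month, tmin_mean, tmax_mean, t_sd,
                            p_ww, p_wd, gamma_shape, gamma_scale,
                            rad_dry, rad_wet, rad_sd) {
  m <- data.frame(month = as.integer(month), tmin_mean = tmin_mean,
                  tmax_mean = tmax_mean, t_sd = t_sd, p_ww = p_ww,
                  p_wd = p_wd, gamma_shape = gamma_shape,
                  gamma_scale = gamma_scale, rad_dry = rad_dry,
                  rad_wet = rad_wet, rad_sd = rad_sd)
  validate_normals(m)
}

validate_normals <- function(m) {
  req <- c("month", "tmin_mean", "tmax_mean", "t_sd", "p_ww", "p_wd",
           "gamma_shape", "gamma_scale", "rad_dry", "rad_wet", "rad_sd")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("monthly normals missing field(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(m) != 12L || !identical(sort(m$month), 1:12))
    stop("monthly normals must have one row per month 1..12")
  chk <- function(ok, field)
    if (!all(ok)) stop("invalid monthly normals field: ", field)
  chk(m$p_ww >= 0 & m$p_ww <= 1, "p_ww")
  chk(m$p_wd >= 0 & m$p_wd <= 1, "p_wd")
  chk(m$t_sd >= 0, "t_sd")
  chk(m$rad_sd >= 0, "rad_sd")
  chk(m$gamma_shape > 0, "gamma_shape")
  chk(m$gamma_scale > 0, "gamma_scale")
  chk(m$tmax_mean >= m$tmin_mean, "tmax_mean >= tmin_mean")
  chk(m$rad_dry >= 0 & m$rad_wet >= 0, "radiation means")
  m <- m[order(m$month), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("monthly_normals", "data.frame")
  m
}

#' Site climate parameterization
#'
#' @param site character site id.
#' @param latitude signed decimal degrees (positive north).
#' @param monthly a `monthly_normals` table.
#' @param co2 atmospheric CO2 (ppm).
#' @return list of class `site_climate`.
#' @export
site_climate <- function(site, latitude, monthly, co2 = 364) {
  if (!is.numeric(latitude) || abs(latitude) > 90)
    stop("latitude must be in [-90, 90]")
  if (!is.numeric(co2) || co2 <= 0) stop("co2 must be > 0")
  structure(list(site = as.character(site), latitude = latitude,
                 monthly = validate_normals(monthly), co2 = co2),
            class = "site_climate")
}

# Table of the six study sites: annual mean temperature (degC), annual
# precipitation (mm) and mean daily global radiation (MJ m-2 day-1).
STUDY_SITES <- data.frame(
  site = c("ED", "LE", "RR", "GO", "LI", "PU"),
  country = c("UK", "UK", "UK", "NZ", "NZ", "NZ"),
  latitude = c(55.94, 54.30, 51.80, -46.12, -43.70, -37.21),
  t_ann = c(8.6, 9.5, 9.8, 9.8, 11.6, 14.5),
  p_ann = c(717, 626, 700, 976, 596, 1296),
  r_ann = c(8.7, 8.6, 9.8, 12.4, 13.6, 14.0),
  stringsAsFactors = FALSE
)

#' Built-in study sites
#'
#' Six sites across the UK (ED, LE, RR) and NZ (GO, LI, PU). Monthly shapes
#' are sinusoidal (hemisphere-aware phase) fitted so that the long-run
#' annual mean temperature, annual precipitation and mean daily radiation
#' equal the site's annual normals exactly in expectation.
#'
#' @param id one of "ED", "LE", "RR", "GO", "LI", "PU".
#' @param co2 atmospheric CO2 (ppm), default 364 (baseline).
#' @return A `site_climate` object.
#' @export
#' @examples
#' rr <- builtin_site("RR")
builtin_site <- function(id, co2 = 364) {
  i <- match(id, STUDY_SITES$site)
  if (is.na(i)) stop("unknown site id: ", id, " (use ",
                     paste(STUDY_SITES$site, collapse = "/"), ")")
  s <- STUDY_SITES[i, ]
  site_from_annual(s$site, s$latitude, s$t_ann, s$p_ann, s$r_ann, co2 = co2)
}

#' Build a site parameterization from annual climate summaries
#'
#' Fits sinusoidal monthly shapes (warm-season peak in July for northern,
#' January for southern latitudes) whose day-weighted annual aggregates
#' reproduce the supplied annual values exactly in expectation.
#'
#' @param site site id.
#' @param latitude signed degrees.
#' @param t_ann annual mean air temperature (degC).
#' @param p_ann annual precipitation (mm).
#' @param r_ann mean daily global radiation (MJ m-2 day-1).
#' @param co2 atmospheric CO2 (ppm).
#' @param t_amp,diurnal_range,t_sd seasonal temperature amplitude, mean
#'   diurnal range and between-day SD (degC). `t_amp = NULL` uses a
#'   latitude-based default.
#' @param p_ww,p_wd Markov wet-day transition probabilities.
#' @param gamma_shape gamma shape of wet-day amounts.
#' @return A `site_climate` object.
#' @export
site_from_annual <- function(site, latitude, t_ann, p_ann, r_ann, co2 = 364,
                             t_amp = NULL, diurnal_range = 7, t_sd = 2.5,
                             p_ww = 0.65, p_wd = 0.35, gamma_shape = 0.75) {
  peak <- if (latitude >= 0) 7 else 1
  cosv <- cos(2 * pi * (1:12 - peak) / 12)
  w <- MONTH_DAYS / 365
  if (is.null(t_amp)) t_amp <- 2.0 + 0.072 * abs(latitude)

  tmean <- t_ann + t_amp * cosv
  tmean <- tmean + (t_ann - sum(w * tmean))  # exact annual mean

  pi_wet <- p_wd / (1 - p_ww + p_wd)  # stationary wet-day frequency
  scale0 <- 1 + 0.15 * (-cosv)        # winter-skewed amounts
  implied <- sum(MONTH_DAYS * pi_wet * gamma_shape * scale0)
  gscale <- scale0 * (p_ann / implied)

  r_frac <- min(0.85, 0.25 + 0.009 * abs(latitude))
  radm <- r_ann * (1 + r_frac * cosv)
  radm <- radm * (r_ann / sum(w * radm))
  f_wet <- 0.6
  rad_dry <- radm / (1 - (1 - f_wet) * pi_wet)
  rad_wet <- f_wet * rad_dry

  m <- monthly_normals(
    month = 1:12,
    tmin_mean = tmean - diurnal_range / 2,
    tmax_mean = tmean + diurnal_range / 2,
    t_sd = rep(t_sd, 12),
    p_ww = rep(p_ww, 12), p_wd = rep(p_wd, 12),
    gamma_shape = rep(gamma_shape, 12), gamma_scale = gscale,
    rad_dry = rad_dry, rad_wet = rad_wet, rad_sd = 0.18 * radm
  )
  site_climate(site, latitude, m, co2 = co2)
}

#' Climate-change scenario
#'
#' Morphing deltas applied to a site parameterization: an additive monthly
#' temperature offset, multiplicative precipitation and radiation factors,
#' a replacement CO2 concentration, and a light-use-efficiency multiplier
#' carried along for the crop model.
#'
#' @param dtemp temperature offset (degC), scalar or length-12.
#' @param precip_mult,rad_mult multiplicative factors (>= 0), scalar or
#'   length-12.
#' @param co2 target CO2 (ppm).
#' @param lue light-use-efficiency multiplier (default 1).
#' @return list of class `climate_scenario`.
#' @export
climate_scenario <- function(dtemp = 0, precip_mult = 1, rad_mult = 1,
                             co2 = 364, lue = 1) {
  r12 <- function(x, nm) {
    if (!length(x) %in% c(1L, 12L)) stop(nm, " must have length 1 or 12")
    rep(x, length.out = 12)
  }
  pm <- r12(precip_mult, "precip_mult"); rm <- r12(rad_mult, "rad_mult")
  if (any(pm < 0) || any(rm < 0)) stop("multipliers must be >= 0")
  if (co2 <= 0) stop("co2 must be > 0")
  if (lue <= 0) stop("lue must be > 0")
  structure(list(dtemp = r12(dtemp, "dtemp"), precip_mult = pm,
                 rad_mult = rm, co2 = co2, lue = lue),
            class = "climate_scenario")
}

#' Built-in 2050 scenario (country-level deltas)
#'
#' Mid-century high-emission deltas: annual-mean warming of +2.1 degC (UK)
#' or +1.9 degC (NZ) distributed with a warm-season-weighted sinusoidal
#' shape (GCM warming over both countries is stronger in summer than in
#' winter; the day-weighted annual mean equals the printed country value
#' exactly), radiation x1.067 (UK) / x1.011 (NZ), precipitation x0.98 and
#' CO2 541 ppm in both countries.
#'
#' @param country "UK" or "NZ".
#' @param lue light-use-efficiency multiplier; the ideotype-design runs use
#'   1.10, cultivar impact runs 1.0.
#' @return A `climate_scenario`.
#' @export
scenario_2050 <- function(country = c("UK", "NZ"), lue = 1) {
  country <- match.arg(country)
  seasonal_dt <- function(mean_dt, amp, peak) {
    v <- mean_dt + amp * cos(2 * pi * (1:12 - peak) / 12)
    v + (mean_dt - sum(MONTH_DAYS * v) / 365)
  }
  if (country == "UK")
    climate_scenario(dtemp = seasonal_dt(2.1, 0.8, 7),
                     precip_mult = 0.98, rad_mult = 1.067,
                     co2 = 541, lue = lue)
  else
    climate_scenario(dtemp = seasonal_dt(1.9, 0.6, 1),
                     precip_mult = 0.98, rad_mult = 1.011,
                     co2 = 541, lue = lue)
}

#' Apply a climate scenario to a site parameterization
#'
#' Returns a new `site_climate`: monthly Tmin/Tmax means shifted by the
#' offset, precipitation gamma scale and the dry/wet radiation means
#' multiplied, CO2 replaced. The input is not modified.
#'
#' @param params a `site_climate`.
#' @param scenario a `climate_scenario`.
#' @return A new `site_climate`.
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(inherits(params, "site_climate"),
            inherits(scenario, "climate_scenario"))
  m <- params$monthly
  m$tmin_mean <- m$tmin_mean + scenario$dtemp
  m$tmax_mean <- m$tmax_mean + scenario$dtemp
  m$gamma_scale <- m$gamma_scale * scenario$precip_mult
  m$rad_dry <- m$rad_dry * scenario$rad_mult
  m$rad_wet <- m$rad_wet * scenario$rad_mult
  ok <- m$gamma_scale > 0
  m$gamma_scale[!ok] <- .Machine$double.eps  # zero-rain handled via p_wd/p_ww? keep >0
  if (any(!ok)) { m$p_ww[!ok] <- 0; m$p_wd[!ok] <- 0 }
  site_climate(params$site, params$latitude, m, co2 = scenario$co2)
}

#' Generate a multi-year daily weather series
#'
#' Seeded stochastic generator on a 365-day calendar (no leap days).
#' Precipitation occurrence follows a first-order two-state Markov chain
#' with monthly transition probabilities; wet-day amounts are gamma
#' distributed; daily temperature is the monthly mean plus an independent
#' Gaussian deviation shared by Tmin and Tmax (plus diurnal-range jitter);
#' radiation is conditioned on wet/dry status.
#'
#' @param params a `site_climate`.
#' @param n_years number of years (>= 1).
#' @param seed integer RNG seed; same seed, same series.
#' @return data.frame of class `weather_series` with columns
#'   `year, doy, tmin_c, tmax_c, rain_mm, rad_mj` and attributes
#'   `site`, `latitude`, `co2`, `seed`.
#' @export
#' @examples
#' ws <- generate_weather(builtin_site("RR"), n_years = 2, seed = 42)
#' summarize_weather(ws)
generate_weather <- function(params, n_years, seed) {
  stopifnot(inherits(params, "site_climate"))
  if (!is.numeric(n_years) || n_years < 1 || n_years != round(n_years))
    stop("n_years must be a positive integer")
  n_years <- as.integer(n_years)
  m <- params$monthly
  n <- n_years * 365L
  doy <- rep.int(1:365, n_years)
  year <- rep(seq_len(n_years), each = 365L)
  mo <- MONTH_OF_DOY[doy]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  p_ww <- m$p_ww[mo]; p_wd <- m$p_wd[mo]
  u <- runif(n)
  wet <- logical(n)
  pi1 <- m$p_wd[1] / max(1 - m$p_ww[1] + m$p_wd[1], .Machine$double.eps)
  wet[1] <- u[1] < pi1
  for (d in 2:n)
    wet[d] <- u[d] < (if (wet[d - 1L]) p_ww[d] else p_wd[d])

  rain <- numeric(n)
  nw <- sum(wet)
  if (nw > 0)
    rain[wet] <- rgamma(nw, shape = m$gamma_shape[mo[wet]],
                        scale = m$gamma_scale[mo[wet]])

  dev <- rnorm(n, 0, m$t_sd[mo])
  tmin <- m$tmin_mean[mo] + dev
  dtr <- m$tmax_mean[mo] - m$tmin_mean[mo]
  tmax <- tmin + pmax(0.1, dtr[mo] + rnorm(n, 0, 0.8))

  radm <- ifelse(wet, m$rad_wet[mo], m$rad_dry[mo])
  rad <- pmax(0.05, radm + rnorm(n, 0, m$rad_sd[mo]))

  ws <- data.frame(year = year, doy = doy, tmin_c = tmin, tmax_c = tmax,
                   rain_mm = rain, rad_mj = rad)
  attr(ws, "site") <- params$site
  attr(ws, "latitude") <- params$latitude
  attr(ws, "co2") <- params$co2
  attr(ws, "seed") <- seed
  class(ws) <- c("weather_series", "data.frame")
  ws
}

#' Summarize a weather series
#'
#' @param series a `weather_series`.
#' @return list with `mean_temp` (degC), `annual_precip` (mm yr-1) and
#'   `mean_rad` (MJ m-2 day-1).
#' @export
summarize_weather <- function(series) {
  if (is.null(series) || nrow(series) == 0) stop("empty weather series")
  n_years <- nrow(series) / 365
  list(mean_temp = mean((series$tmin_c + series$tmax_c) / 2),
       annual_precip = sum(series$rain_mm) / n_years,
       mean_rad = mean(series$rad_mj))
}

#' Write / read a daily weather series as CSV
#'
#' Plain CSV with mandatory header `year,doy,tmin_c,tmax_c,rain_mm,rad_mj`.
#'
#' @param series a `weather_series`.
#' @param path file path.
#' @return `read_weather_csv` returns a validated `weather_series`.
#' @export
write_weather_csv <- function(series, path) {
  stopifnot(inherits(series, "weather_series"))
  write.csv(as.data.frame(series)[, c("year", "doy", "tmin_c", "tmax_c",
                                      "rain_mm", "rad_mj")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write site and scenario definitions as YAML
#'
#' Key-value schema: `site` (id), `latitude`, `co2`, and either `annual`
#' (keys `t_ann`, `p_ann`, `r_ann` plus any [site_from_annual()]
#' argument) or `monthly` (a list of the 11 [monthly_normals()] columns,
#' 12 values each). Scenario files carry `dtemp`, `precip_mult`,
#' `rad_mult`, `co2`, `lue` (see [climate_scenario()]).
#'
#' @param path YAML file path.
#' @return `read_site_config` returns a `site_climate`;
#'   `read_scenario_config` a `climate_scenario`.
#' @export
read_site_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$monthly))
    site_climate(y$site, y$latitude,
                 do.call(monthly_normals, y$monthly),
                 co2 = if (is.null(y$co2)) 364 else y$co2)
  else
    do.call(site_from_annual,
            c(list(site = y$site, latitude = y$latitude), y$annual,
              if (!is.null(y$co2)) list(co2 = y$co2)))
}

#' @rdname read_site_config
#' @param site a `site_climate` to serialize.
#' @export
write_site_config <- function(site, path) {
  stopifnot(inherits(site, "site_climate"))
  yaml::write_yaml(list(site = site$site, latitude = site$latitude,
                        co2 = site$co2,
                        monthly = as.list(as.data.frame(site$monthly))),
                   path)
  invisible(path)
}

#' @rdname read_site_config
#' @export
read_scenario_config <- function(path) {
  do.call(climate_scenario, yaml::read_yaml(path))
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  ws <- read.csv(path)
  req <- c("year", "doy", "tmin_c", "tmax_c", "rain_mm", "rad_mj")
  miss <- setdiff(req, names(ws))
  if (length(miss)) stop("weather CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(ws$tmax_c < ws$tmin_c)) stop("weather CSV: tmax_c < tmin_c")
  if (any(ws$rain_mm < 0)) stop("weather CSV: negative rain_mm")
  if (any(ws$rad_mj < 0)) stop("weather CSV: negative rad_mj")
  class(ws) <- c("weather_series", "data.frame")
  ws
}
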