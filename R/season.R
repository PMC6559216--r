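#' Simulation configuration
#'
#' Site, management and numerical constants for one simulation setup.
#' Sowing is on a fixed calendar day every year: day-of-year 293 (20
#' October) for the UK sites and 110 (20 April) for the NZ sites.
#'
#' @param sowing_doy sowing day of year (1..365).
#' @param latitude site latitude (signed degrees).
#' @param soil a `soil_profile` or a built-in id
#'   (`"rothamsted_210"`, `"lincoln_270"`).
#' @param water_mode `"rainfed"` or `"irrigated"`. Irrigated runs pin the
#'   daily water stress factor FW to 1 (no-water-limitation potential
#'   condition); the soil balance is skipped.
#' @param co2 atmospheric CO2 (ppm); `NA` takes the value carried by the
#'   weather series.
#' @param lue light-use-efficiency multiplier (1.10 in the ideotype-design
#'   scenario runs).
#' @param k canopy extinction coefficient.
#' @param rue_base base radiation use efficiency (g DM MJ-1 PAR) at the
#'   338 ppm CO2 reference.
#' @param ear_fraction ear dry mass at anthesis as a fraction of
#'   above-ground biomass.
#' @param shoot_density shoots per m2 soil converting per-shoot leaf layer
#'   areas (`A_Max` is the flag-leaf area of one shoot) into canopy LAI.
#'   The default is calibrated so the reference cultivar reaches an
#'   anthesis LAI near 7.7.
#' @param t_base base temperature for thermal time (degC).
#' @param anthesis_lag phyllochrons from flag-leaf completion to anthesis.
#' @param dl_ref,fln_scale final-leaf-number response constants, see
#'   [final_leaf_number()].
#' @param dsf_window_tt thermal-time span before anthesis opening the
#'   drought-sensitive reproductive window (degC day); the window closes at
#'   the beginning of grain fill.
#' @param max_days failsafe season length (days after sowing).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(sowing_doy = 293, latitude = 51.80,
                       soil = "rothamsted_210",
                       water_mode = c("rainfed", "irrigated"),
                       co2 = NA, lue = 1, k = 0.45, rue_base = 2.7,
                       ear_fraction = 0.19, shoot_density = 125,
                       t_base = 0, anthesis_lag = 2,
                       dl_ref = 20, fln_scale = 1, dsf_window_tt = 300,
                       max_days = 400) {
  water_mode <- match.arg(water_mode)
  if (is.character(soil)) soil <- builtin_soil(soil)
  stopifnot(inherits(soil, "soil_profile"))
  if (sowing_doy < 1 || sowing_doy > 365) stop("sowing_doy must be in 1..365")
  cfg <- list(sowing_doy = as.integer(sowing_doy), latitude = latitude,
              soil = soil, water_mode = water_mode, co2 = co2, lue = lue,
              k = k, rue_base = rue_base, ear_fraction = ear_fraction,
              shoot_density = shoot_density,
              t_base = t_base, anthesis_lag = anthesis_lag,
              dl_ref = dl_ref, fln_scale = fln_scale,
              dsf_window_tt = dsf_window_tt, max_days = as.integer(max_days))
  class(cfg) <- "sim_config"
  cfg
}

# Stable short hash of a configuration/cultivar for provenance
# (polynomial rolling hash mod 2^32, double-safe).
config_hash <- function(...) {
  s <- paste(deparse(list(...)), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  format(h, scientific = FALSE)
}

#' One step of grain filling
#'
#' The labile carbohydrate pool (25\% of anthesis biomass) is translocated
#' to the grain uniformly per unit thermal time over the grain-filling
#' window; new post-anthesis assimilate also goes to the grain. Grain mass
#' is capped by the sink (grain number x maximum grain weight). If the
#' canopy is dead, filling stops and the remaining labile pool is
#' forfeited.
#'
#' @param grain_mass current grain mass (g m-2).
#' @param labile_remaining remaining labile pool (g m-2).
#' @param labile_total initial labile pool (g m-2).
#' @param new_assim daily assimilate (g m-2).
#' @param canopy_alive logical; FALSE stops filling.
#' @param sink_cap grain number x maximum grain weight (g m-2).
#' @param dtt daily thermal time (degC day).
#' @param g_f grain-filling duration (degC day).
#' @return list with updated `grain_mass` and `labile_remaining`.
#' @export
grain_fill_step <- function(grain_mass, labile_remaining, labile_total,
                            new_assim, canopy_alive, sink_cap, dtt, g_f) {
  if (!canopy_alive)
    return(list(grain_mass = grain_mass, labile_remaining = labile_remaining))
  release <- min(labile_remaining, labile_total * dtt / g_f)
  list(grain_mass = min(sink_cap, grain_mass + new_assim + release),
       labile_remaining = labile_remaining - release)
}

failed_season <- function(reason) {
  structure(list(yield = 0, biomass = 0, hi = 0, grain_number = 0,
                 anthesis_das = NA_integer_, maturity_das = NA_integer_,
                 anthesis_doy = NA_integer_, maturity_doy = NA_integer_,
                 gf_days = NA_integer_, lai_anthesis = NA_real_,
                 intercepted_mj = 0, dsf = NA_real_, heat_red = NA_real_,
                 fln = NA_real_, matured = FALSE, failed = TRUE,
                 reason = reason, water_balance = NULL),
            class = "season_result")
}

#' Simulate one wheat season
#'
#' Runs the daily loop from sowing to maturity (or the failsafe horizon):
#' thermal time, phenology, leaf-layer canopy with stay-green-modulated
#' senescence, light interception, soil water balance with root
#' extraction (rainfed mode), RUE biomass production with CO2/LUE/
#' temperature/water modifiers, grain setting under heat and drought
#' stress, and grain filling from new assimilate plus the labile pool.
#'
#' @param cultivar a `cultivar_params`.
#' @param weather a `weather_series` covering the season.
#' @param sowing_year_index year (of the series) in which sowing occurs.
#' @param config a `sim_config`.
#' @return list of class `season_result`: `yield` and `biomass` (t ha-1),
#'   `hi`, stage dates (day of year and days after sowing), grain-filling
#'   duration (days), LAI at anthesis, cumulative intercepted solar
#'   radiation (MJ m-2), `dsf`, `heat_red`, `fln`, flags, and a
#'   `water_balance` list for rainfed runs.
#' @export
simulate_season <- function(cultivar, weather, sowing_year_index, config) {
  stopifnot(inherits(cultivar, "cultivar_params"),
            inherits(config, "sim_config"))
  i0 <- which(weather$year == sowing_year_index &
                weather$doy == config$sowing_doy)
  if (length(i0) != 1L) stop("sowing day not found in weather series")
  i1 <- min(i0 + config$max_days - 1L, nrow(weather))
  if (i1 - i0 + 1L < 250L) stop("weather series too short after sowing")
  idx <- i0:i1
  tmin <- weather$tmin_c[idx]; tmax <- weather$tmax_c[idx]
  rain <- weather$rain_mm[idx]; rad <- weather$rad_mj[idx]
  doy <- weather$doy[idx]
  n <- length(idx)

  co2 <- if (is.na(config$co2)) attr(weather, "co2") else config$co2
  if (is.null(co2) || is.na(co2)) co2 <- 364

  ph <- compute_phenology(tmin, tmax, doy, cultivar, config$latitude,
                          t_base = config$t_base,
                          anthesis_lag = config$anthesis_lag,
                          dl_ref = config$dl_ref,
                          fln_scale = config$fln_scale)
  if (is.na(ph$d_em) || is.na(ph$d_anth) || is.na(ph$d_bgf))
    return(failed_season("no anthesis within the failsafe horizon"))

  ctt <- ph$ctt; dtt <- ph$dtt
  d_end <- if (ph$complete) ph$d_mat else n
  tmean <- (tmin + tmax) / 2
  f_temp <- pmin(1, pmax(0, tmean / 10))
  rue_eff <- config$rue_base * co2_rue_factor(co2) * config$lue
  g_f <- cultivar$TT_BGFEGF
  laipot <- config$shoot_density *
    canopy_lai_potential(ctt, ph$tt_em, ph$fln, cultivar$P_h,
                         cultivar$A_Max)
  onset_tt <- senescence_onset_tt(ph$tt_bgf, g_f, cultivar$S_G)
  sen_win <- ph$tt_egf - onset_tt
  heat_idx <- which(ctt >= ph$tt_anth - cultivar$TT_ANBGF &
                      ctt <= ph$tt_anth + cultivar$TT_ANBGF)
  dsf_idx <- which(ctt >= ph$tt_anth - config$dsf_window_tt &
                     ctt <= ph$tt_bgf)
  heat_red <- heat_stress_reduction(tmax[heat_idx], cultivar$HSGNT,
                                    cultivar$HSGNR)

  if (config$water_mode == "irrigated") {
    gfrac <- pmin(1, pmax(0, 1 - (ctt - onset_tt) / sen_win))
    gfrac[ctt >= ph$tt_egf] <- 0
    lai <- laipot * gfrac
    fint <- 1 - exp(-config$k * lai)
    db <- daily_biomass_increment(0.5 * rad * fint, rue_eff,
                                  f_temp = f_temp, fw = 1,
                                  w_sa = cultivar$W_sa)
    db[seq_len(n) > d_end] <- 0
    bm <- cumsum(db)
    bm_anth <- bm[ph$d_anth]
    dsf <- 1
    gn <- set_grain_number(bm_anth, cultivar$GNEar, config$ear_fraction,
                           heat_red, drought_gn_reduction(dsf, cultivar$DSGNT,
                                                          cultivar$DSGNS,
                                                          cultivar$DSGNRMax))
    labile <- 0.25 * bm_anth
    cap <- gn * cultivar$MaxGW
    # all post-anthesis assimilate is committed to the grain (until the
    # sink cap); the labile pool is released per unit thermal time
    fill <- which(seq_len(n) > ph$d_anth & seq_len(n) <= d_end & lai > 0)
    rel_frac <- if (length(fill)) min(1, max((ctt[fill] - ph$tt_bgf) / g_f)) else 0
    rel_frac <- max(0, rel_frac)
    grain <- min(cap, sum(db[fill]) + labile * rel_frac)
    bm_final <- bm[d_end]
    fw_mean_window <- 1
    wb <- NULL
  } else {
    soil <- config$soil
    z_top <- (seq_along(soil$cap) - 1) * soil$layer_cm
    maxd <- soil$depth_cm
    storage0 <- sum(soil$water)
    drain_tot <- 0; uptake_tot <- 0; rain_tot <- 0
    gfrac <- 1; sen_eff <- 0
    bm <- 0; bm_anth <- NA_real_; ear_pool <- 0
    labile <- 0; labile_rem <- 0; grain <- 0; cap <- Inf; gn <- 0
    dsf <- NA_real_
    fw_vec <- rep(1, n)
    fint_vec <- numeric(n)
    lai_anth <- NA_real_
    w_sa <- cultivar$W_sa; w_ss <- cultivar$W_ss; r_u <- cultivar$R_u
    k <- config$k
    for (d in seq_len(d_end)) {
      lai <- if (ctt[d] >= ph$tt_egf) 0 else laipot[d] * gfrac
      fint <- 1 - exp(-k * lai)
      fint_vec[d] <- fint
      # infiltration cascade
      if (rain[d] > 0) {
        deficit <- soil$cap - soil$water
        room <- c(0, cumsum(deficit)[-length(deficit)])
        fill_mm <- pmin(deficit, pmax(0, rain[d] - room))
        soil$water <- soil$water + fill_mm
        drain_tot <- drain_tot + rain[d] - sum(fill_mm)
        rain_tot <- rain_tot + rain[d]
      }
      # extraction and stress
      fw <- 1
      if (fint > 1e-9) {
        rd <- maxd * min(1, ctt[d] / ph$tt_anth)
        rooted <- z_top < rd
        if (!any(rooted)) rooted[1] <- TRUE
        frac <- numeric(length(z_top))
        frac[rooted] <- pmax(0, (10 + (r_u - 10) * z_top[rooted] /
                                   max(rd, soil$layer_cm)) / 100)
        extr <- frac * soil$water
        supply <- sum(extr)
        demand <- transpiration_demand(rad[d], tmean[d], fint)
        if (demand > 0) {
          fw <- min(1, supply / demand)
          uptake <- min(supply, demand)
          if (uptake > 0) {
            soil$water <- soil$water - uptake * extr / supply
            uptake_tot <- uptake_tot + uptake
          }
        }
      }
      fw_vec[d] <- fw
      db <- 0.5 * rad[d] * fint * rue_eff * f_temp[d] *
        (1 - w_sa * (1 - fw))
      bm <- bm + db
      if (d == ph$d_anth) {
        bm_anth <- bm
        labile <- 0.25 * bm_anth
        labile_rem <- labile
        lai_anth <- lai
      } else if (!is.na(bm_anth) && d < ph$d_bgf && lai > 0) {
        ear_pool <- ear_pool + db  # post-anthesis assimilate held for grain
      }
      if (ctt[d] > onset_tt && sen_win > 0) {
        sen_eff <- sen_eff + dtt[d] * (1 + (w_ss - 1) * (1 - fw))
        gfrac <- max(0, 1 - sen_eff / sen_win)
      }
      if (d == ph$d_bgf) {
        dsf <- drought_stress_factor(fw_vec[dsf_idx])
        gn <- set_grain_number(bm_anth, cultivar$GNEar, config$ear_fraction,
                               heat_red,
                               drought_gn_reduction(dsf, cultivar$DSGNT,
                                                    cultivar$DSGNS,
                                                    cultivar$DSGNRMax))
        cap <- gn * cultivar$MaxGW
        grain <- min(cap, ear_pool)
      }
      if (d > ph$d_bgf && lai > 0 && labile >= 0) {
        st <- grain_fill_step(grain, labile_rem, labile, db, TRUE, cap,
                              dtt[d], g_f)
        grain <- st$grain_mass
        labile_rem <- st$labile_remaining
      }
    }
    bm_final <- bm
    fw_mean_window <- dsf
    wb <- list(rain = rain_tot, drainage = drain_tot, uptake = uptake_tot,
               storage_initial = storage0, storage_final = sum(soil$water))
  }

  if (config$water_mode == "irrigated")
    lai_anth <- laipot[ph$d_anth] *
      min(1, max(0, 1 - (ctt[ph$d_anth] - onset_tt) / sen_win))
  intercepted <- if (config$water_mode == "irrigated")
    sum(rad[seq_len(d_end)] * fint[seq_len(d_end)]) else
      sum(rad[seq_len(d_end)] * fint_vec[seq_len(d_end)])

  structure(list(
    yield = 0.01 * grain, biomass = 0.01 * bm_final,
    hi = if (bm_final > 0) grain / bm_final else 0,
    grain_number = gn,
    anthesis_das = ph$d_anth, maturity_das = if (ph$complete) ph$d_mat else NA_integer_,
    anthesis_doy = doy[ph$d_anth],
    maturity_doy = if (ph$complete) doy[ph$d_mat] else NA_integer_,
    gf_days = if (!is.na(ph$d_egf)) ph$d_egf - ph$d_bgf else NA_integer_,
    lai_anthesis = lai_anth, intercepted_mj = intercepted,
    dsf = dsf, heat_red = heat_red, fln = ph$fln,
    matured = isTRUE(ph$complete), failed = FALSE, reason = NA_character_,
    water_balance = wb), class = "season_result")
}

#' Simulate an ensemble of seasons
#'
#' Sows every year of the weather series (dropping the final year, whose
#' season would run past the end of the record) and aggregates the
#' per-season results: mean, SD and CV (\%) of yield, mean harvest index,
#' and the 5/25/50/75/95 percentiles (linear interpolation between order
#' statistics) of yield and related outputs.
#'
#' @param cultivar a `cultivar_params`.
#' @param weather a `weather_series` spanning at least 3 years.
#' @param config a `sim_config`.
#' @return list of class `ensemble_result` with a per-season data.frame
#'   `seasons` and the aggregate statistics.
#' @export
simulate_ensemble <- function(cultivar, weather, config) {
  n_years <- max(weather$year)
  sow_years <- seq_len(n_years - 1L)
  if (length(sow_years) < 2L) stop("need at least 2 sowing years (3 weather years)")
  res <- lapply(sow_years, function(y)
    simulate_season(cultivar, weather, y, config))
  num <- function(f) vapply(res, function(r) as.numeric(r[[f]]), numeric(1))
  seasons <- data.frame(
    sow_year = sow_years, yield = num("yield"), biomass = num("biomass"),
    hi = num("hi"), anthesis_das = num("anthesis_das"),
    maturity_das = num("maturity_das"), gf_days = num("gf_days"),
    lai_anthesis = num("lai_anthesis"), intercepted_mj = num("intercepted_mj"),
    dsf = num("dsf"), heat_red = num("heat_red"), fln = num("fln"),
    failed = vapply(res, function(r) r$failed, logical(1)))
  y <- seasons$yield
  m <- mean(y); s <- sd(y)
  pct <- function(x) quantile(x, c(0.05, 0.25, 0.50, 0.75, 0.95),
                              names = TRUE, na.rm = TRUE, type = 7)
  structure(list(
    seasons = seasons,
    n = length(y),
    mean_yield = m, sd_yield = s,
    cv_yield = if (m > 0) 100 * s / m else Inf,
    mean_hi = mean(seasons$hi),
    mean_biomass = mean(seasons$biomass),
    mean_lai_anthesis = mean(seasons$lai_anthesis, na.rm = TRUE),
    mean_intercepted = mean(seasons$intercepted_mj),
    mean_anthesis_das = mean(seasons$anthesis_das, na.rm = TRUE),
    mean_maturity_das = mean(seasons$maturity_das, na.rm = TRUE),
    yield_percentiles = pct(y),
    hi_percentiles = pct(seasons$hi),
    any_failed = any(seasons$failed),
    config_hash = config_hash(cultivar, config),
    seed = attr(weather, "seed")), class = "ensemble_result")
}
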