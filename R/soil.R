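#' Layered soil water profile
#'
#' Cascade ("tipping bucket") profile of 5-cm layers with equal available
#' water capacity per layer summing to the profile total. Two built-ins
#' match the study soils: `rothamsted_210` (210 mm AWC) and `lincoln_270`
#' (270 mm AWC), both 150 cm deep (30 layers).
#'
#' @param total_awc total available water capacity (mm).
#' @param depth_cm profile depth (cm), a multiple of 5.
#' @param initial_fill fraction of capacity present at construction;
#'   profiles are initialized full at sowing by default.
#' @return list of class `soil_profile` with `cap` and `water` (mm per
#'   layer), `layer_cm`, `depth_cm`.
#' @export
#' @examples
#' soil_profile(210)                 # the 210 mm profile
#' builtin_soil("lincoln_270")
soil_profile <- function(total_awc, depth_cm = 150, initial_fill = 1) {
  if (total_awc <= 0) stop("total_awc must be > 0")
  if (depth_cm <= 0 || depth_cm %% 5 != 0)
    stop("depth_cm must be a positive multiple of 5")
  if (initial_fill < 0 || initial_fill > 1)
    stop("initial_fill must be in [0, 1]")
  n <- depth_cm / 5
  cap <- rep(total_awc / n, n)
  structure(list(cap = cap, water = cap * initial_fill,
                 layer_cm = 5, depth_cm = depth_cm),
            class = "soil_profile")
}

#' @rdname soil_profile
#' @param id `"rothamsted_210"` or `"lincoln_270"`.
#' @export
builtin_soil <- function(id = c("rothamsted_210", "lincoln_270")) {
  id <- match.arg(id)
  switch(id, rothamsted_210 = soil_profile(210), lincoln_270 = soil_profile(270))
}

#' Infiltrate rain through the layer cascade
#'
#' Water fills layers top-down to capacity; the excess below the bottom
#' layer leaves as drainage. Mass balance: rain = change in storage +
#' drainage.
#'
#' @param profile a `soil_profile`.
#' @param rain daily precipitation (mm, >= 0).
#' @return list with the updated `profile` and `drainage` (mm).
#' @export
infiltrate_and_drain <- function(profile, rain) {
  if (rain < 0) stop("rain must be >= 0")
  deficit <- profile$cap - profile$water
  room_above <- c(0, cumsum(deficit)[-length(deficit)])
  fill <- pmin(deficit, pmax(0, rain - room_above))
  profile$water <- profile$water + fill
  list(profile = profile, drainage = rain - sum(fill))
}

#' Extractable soil water supply
#'
#' Daily extractable water summed over rooted layers. The per-layer
#' extraction fraction declines linearly with the depth of the layer top
#' from 10\% at the soil surface to `r_u`\% at the current root front.
#'
#' @param profile a `soil_profile`.
#' @param root_depth current rooting depth (cm, within the profile).
#' @param r_u uptake rate at the root bottom (\%).
#' @return extractable supply (mm).
#' @export
extractable_supply <- function(profile, root_depth, r_u) {
  if (root_depth < 0) stop("root_depth must be >= 0")
  if (root_depth > profile$depth_cm) root_depth <- profile$depth_cm
  sum(extraction_fractions(profile, root_depth, r_u) * profile$water)
}

# Per-layer extraction fractions (0 for layers below the root front).
extraction_fractions <- function(profile, root_depth, r_u) {
  n <- length(profile$cap)
  z_top <- (seq_len(n) - 1) * profile$layer_cm
  frac <- numeric(n)
  rooted <- z_top < root_depth | (root_depth > 0 & z_top == 0)
  if (root_depth <= 0) {
    frac[1] <- 0.10  # roots at the surface extract from the top layer
    return(frac)
  }
  frac[rooted] <- (10 + (r_u - 10) * z_top[rooted] / root_depth) / 100
  pmax(frac, 0)
}

#' Canopy transpiration demand
#'
#' Priestley-Taylor-style equilibrium evaporation scaled by the fraction of
#' PAR intercepted by the canopy (soil evaporation is not simulated).
#'
#' @param global_rad daily global radiation (MJ m-2 day-1).
#' @param t_mean daily mean air temperature (degC).
#' @param f_par_intercepted canopy interception fraction in \[0, 1\].
#' @param alpha Priestley-Taylor coefficient (default 1.26).
#' @param rn_frac net/global radiation ratio (default 0.65).
#' @return demand (mm day-1, >= 0).
#' @export
transpiration_demand <- function(global_rad, t_mean, f_par_intercepted,
                                 alpha = 1.26, rn_frac = 0.65) {
  es <- 0.6108 * exp(17.27 * t_mean / (t_mean + 237.3))
  s <- 4098 * es / (t_mean + 237.3)^2      # kPa / degC
  gamma <- 0.066                            # psychrometric constant
  lambda <- 2.45                            # MJ / kg
  pmax(0, alpha * s / (s + gamma) * rn_frac * global_rad / lambda *
         f_par_intercepted)
}

#' One day of the soil water stress bookkeeping
#'
#' Computes the water stress factor `FW = min(1, supply/demand)` (1 when
#' demand is zero) and removes the actual uptake `min(supply, demand)`
#' from the rooted layers proportionally to each layer's extractable
#' amount.
#'
#' @param profile a `soil_profile`.
#' @param supply extractable supply (mm).
#' @param demand transpiration demand (mm).
#' @param root_depth rooting depth (cm).
#' @param r_u uptake rate at the root bottom (\%).
#' @return list with `fw`, `uptake` (mm) and the updated `profile`.
#' @export
water_stress_step <- function(profile, supply, demand, root_depth, r_u) {
  if (supply < 0 || demand < 0) stop("supply and demand must be >= 0")
  fw <- if (demand <= 0) 1 else min(1, supply / demand)
  uptake <- min(supply, demand)
  if (uptake > 0) {
    extr <- extraction_fractions(profile, root_depth, r_u) * profile$water
    profile$water <- profile$water - uptake * extr / sum(extr)
  }
  list(fw = fw, uptake = uptake, profile = profile)
}

#' Drought stress factor
#'
#' Arithmetic mean of the daily water stress factor over the reproductive
#' window (300 degC day before anthesis through the beginning of grain
#' fill).
#'
#' @param fw_history daily FW values over the window.
#' @return DSF in \[0, 1\].
#' @export
drought_stress_factor <- function(fw_history) {
  if (!length(fw_history)) stop("empty FW window")
  mean(fw_history)
}
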