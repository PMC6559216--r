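#' CO2 response of radiation use efficiency
#'
#' RUE is proportional to atmospheric CO2, rising 30\% for a doubling
#' relative to the 338 ppm reference.
#'
#' @param co2 atmospheric CO2 (ppm, > 0).
#' @return dimensionless multiplier: `1 + 0.30 * (co2 - 338) / 338`.
#' @export
#' @examples
#' co2_rue_factor(338)  # 1.00
#' co2_rue_factor(676)  # 1.30
co2_rue_factor <- function(co2) {
  if (any(co2 <= 0)) stop("co2 must be > 0")
  1 + 0.30 * (co2 - 338) / 338
}

#' Daily above-ground biomass increment
#'
#' Product of intercepted PAR and radiation use efficiency with CO2,
#' light-use-efficiency, temperature and water-stress modifiers. The water
#' term is `1 - w_sa * (1 - fw)`: with `fw = 1` production is unstressed;
#' with full stress it is reduced by the photosynthesis sensitivity `w_sa`.
#'
#' @param par_int intercepted PAR (MJ m-2).
#' @param rue_base base RUE (g DM MJ-1 PAR) at the 338 ppm reference.
#' @param co2_factor CO2 multiplier, see [co2_rue_factor()].
#' @param lue_factor light-use-efficiency multiplier.
#' @param f_temp temperature factor in \[0, 1\].
#' @param fw daily water stress factor in \[0, 1\].
#' @param w_sa response of photosynthesis to water stress in \[0, 1\].
#' @return biomass increment (g m-2, >= 0), vectorized.
#' @export
daily_biomass_increment <- function(par_int, rue_base, co2_factor = 1,
                                    lue_factor = 1, f_temp = 1, fw = 1,
                                    w_sa = 0.5) {
  if (any(f_temp < 0 | f_temp > 1)) stop("f_temp must be in [0, 1]")
  if (any(fw < 0 | fw > 1)) stop("fw must be in [0, 1]")
  par_int * rue_base * co2_factor * lue_factor * f_temp *
    (1 - w_sa * (1 - fw))
}

#' Heat-stress reduction of grain number
#'
#' Degree-day exceedance of daily maximum temperature above the threshold
#' `hsgnt`, accumulated over the reproductive window and scaled by the
#' reduction rate `hsgnr`; capped at 1 (total sterility).
#'
#' @param tmax_window daily Tmax over the window (degC).
#' @param hsgnt threshold temperature (degC).
#' @param hsgnr reduction rate (degC-1).
#' @return reduction fraction in \[0, 1\].
#' @export
heat_stress_reduction <- function(tmax_window, hsgnt, hsgnr) {
  if (!length(tmax_window)) stop("empty Tmax window")
  min(1, hsgnr * sum(pmax(0, tmax_window - hsgnt)))
}

#' Drought-stress reduction of grain number
#'
#' Piecewise-linear in the drought stress factor: zero at or above the
#' threshold `dsgnt`, the maximum reduction at or below the saturation
#' `dsgns`, linear in between.
#'
#' @param dsf drought stress factor in \[0, 1\].
#' @param dsgnt stress threshold (no reduction above).
#' @param dsgns stress saturation (maximum reduction below).
#' @param dsgnr_max maximum reduction fraction.
#' @return reduction in \[0, dsgnr_max\].
#' @export
drought_gn_reduction <- function(dsf, dsgnt, dsgns, dsgnr_max) {
  if (dsgns >= dsgnt) stop("dsgns must be < dsgnt")
  if (dsf >= dsgnt) return(0)
  if (dsf <= dsgns) return(dsgnr_max)
  dsgnr_max * (dsgnt - dsf) / (dsgnt - dsgns)
}

#' Grain number at the start of grain fill
#'
#' Proportional to ear dry mass at anthesis (a fixed fraction of anthesis
#' biomass) via the grains-per-gram-ear parameter, with the heat and
#' drought reductions applied multiplicatively.
#'
#' @param anthesis_biomass above-ground biomass at anthesis (g m-2).
#' @param gn_ear grains per g ear dry mass (g-1).
#' @param ear_fraction ear dry mass as a fraction of anthesis biomass.
#' @param heat_red,drought_red reduction fractions in \[0, 1\].
#' @return grain number (grains m-2).
#' @export
set_grain_number <- function(anthesis_biomass, gn_ear, ear_fraction,
                             heat_red = 0, drought_red = 0) {
  gn_ear * ear_fraction * anthesis_biomass *
    (1 - heat_red) * (1 - drought_red)
}

#' Harvest index
#'
#' @param grain_mass grain mass (g m-2).
#' @param total_biomass total above-ground biomass (g m-2, > 0).
#' @return grain/total ratio in \[0, 1\].
#' @export
harvest_index <- function(grain_mass, total_biomass) {
  if (any(total_biomass <= 0)) stop("total biomass must be > 0")
  grain_mass / total_biomass
}
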