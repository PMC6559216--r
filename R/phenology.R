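#' Daily thermal time
#'
#' Mean daily temperature above the base temperature, clipped at zero.
#'
#' @param tmin,tmax daily minimum / maximum air temperature (degC).
#' @param t_base base temperature (degC), default 0 for winter wheat.
#' @return thermal time (degC day), vectorized.
#' @export
daily_thermal_time <- function(tmin, tmax, t_base = 0) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  pmax(0, (tmin + tmax) / 2 - t_base)
}

#' Astronomical day length
#'
#' Standard solar-declination formula: declination
#' -23.44 cos(2 pi (doy + 10)/365), day length from the sunrise hour angle.
#'
#' @param latitude signed degrees, |latitude| <= 66 (polar regimes are
#'   rejected).
#' @param doy day of year, 1-based (365-day calendar).
#' @return day length in hours, in (0, 24).
#' @export
day_length <- function(latitude, doy) {
  if (any(abs(latitude) > 66)) stop("polar latitudes (|lat| > 66) not supported")
  decl <- -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  phi <- latitude * pi / 180
  cosH <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  24 / pi * acos(cosH)
}

#' Daily vernalization rate
#'
#' Linear response of the vernalization rate to mean temperature:
#' `max(0, VBEE + VAI * t_mean)` per day; progress saturates at 1.
#'
#' @param t_mean daily mean temperature (degC).
#' @param VAI response of vernalization rate to temperature (day-1 degC-1).
#' @param VBEE vernalization rate at 0 degC (day-1).
#' @return daily increment of vernalization progress, vectorized.
#' @export
vernalization_rate <- function(t_mean, VAI, VBEE) {
  pmax(0, VBEE + VAI * t_mean)
}

#' Final leaf number from day length at vernalization saturation
#'
#' Once vernalization saturates, the final mainstem leaf number is fixed
#' from that day's photoperiod:
#' `FLN = clamp(L_Min + fln_scale * P_p * max(0, dl_ref - dl), L_Min, L_Max)`.
#' Shorter days at saturation give more leaves; the response is monotone
#' non-increasing in day length with slope `P_p` (leaves per hour).
#'
#' @param cultivar a `cultivar_params`.
#' @param dl_at_vernsat day length on the saturation day (hours).
#' @param dl_ref reference (ceiling) day length (hours), default 20.
#' @param fln_scale dimensionless scaling of the response, default 1.
#' @return final leaf number (real, within `[L_Min, L_Max]`).
#' @export
final_leaf_number <- function(cultivar, dl_at_vernsat, dl_ref = 20,
                              fln_scale = 1) {
  fln <- cultivar$L_Min +
    fln_scale * cultivar$P_p * pmax(0, dl_ref - dl_at_vernsat)
  pmin(cultivar$L_Max, pmax(cultivar$L_Min, fln))
}

#' Phenological schedule for one season
#'
#' Vectorized thermal-time bookkeeping from sowing: emergence when
#' cumulative thermal time reaches `TT_SOWEM`; vernalization progress
#' accumulates daily and fixes the final leaf number (FLN) from the day
#' length at saturation (FLN defaults to `L_Max` if saturation is never
#' reached); the Haun stage advances by `dtt / P_h` after emergence;
#' anthesis occurs `anthesis_lag` phyllochrons after the Haun stage reaches
#' FLN; grain fill begins `TT_ANBGF` after anthesis, ends `TT_BGFEGF`
#' later; maturity `TT_EGFMAT` after that.
#'
#' @param tmin,tmax daily temperature vectors from sowing (degC).
#' @param doy day-of-year vector aligned with the temperatures.
#' @param cultivar a `cultivar_params`.
#' @param latitude site latitude (degrees).
#' @param t_base base temperature (degC).
#' @param anthesis_lag phyllochrons between flag-leaf completion and
#'   anthesis (default 2).
#' @param dl_ref,fln_scale see [final_leaf_number()].
#' @return list with cumulative thermal time `ctt`, `fln`, stage thermal
#'   times (`tt_em`, `tt_anth`, `tt_bgf`, `tt_egf`, `tt_mat`), stage day
#'   indices (`d_em`, `d_vsat`, `d_anth`, `d_bgf`, `d_egf`, `d_mat`; NA if
#'   not reached) and `complete` (TRUE if maturity falls inside the
#'   weather window).
#' @export
compute_phenology <- function(tmin, tmax, doy, cultivar, latitude,
                              t_base = 0, anthesis_lag = 2,
                              dl_ref = 20, fln_scale = 1) {
  dtt <- daily_thermal_time(tmin, tmax, t_base)
  ctt <- cumsum(dtt)
  first_at <- function(x, thr) {
    i <- which(x >= thr)
    if (length(i)) i[1] else NA_integer_
  }
  d_em <- first_at(ctt, cultivar$TT_SOWEM)
  vprog <- cumsum(vernalization_rate((tmin + tmax) / 2,
                                     cultivar$VAI, cultivar$VBEE))
  d_vsat <- first_at(vprog, 1)
  fln <- if (is.na(d_vsat)) cultivar$L_Max else
    final_leaf_number(cultivar, day_length(latitude, doy[d_vsat]),
                      dl_ref = dl_ref, fln_scale = fln_scale)
  if (is.na(d_em))
    return(list(ctt = ctt, dtt = dtt, fln = fln, tt_em = NA_real_,
                tt_anth = NA_real_, tt_bgf = NA_real_, tt_egf = NA_real_,
                tt_mat = NA_real_, d_em = NA_integer_, d_vsat = d_vsat,
                d_anth = NA_integer_, d_bgf = NA_integer_,
                d_egf = NA_integer_, d_mat = NA_integer_, complete = FALSE))
  tt_em <- ctt[d_em]
  tt_anth <- tt_em + (fln + anthesis_lag) * cultivar$P_h
  if (!is.na(d_vsat)) tt_anth <- max(tt_anth, ctt[d_vsat])
  tt_bgf <- tt_anth + cultivar$TT_ANBGF
  tt_egf <- tt_bgf + cultivar$TT_BGFEGF
  tt_mat <- tt_egf + cultivar$TT_EGFMAT
  d_anth <- first_at(ctt, tt_anth)
  d_bgf <- first_at(ctt, tt_bgf)
  d_egf <- first_at(ctt, tt_egf)
  d_mat <- first_at(ctt, tt_mat)
  list(ctt = ctt, dtt = dtt, fln = fln, tt_em = tt_em, tt_anth = tt_anth,
       tt_bgf = tt_bgf, tt_egf = tt_egf, tt_mat = tt_mat,
       d_em = d_em, d_vsat = d_vsat, d_anth = d_anth, d_bgf = d_bgf,
       d_egf = d_egf, d_mat = d_mat, complete = !is.na(d_mat))
}
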