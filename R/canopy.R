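#' Potential area of a leaf layer
#'
#' The canopy is a stack of leaf layers, one per mainstem leaf rank.
#' Potential layer area ramps linearly from 0.25 x A_Max for the first leaf
#' to A_Max for the flag leaf.
#'
#' @param rank leaf rank, 1-based (1 = first leaf, highest rank = flag).
#' @param fln final leaf number (real).
#' @param a_max maximum (flag) leaf layer area (m2 leaf m-2 soil).
#' @return potential layer area (m2 m-2), vectorized over `rank`.
#' @export
potential_layer_area <- function(rank, fln, a_max) {
  nl <- ceiling(fln)
  if (any(rank < 1 | rank > nl)) stop("rank out of 1..ceiling(fln)")
  if (nl <= 1) return(rep(a_max, length(rank)))
  a_max * (0.25 + 0.75 * (rank - 1) / (nl - 1))
}

#' Intercepted photosynthetically active radiation
#'
#' Beer's law on green LAI; PAR is taken as half the global radiation.
#'
#' @param lai green leaf area index (>= 0).
#' @param global_rad daily global radiation (MJ m-2 day-1, >= 0).
#' @param k canopy extinction coefficient (default 0.45).
#' @return intercepted PAR (MJ m-2 day-1), bounded by `0.5 * global_rad`.
#' @export
intercepted_par <- function(lai, global_rad, k = 0.45) {
  if (any(lai < 0)) stop("lai must be >= 0")
  if (any(global_rad < 0)) stop("global_rad must be >= 0")
  0.5 * global_rad * (1 - exp(-k * lai))
}

#' Effective senescence thermal-time multiplier under water stress
#'
#' Water stress accelerates post-anthesis senescence: the daily thermal
#' time driving senescence is multiplied by
#' `1 + (w_ss - 1) * (1 - stress_factor)`, so an unstressed day
#' (factor 1) gets multiplier 1 and a fully stressed day (factor 0) gets
#' multiplier `w_ss`.
#'
#' @param stress_factor daily water stress factor FW in \[0, 1\].
#' @param w_ss maximum senescence acceleration (>= 1).
#' @return multiplier, vectorized.
#' @export
senescence_acceleration <- function(stress_factor, w_ss) {
  if (any(stress_factor < 0 | stress_factor > 1))
    stop("stress_factor must be in [0, 1]")
  1 + (w_ss - 1) * (1 - stress_factor)
}

# Potential green-LAI trajectory (no senescence): each leaf expands over
# one phyllochron after its appearance; leaf i appears when the Haun stage
# reaches i, i.e. at thermal time tt_em + i * P_h. Fractional final leaves
# get a proportional weight.
canopy_lai_potential <- function(ctt, tt_em, fln, p_h, a_max) {
  nl <- ceiling(fln)
  ranks <- seq_len(nl)
  pot <- potential_layer_area(ranks, fln, a_max)
  wt <- pmin(1, fln - (ranks - 1))
  app <- tt_em + ranks * p_h
  ef <- outer(ctt, app, "-") / p_h
  ef[ef < 0] <- 0
  ef[ef > 1] <- 1
  as.numeric(ef %*% (pot * wt))
}

# Senescence schedule: onset delayed past begin grain fill by the
# stay-green fraction S_G/(1+S_G) of the grain-fill thermal window; green
# fraction then falls linearly in effective senescence thermal time,
# reaching 0 no later than end of grain fill.
senescence_onset_tt <- function(tt_bgf, g_f, s_g) {
  tt_bgf + s_g / (1 + s_g) * g_f
}
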