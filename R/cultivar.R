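#' Cultivar parameter set
#'
#' Builds a validated set of the 22 cultivar parameters driving the wheat
#' simulator. Defaults are the calibration of the winter wheat cv. Claire.
#'
#' Parameters (units in brackets):
#' \describe{
#'   \item{P_h}{Phyllochron, thermal time between successive mainstem
#'     leaves (degC day).}
#'   \item{P_p}{Day length response of final leaf number
#'     (leaves per hour of day length).}
#'   \item{TT_SOWEM}{Thermal time sowing to emergence (degC day).}
#'   \item{TT_ANBGF}{Thermal time anthesis to beginning of grain fill
#'     (degC day).}
#'   \item{TT_BGFEGF}{Thermal time beginning to end of grain fill, the
#'     grain-filling duration G_f (degC day).}
#'   \item{TT_EGFMAT}{Thermal time end of grain fill to maturity (degC day).}
#'   \item{A_Max}{Maximum (flag) leaf layer area (m2 leaf m-2 soil).}
#'   \item{L_Min, L_Max}{Minimum / absolute maximum final leaf number.}
#'   \item{VAI}{Response of vernalization rate to temperature
#'     (day-1 degC-1).}
#'   \item{VBEE}{Vernalization rate at 0 degC (day-1).}
#'   \item{HSGNT}{Heat-stress grain-number reduction threshold (degC).}
#'   \item{HSGNR}{Heat-stress grain-number reduction rate (degC-1).}
#'   \item{DSGNT, DSGNS}{Drought-stress grain-number reduction threshold /
#'     saturation (on the drought stress factor scale).}
#'   \item{DSGNRMax}{Maximum drought-stress grain-number reduction.}
#'   \item{MaxGW}{Maximum potential grain weight (g).}
#'   \item{GNEar}{Grain number per g dry mass of ear (g-1).}
#'   \item{S_G}{Stay-green trait; delays post-anthesis senescence onset.}
#'   \item{R_u}{Root water uptake rate at the root bottom (\%).}
#'   \item{W_sa}{Response of photosynthesis to water stress.}
#'   \item{W_ss}{Maximum acceleration of leaf senescence under water
#'     stress.}
#' }
#'
#' @param ... named parameter overrides of the Claire defaults.
#' @return A named list of class `cultivar_params`.
#' @export
#' @examples
#' cl <- cultivar_claire()
#' hi_gf <- cultivar_claire(TT_BGFEGF = 900)
cultivar_claire <- function(...) {
  p <- list(
    P_h      = 110.0,
    P_p      = 0.50,
    TT_SOWEM = 150.0,
    TT_ANBGF = 100.0,
    TT_BGFEGF = 650.0,
    TT_EGFMAT = 200.0,
    A_Max    = 0.0070,
    L_Min    = 8.0,
    L_Max    = 18.0,
    VAI      = 0.0012,
    VBEE     = 0.012,
    HSGNT    = 30.0,
    HSGNR    = 0.04,
    DSGNT    = 0.90,
    DSGNS    = 0.30,
    DSGNRMax = 0.20,
    MaxGW    = 0.045,
    GNEar    = 100,
    S_G      = 0.50,
    R_u      = 3.0,
    W_sa     = 0.500,
    W_ss     = 1.270
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown cultivar parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_cultivar(p)
}

validate_cultivar <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p))
    if (!num1(p[[nm]])) stop("cultivar parameter '", nm, "' must be a finite number")
  pos <- setdiff(names(p), "S_G")
  for (nm in pos)
    if (p[[nm]] <= 0) stop("cultivar parameter '", nm, "' must be > 0")
  if (p$S_G < 0) stop("cultivar parameter 'S_G' must be >= 0")
  if (p$L_Min > p$L_Max) stop("L_Min must not exceed L_Max")
  if (p$DSGNS >= p$DSGNT) stop("DSGNS must be < DSGNT")
  structure(p, class = "cultivar_params")
}

#' Optimizable trait ranges for ideotype design
#'
#' The eight cultivar traits explored by the evolutionary search, with the
#' lower and upper bounds used in optimization. `G_f` is the grain-filling
#' duration and maps onto the cultivar parameter `TT_BGFEGF`.
#'
#' @return A data.frame with columns `trait`, `lower`, `upper`.
#' @export
trait_ranges <- function() {
  data.frame(
    trait = c("P_h", "P_p", "G_f", "A_Max", "S_G", "R_u", "W_sa", "W_ss"),
    lower = c(70,  0.065, 500, 0.005, 0.0, 1.0, 0.1, 1.0),
    upper = c(120, 0.900, 900, 0.010, 1.5, 5.0, 1.0, 1.7),
    stringsAsFactors = FALSE
  )
}

#' Apply an 8-trait vector to a base cultivar
#'
#' @param traits named numeric vector with entries
#'   `P_h, P_p, G_f, A_Max, S_G, R_u, W_sa, W_ss`.
#' @param base cultivar to modify (default Claire).
#' @return A `cultivar_params` object.
#' @export
cultivar_from_traits <- function(traits, base = cultivar_claire()) {
  stopifnot(is.numeric(traits))
  nm <- trait_ranges()$trait
  if (!all(nm %in% names(traits)))
    stop("traits must contain: ", paste(nm, collapse = ", "))
  base$P_h <- unname(traits[["P_h"]])
  base$P_p <- unname(traits[["P_p"]])
  base$TT_BGFEGF <- unname(traits[["G_f"]])
  base$A_Max <- unname(traits[["A_Max"]])
  base$S_G <- unname(traits[["S_G"]])
  base$R_u <- unname(traits[["R_u"]])
  base$W_sa <- unname(traits[["W_sa"]])
  base$W_ss <- unname(traits[["W_ss"]])
  validate_cultivar(unclass(base))
}

#' Extract the 8 optimizable traits from a cultivar
#' @param cultivar a `cultivar_params` object.
#' @return named numeric vector of length 8.
#' @export
traits_from_cultivar <- function(cultivar) {
  c(P_h = cultivar$P_h, P_p = cultivar$P_p, G_f = cultivar$TT_BGFEGF,
    A_Max = cultivar$A_Max, S_G = cultivar$S_G, R_u = cultivar$R_u,
    W_sa = cultivar$W_sa, W_ss = cultivar$W_ss)
}
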