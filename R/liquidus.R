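# Gas constant, J/(mol K). Fixed at the CODATA-rounded 8.314 so computed
# eutectic compositions are reproducible to the digit.
.R_GAS <- 8.314

.need_thermo <- function(phase, fun) {
  if (!inherits(phase, "crystalline_phase"))
    stop(fun, "() expects a crystalline_phase", call. = FALSE)
  if (!has_thermo_data(phase))
    stop("phase '", phase$name, "' has no melting data (t_fus/dh_fus); ",
         fun, "() cannot be evaluated", call. = FALSE)
}

#' Schroeder-van Laar liquidus: equilibrium mole fraction at a temperature
#'
#' For an ideal eutectic system the liquidus of a pure crystalline phase obeys
#' \deqn{\ln x_i = \frac{\Delta H_i}{R}\left(\frac{1}{T^f_i} -
#'   \frac{1}{T}\right),}
#' giving the mole fraction of component i in a melt saturated with solid i at
#' temperature T. At `T = t_fus` the fraction is exactly 1; above the melting
#' point the formal value exceeds 1, meaning the liquid is stable and the
#' phase cannot be the equilibrium solid. Such values are returned as-is with
#' a `liquid_stable` attribute flagging them, so callers can detect which
#' branch dominates.
#'
#' @param phase A [crystalline_phase()] with melting data.
#' @param temp Temperature(s) in kelvin, > 0.
#' @return Mole fraction(s) x, with logical attribute `liquid_stable`
#'   (`TRUE` where x > 1).
#' @seealso [svl_T_at_fraction()] for the inverse, [pd_T_at_fraction()] for
#'   the racemic-compound branch.
#' @export
svl_fraction_at_T <- function(phase, temp) {
  .need_thermo(phase, "svl_fraction_at_T")
  stopifnot(is.numeric(temp))
  if (any(temp <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  x <- exp(phase$dh_fus / .R_GAS * (1 / phase$t_fus - 1 / temp))
  attr(x, "liquid_stable") <- x > 1
  x
}

#' Schroeder-van Laar liquidus: temperature at a mole fraction
#'
#' Closed-form inversion of [svl_fraction_at_T()]:
#' \deqn{T = \left(\frac{1}{T^f_i} - \frac{R \ln x}{\Delta H_i}\right)^{-1}.}
#' Round-trips with the forward form to 1e-9 relative.
#'
#' @param phase A [crystalline_phase()] with melting data.
#' @param x Mole fraction(s) in (0, 1].
#' @return Liquidus temperature(s) in kelvin.
#' @export
svl_T_at_fraction <- function(phase, x) {
  .need_thermo(phase, "svl_T_at_fraction")
  stopifnot(is.numeric(x))
  if (any(x <= 0))
    stop("mole fraction must be in (0, 1]", call. = FALSE)
  if (any(x > 1 + 1e-12))
    stop("mole fraction must be in (0, 1]", call. = FALSE)
  denom <- 1 / phase$t_fus - .R_GAS * log(pmin(x, 1)) / phase$dh_fus
  if (any(denom <= 0))
    stop("no physical liquidus temperature for phase '", phase$name,
         "' at the requested fraction", call. = FALSE)
  1 / denom
}

#' Prigogine-Defay liquidus of a racemic compound (or double salt)
#'
#' The liquidus branch of a 1:1 crystalline addition compound RS in contact
#' with a melt of composition x_S obeys
#' \deqn{\ln\left[4 x_S (1 - x_S)\right] = \frac{\Delta H_{RS}}{R}
#'   \left(\frac{1}{T^f_{RS}} - \frac{1}{T}\right),}
#' valid between the two eutectics flanking the compound. The branch is
#' symmetric about x_S = 0.5, where it attains its maximum, the compound's own
#' melting point. Double salts of a diastereomeric salt pair are treated
#' formally by the same equation on the salt-salt pseudo-binary axis, the
#' compound counting as 0.5 A + 0.5 B.
#'
#' @param compound A [crystalline_phase()] with melting data (the 1:1
#'   addition compound).
#' @param x_S Mole fraction(s) in (0, 1), strictly: the logarithm diverges at
#'   the endpoints.
#' @return Liquidus temperature(s) in kelvin.
#' @export
pd_T_at_fraction <- function(compound, x_S) {
  .need_thermo(compound, "pd_T_at_fraction")
  stopifnot(is.numeric(x_S))
  if (any(x_S <= 0) || any(x_S >= 1))
    stop("x_S must lie strictly inside (0, 1)", call. = FALSE)
  denom <- 1 / compound$t_fus -
    .R_GAS * log(4 * x_S * (1 - x_S)) / compound$dh_fus
  if (any(denom <= 0))
    stop("no physical liquidus temperature for compound '", compound$name,
         "' at the requested fraction", call. = FALSE)
  1 / denom
}
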