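# Canopy flux derivation from raw Ecotron records: net ecosystem exchange
# from the open-chamber CO2 mass balance, and transpiration from the
# smoothed time-derivative of the lysimeter mass.

#' Net ecosystem exchange from the open-chamber mass balance
#'
#' `A_c = flow * (c_in - c_out) / area`, in umol CO2 m-2 ground s-1
#' (positive = net uptake). The balance is defined on molar air flow at the
#' chamber inlet; a volumetric flow must be converted to mol s-1 by the
#' caller before use.
#'
#' @param flow_mol_s Inlet molar air flow, mol s-1 (> 0).
#' @param c_in,c_out CO2 mole fraction at inlet/outlet, umol mol-1.
#' @param ground_area_m2 Chamber ground area, m2 (> 0; 2 m2 by default).
#' @return Canopy assimilation, umol m-2 s-1 (vectorized).
#' @export
nee_from_chamber <- function(flow_mol_s, c_in, c_out, ground_area_m2 = 2) {
  if (any(flow_mol_s <= 0)) stopf("flow_mol_s must be positive")
  if (any(ground_area_m2 <= 0)) stopf("ground_area_m2 must be positive")
  flow_mol_s * (c_in - c_out) / ground_area_m2
}

#' Transpiration from a lysimeter mass record
#'
#' Fits a penalized-spline smooth ([fit_smooth()], no AR(1) term) to
#' mass(t) and returns `E(t) = -dm/dt` (1 kg = 1 l of water), evaluated at
#' the observation times. Negative rate estimates (possible in noisy or
#' boundary regions) are floored at zero and flagged.
#'
#' @param t_h Strictly increasing time grid, hours (>= 10 points).
#' @param mass_kg Lysimeter mass, kg.
#' @param k Spline basis dimension.
#' @param at Times at which to evaluate E (default: `t_h`).
#' @return Data frame `t_h`, `e_canopy` (l h-1), `floored` (logical).
#' @export
transpiration_from_mass <- function(t_h, mass_kg, k = 20, at = t_h) {
  stopifnot(length(t_h) == length(mass_kg))
  if (length(t_h) < 10) stopf("need at least 10 mass observations")
  if (any(diff(t_h) <= 0)) stopf("t_h must be strictly increasing")
  fit <- fit_smooth(data.frame(t_h = t_h, value = mass_kg), k = k,
                    ar1 = FALSE, compute_derivative = FALSE)
  dm <- predict(fit, at, deriv = TRUE)
  e <- -dm$fit
  data.frame(t_h = at, e_canopy = pmax(e, 0), floored = e < 0)
}
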