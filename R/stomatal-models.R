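# Stomatal conductance model families (Ball-Berry, Leuning, Medlyn) with an
# optional minimal conductance g0 and an optional circadian oscillator on the
# slope g1. All functions are pure: they map drivers + parameters to gs and
# never touch data files or global state.

#' Saturation vapour pressure (Tetens)
#'
#' `esat(t) = 0.61078 * exp(17.27 t / (t + 237.3))` in kPa, used to convert
#' vapour pressure deficit to relative humidity for the Ball-Berry model.
#'
#' @param t_c Air temperature, degrees C (> -273.15).
#' @return Saturation vapour pressure, kPa.
#' @export
esat <- function(t_c) {
  stopifnot(all(t_c > -273.15))
  0.61078 * exp(17.27 * t_c / (t_c + 237.3))
}

#' Circadian oscillator parameters for the stomatal slope
#'
#' The slope g1 of a stomatal model is modulated as
#' \deqn{g_1(t) = g_{1m} + g_{1a} \sin(g_{1f} \, 2\pi t / 24 + g_{1p})}
#' with `t` in hours since experiment onset. `g1f = 1` gives a 24 h period;
#' it is conventionally held fixed at 1 when fitting.
#'
#' @param g1m Mean slope (units of the host model's g1).
#' @param g1a Amplitude (same units). Constrained to `>= 0` at fit time; the
#'   reflection `(-g1a, g1p)` is identical to `(g1a, g1p + pi)`.
#' @param g1f Dimensionless frequency multiplier (period = 24/g1f h).
#' @param g1p Phase, radians.
#' @param t_origin Time origin, hours (defaults to experiment onset = 0).
#' @return An object of class `oscillator_params`.
#' @export
oscillator_params <- function(g1m, g1a, g1f = 1, g1p = 0, t_origin = 0) {
  stopifnot(is.numeric(g1m), is.numeric(g1a), g1f > 0)
  structure(list(g1m = g1m, g1a = g1a, g1f = g1f, g1p = g1p,
                 t_origin = t_origin),
            class = "oscillator_params")
}

#' Evaluate the oscillating slope g1 at given times
#'
#' @param osc An [oscillator_params()] object.
#' @param t_h Time in hours since experiment onset (vectorized).
#' @return g1 values; periodic with period `24 / g1f` hours.
#' @export
oscillator_g1 <- function(osc, t_h) {
  stopifnot(inherits(osc, "oscillator_params"))
  osc$g1m + osc$g1a * sin(osc$g1f * 2 * pi * (t_h - osc$t_origin) / 24 + osc$g1p)
}

#' Stomatal model specification
#'
#' One of the twelve legal model variants: three families crossed with
#' presence/absence of minimal conductance g0 and of the circadian oscillator
#' on g1. The Leuning family carries two fixed constants: the CO2 compensation
#' point `gamma` and the VPD sensitivity `d0` (neither is fitted).
#'
#' @param family One of `"Med"` (Medlyn), `"Leu"` (Leuning), `"Bal"`
#'   (Ball-Berry).
#' @param g0 Include a minimal-conductance intercept?
#' @param oscillator Modulate g1 by the circadian sinusoid?
#' @param gamma Leuning CO2 compensation point, umol mol-1.
#' @param d0 Leuning VPD parameter, kPa.
#' @return An object of class `stomatal_spec`.
#' @export
stomatal_spec <- function(family = c("Med", "Leu", "Bal"), g0 = FALSE,
                          oscillator = FALSE, gamma = 50, d0 = 1.5) {
  family <- match.arg(family)
  structure(list(family = family, g0 = isTRUE(g0),
                 oscillator = isTRUE(oscillator), gamma = gamma, d0 = d0),
            class = "stomatal_spec")
}

#' @export
format.stomatal_spec <- function(x, ...) {
  paste0(x$family, if (x$g0) "+g0" else "", if (x$oscillator) "+Osc" else "")
}

#' @export
print.stomatal_spec <- function(x, ...) {
  cat("<stomatal_spec>", format(x), "\n"); invisible(x)
}

#' The full 3 x 2 x 2 model grid
#'
#' @param gamma,d0 Leuning constants passed to every Leuning spec.
#' @return Named list of 12 [stomatal_spec()] objects; names are the registry
#'   labels, e.g. `"Med"`, `"Med+g0"`, `"Med+Osc"`, `"Med+g0+Osc"`.
#' @export
model_grid <- function(gamma = 50, d0 = 1.5) {
  grid <- list()
  for (fam in c("Med", "Leu", "Bal"))
    for (g0 in c(FALSE, TRUE))
      for (osc in c(FALSE, TRUE)) {
        sp <- stomatal_spec(fam, g0 = g0, oscillator = osc,
                            gamma = gamma, d0 = d0)
        grid[[format(sp)]] <- sp
      }
  grid
}

# Decompose a model into gs = g0 + g1 * x + offset, where x and offset are
# functions of the drivers only. This linear-in-g1 structure is shared by all
# three families and is what makes the fits exact least-squares problems.
#   Med: gs = g0 + 1.6 (1 + g1/sqrt(D)) A/Ca  -> x = 1.6 A/(Ca sqrt(D)),
#        offset = 1.6 A/Ca
#   Leu: gs = g0 + g1 A / ((Ca - gamma)(1 + D/d0))
#   Bal: gs = g0 + g1 A h / Ca, h = 1 - D/esat(Tair) clipped to [0, 1]
gs_driver_terms <- function(spec, drivers) {
  a <- drivers$a_leaf; ca <- drivers$ca_umol_mol; d <- drivers$vpd_kpa
  stopifnot(all(ca > 0), all(d >= 0))
  switch(spec$family,
    Med = {
      if (any(d == 0)) stopf("Medlyn model is singular at VPD = 0 kPa")
      list(x = 1.6 * a / (ca * sqrt(d)), offset = 1.6 * a / ca)
    },
    Leu = {
      if (any(ca <= spec$gamma))
        stopf("Leuning model requires Ca > gamma (%.1f umol mol-1)", spec$gamma)
      list(x = a / ((ca - spec$gamma) * (1 + d / spec$d0)), offset = 0)
    },
    Bal = {
      h <- pmin(pmax(1 - d / esat(drivers$tair_c), 0), 1)
      list(x = a * h / ca, offset = 0)
    })
}

#' Predict stomatal conductance
#'
#' Evaluates one of the three model families at given drivers. Parameters are
#' supplied as a named list/vector: `g0` (only read when the spec includes
#' it), and either `g1` (no oscillator) or `g1m`, `g1a`, `g1p` (oscillator;
#' `g1f` defaults to 1, `t_origin` to 0).
#'
#' @param spec A [stomatal_spec()].
#' @param params Named numeric vector or list of parameters.
#' @param drivers Data frame with columns `a_leaf` (umol m-2 s-1),
#'   `ca_umol_mol`, `vpd_kpa`, `tair_c` and, for oscillator specs, `t_h`.
#' @return gs in mol m-2 s-1.
#' @export
predict_gs <- function(spec, params, drivers) {
  stopifnot(inherits(spec, "stomatal_spec"))
  params <- as.list(params)
  tr <- gs_driver_terms(spec, drivers)
  g0 <- if (spec$g0) params$g0 else 0
  if (spec$oscillator) {
    osc <- oscillator_params(params$g1m, params$g1a,
                             params$g1f %||% 1, params$g1p %||% 0,
                             params$t_origin %||% 0)
    g1 <- oscillator_g1(osc, drivers$t_h)
  } else {
    g1 <- params$g1
  }
  g0 + g1 * tr$x + tr$offset
}
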