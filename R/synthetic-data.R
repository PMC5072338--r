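# Synthetic Ecotron-style experiment generator. Emulates the measurement
# protocol of a canopy-scale circadian experiment: a multi-day entrainment
# phase with diurnal cycles of PAR, air temperature and VPD, followed by a
# free-running phase in which all drivers are frozen at their solar-noon
# values, while leaf and canopy fluxes keep oscillating with a known,
# configurable circadian structure. Every downstream stage of the analysis
# can therefore be tested against ground truth without any external data.

#' Experiment protocol settings
#'
#' Defaults reproduce the reference protocol: 5 entrainment days with the
#' diurnal pattern of a clear Mediterranean summer day (Tair 28/19 degC
#' max/min, VPD 1.7/0.5 kPa, 12 h photoperiod at PAR 500 umol m-2 s-1),
#' then 48 h of constant conditions starting at solar noon. Canopy fluxes are recorded
#' every 12 min, leaf gas exchange every 4 h, in 3 macrocosms per species.
#'
#' @param entrain_days Number of full entrainment days (>= 1).
#' @param constant_hours Duration of the constant (free-running) phase, h.
#' @param step_h Canopy sampling step, h (default 0.2 h = 12 min).
#' @param leaf_step_h Leaf sampling cadence, h (must be a multiple of
#'   `step_h`).
#' @param lights_on,lights_off Clock hours of the entrainment photoperiod.
#'   The reference protocol fixes a 12 h photoperiod; lights-on at 06:00 is
#'   a convention (solar noon = 12:00 falls mid-photoperiod).
#' @param par_max PAR when lamps are on, umol m-2 s-1.
#' @param tair_max,tair_min Air temperature extremes, degC.
#' @param vpd_max,vpd_min Vapour pressure deficit extremes, kPa.
#' @param ca_umol_mol Chamber CO2 mole fraction, umol mol-1.
#' @param n_macrocosms Replicate macrocosms per species.
#' @param ground_area_m2 Macrocosm ground area, m2.
#' @param flow_mol_s Chamber inlet molar air flow, mol s-1 (about two dome
#'   volumes per minute).
#' @param initial_mass_kg Lysimeter starting mass, kg.
#' @return A validated list of class `ecotron_protocol`.
#' @export
ecotron_protocol <- function(entrain_days = 5, constant_hours = 48,
                             step_h = 0.2, leaf_step_h = 4,
                             lights_on = 6, lights_off = 18,
                             par_max = 500, tair_max = 28, tair_min = 19,
                             vpd_max = 1.7, vpd_min = 0.5,
                             ca_umol_mol = 400, n_macrocosms = 3,
                             ground_area_m2 = 2, flow_mol_s = 13.6,
                             initial_mass_kg = 1000) {
  if (step_h <= 0) stopf("sampling step must be positive")
  if (entrain_days < 1 || constant_hours < 0)
    stopf("need entrain_days >= 1 and constant_hours >= 0")
  if (lights_off <= lights_on)
    stopf("lights_off must be after lights_on")
  structure(as.list(environment()), class = "ecotron_protocol")
}

# hour-of-day helper
hod <- function(t_h) t_h %% 24

#' Generate the environmental driver series
#'
#' Entrainment drivers follow the simplest smooth curves honouring the stated
#' extremes: Tair and VPD are cosines peaking at solar noon (12:00) with the
#' minimum at midnight; PAR is a square wave (0 / `par_max`) following the
#' photoperiod, since the plasma lamps deliver constant PAR when lit. The
#' constant phase starts at the solar noon following the last entrainment day
#' and freezes all drivers at their solar-noon values (PAR = `par_max`,
#' Tair = `tair_max`, VPD = `vpd_max`).
#'
#' @param protocol An [ecotron_protocol()].
#' @return Data frame with columns `t_h`, `par`, `tair_c`, `vpd_kpa`,
#'   `ca_umol_mol`, `phase` (`"entrainment"` / `"constant"`), and
#'   `subjective_day` (TRUE iff the hour-of-day was lit during entrainment).
#' @export
generate_environment <- function(protocol = ecotron_protocol()) {
  stopifnot(inherits(protocol, "ecotron_protocol"))
  p <- protocol
  t_const <- p$entrain_days * 24 + 12  # solar noon after the last full day
  t_end <- t_const + p$constant_hours
  t_h <- seq(0, t_end, by = p$step_h)
  if (p$constant_hours == 0) t_h <- t_h[t_h < t_const]
  const <- t_h >= t_const
  h <- hod(t_h)
  lit <- h >= p$lights_on & h < p$lights_off
  diurnal <- function(mx, mn) (mx + mn) / 2 + (mx - mn) / 2 * cos(2 * pi * (h - 12) / 24)
  env <- data.frame(
    t_h = t_h,
    par = ifelse(const, p$par_max, ifelse(lit, p$par_max, 0)),
    tair_c = ifelse(const, p$tair_max, diurnal(p$tair_max, p$tair_min)),
    vpd_kpa = ifelse(const, p$vpd_max, diurnal(p$vpd_max, p$vpd_min)),
    ca_umol_mol = p$ca_umol_mol,
    phase = ifelse(const, "constant", "entrainment"),
    subjective_day = lit
  )
  attr(env, "protocol") <- p
  attr(env, "t_const") <- t_const
  env
}

#' Ground-truth parameters for flux simulation
#'
#' Encodes the generating model for one species: a non-rectangular-hyperbola
#' light response for assimilation, multiplied by a 24 h sinusoid (relative
#' amplitude `amp_a`); stomatal conductance from the Medlyn model with the
#' circadian oscillator on g1; canopy fluxes equal the leaf-driven signal
#' with the circadian amplitude multiplied by `dilution` (shaded leaves damp
#' the canopy-integrated rhythm). Noise is additive Gaussian with AR(1)
#' correlation at the sampling step, independent per macrocosm.
#'
#' @param species Species label (e.g. `"bean"`, `"cotton"`).
#' @param amax Light-saturated assimilation scale, umol m-2 s-1.
#' @param alpha Apparent quantum yield, mol mol-1.
#' @param theta Light-response convexity (0.9).
#' @param g0 Minimal conductance, mol m-2 s-1.
#' @param osc [oscillator_params()] for g1 (Medlyn units). The default phase
#'   (7*pi/4) puts the conductance peak at ~09:00: stomatal conductance is
#'   characteristically higher in the morning than in the afternoon under
#'   equal conditions, and this morning/afternoon asymmetry is what a
#'   circadian slope adds beyond the symmetric diurnal drivers.
#' @param amp_a Relative circadian amplitude of assimilation, in [0, 1).
#' @param phase_a Assimilation phase, radians (3*pi/2 puts the peak at
#'   subjective noon).
#' @param noise_sd_leaf SD of leaf assimilation noise, umol m-2 s-1.
#' @param noise_sd_gs SD of leaf conductance noise, mol m-2 s-1.
#' @param noise_sd_canopy SD of canopy assimilation noise, umol m-2 s-1.
#' @param noise_sd_e SD of canopy transpiration noise, l h-1.
#' @param macro_sd SD of per-macrocosm additive intercepts (flux units).
#' @param ar1_rho Lag-1 autocorrelation of all noise series, in (-1, 1).
#' @param dilution Fraction in (0, 1] scaling the leaf-level circadian
#'   amplitude to canopy level.
#' @param seed Integer seed for the noise draws.
#' @return A validated list of class `true_params`.
#' @export
true_params <- function(species = "bean", amax = 20, alpha = 0.05,
                        theta = 0.9, g0 = 0.01,
                        osc = oscillator_params(g1m = 4, g1a = 1,
                                                g1p = 7 * pi / 4),
                        amp_a = 0.24, phase_a = 3 * pi / 2,
                        noise_sd_leaf = 0.5, noise_sd_gs = 0.01,
                        noise_sd_canopy = 0.3, noise_sd_e = 0.02,
                        macro_sd = 0.1, ar1_rho = 0.6,
                        dilution = 0.5, seed = 1L) {
  stopifnot(amp_a >= 0, amp_a < 1, dilution > 0, dilution <= 1,
            noise_sd_leaf >= 0, noise_sd_gs >= 0, noise_sd_canopy >= 0,
            noise_sd_e >= 0, abs(ar1_rho) < 1,
            inherits(osc, "oscillator_params"))
  structure(as.list(environment()), class = "true_params")
}

#' Default parameter sets for the two species
#'
#' Bean (LAI 7.5) receives a smaller `dilution` than cotton (LAI 4.5): a
#' denser canopy has more shaded leaves whose rhythms are not expressed at
#' the canopy scale, so the canopy-integrated circadian amplitude is damped
#' more strongly.
#'
#' @param seed Base seed; the two species get `seed` and `seed + 1`.
#' @return Named list of two [true_params()] objects.
#' @export
species_defaults <- function(seed = 1L) {
  list(
    bean = true_params(species = "bean", amax = 20, amp_a = 0.24,
                       dilution = 0.5, seed = seed),
    cotton = true_params(species = "cotton", amax = 17, amp_a = 0.27,
                         dilution = 0.7, seed = seed + 1L)
  )
}

# Non-rectangular hyperbola light response (zero at PAR = 0).
nrh_assimilation <- function(par, amax, alpha, theta) {
  s <- alpha * par + amax
  (s - sqrt(pmax(s^2 - 4 * theta * alpha * par * amax, 0))) / (2 * theta)
}

# Noiseless signal components shared by leaf and canopy series.
flux_signals <- function(env, truth, dilution = 1) {
  circ_a <- 1 + dilution * truth$amp_a * sin(2 * pi * env$t_h / 24 + truth$phase_a)
  a_pot <- nrh_assimilation(env$par, truth$amax, truth$alpha, truth$theta)
  a <- a_pot * circ_a
  osc_d <- truth$osc
  osc_d$g1a <- dilution * osc_d$g1a
  gs <- predict_gs(
    stomatal_spec("Med", g0 = TRUE, oscillator = TRUE),
    list(g0 = truth$g0, g1m = osc_d$g1m, g1a = osc_d$g1a,
         g1f = osc_d$g1f, g1p = osc_d$g1p, t_origin = osc_d$t_origin),
    data.frame(a_leaf = a, ca_umol_mol = env$ca_umol_mol,
               vpd_kpa = env$vpd_kpa, tair_c = env$tair_c, t_h = env$t_h))
  list(a = a, gs = pmax(gs, 0))
}

# mol m-2 s-1 of water vapour -> litres per hour per macrocosm:
# E = gs * D / P_atm, times ground area, 3600 s, 18 g mol-1.
transpiration_lh <- function(gs, vpd_kpa, ground_area_m2) {
  gs * (vpd_kpa / 101.325) * ground_area_m2 * 3600 * 0.018 * 1000 / 1000
}

#' Simulate leaf and canopy flux observations
#'
#' Leaf series (per macrocosm, at the leaf cadence): assimilation from the
#' light response times the circadian sinusoid, conductance from the Medlyn
#' model with oscillating g1, both plus AR(1) noise; gs is truncated at zero;
#' leaf temperature equals air temperature. Canopy series (per macrocosm, at
#' the canopy cadence): same signals with circadian amplitude scaled by
#' `truth$dilution`; transpiration converted to l h-1 per macrocosm; the
#' open-chamber raw record (inlet/outlet CO2 at constant molar flow) and the
#' lysimeter mass record are emitted alongside so the flux-derivation stage
#' can be exercised end-to-end.
#'
#' @param env Output of [generate_environment()].
#' @param truth A [true_params()] object.
#' @param protocol The [ecotron_protocol()] (defaults to the one attached to
#'   `env`).
#' @return List with data frames `leaf` (`t_h`, `species`, `macrocosm_id`,
#'   `a_leaf`, `gs`, `tleaf_c`), `canopy` (`t_h`, `species`, `macrocosm_id`,
#'   `a_canopy`, `e_canopy`, `mass_kg`), and `chamber` (`t_h`, `species`,
#'   `macrocosm_id`, `flow_mol_s`, `c_in`, `c_out`, `ground_area_m2`).
#' @export
simulate_fluxes <- function(env, truth, protocol = attr(env, "protocol")) {
  stopifnot(nrow(env) > 0, inherits(truth, "true_params"))
  p <- protocol %||% ecotron_protocol(step_h = min(diff(env$t_h)))
  set.seed(truth$seed)

  leaf_idx <- which(abs(env$t_h / p$leaf_step_h -
                          round(env$t_h / p$leaf_step_h)) < 1e-9)
  env_leaf <- env[leaf_idx, ]
  sig_leaf <- flux_signals(env_leaf, truth, dilution = 1)
  sig_can <- flux_signals(env, truth, dilution = truth$dilution)
  e_sig <- transpiration_lh(sig_can$gs, env$vpd_kpa, p$ground_area_m2)

  leaf <- do.call(rbind, lapply(seq_len(p$n_macrocosms), function(m) {
    mu <- stats::rnorm(2, sd = truth$macro_sd)
    data.frame(
      t_h = env_leaf$t_h, species = truth$species, macrocosm_id = m,
      a_leaf = sig_leaf$a + mu[1] +
        ar1_noise(nrow(env_leaf), truth$noise_sd_leaf, truth$ar1_rho),
      gs = pmax(sig_leaf$gs + mu[2] / 50 +
        ar1_noise(nrow(env_leaf), truth$noise_sd_gs, truth$ar1_rho), 0),
      tleaf_c = env_leaf$tair_c
    )
  }))

  canopy <- do.call(rbind, lapply(seq_len(p$n_macrocosms), function(m) {
    mu <- stats::rnorm(1, sd = truth$macro_sd)
    a_can <- sig_can$a + mu +
      ar1_noise(nrow(env), truth$noise_sd_canopy, truth$ar1_rho)
    e_can <- pmax(e_sig +
      ar1_noise(nrow(env), truth$noise_sd_e, truth$ar1_rho), 0)
    mass <- simulate_lysimeter(env$t_h, e_can, p$initial_mass_kg,
                               noise_sd = 0)
    data.frame(t_h = env$t_h, species = truth$species, macrocosm_id = m,
               a_canopy = a_can, e_canopy = e_can, mass_kg = mass)
  }))

  chamber <- data.frame(
    t_h = canopy$t_h, species = canopy$species,
    macrocosm_id = canopy$macrocosm_id, flow_mol_s = p$flow_mol_s,
    c_in = p$ca_umol_mol,
    c_out = p$ca_umol_mol -
      canopy$a_canopy * p$ground_area_m2 / p$flow_mol_s,
    ground_area_m2 = p$ground_area_m2
  )
  list(leaf = leaf, canopy = canopy, chamber = chamber)
}

#' Simulate a weighing-lysimeter mass record
#'
#' `mass(t) = initial_mass - \int_0^t E dt` (1 l of water = 1 kg) plus
#' optional Gaussian measurement noise; the integral is trapezoidal on the
#' given grid. Deterministic for a given seed.
#'
#' @param t_h Time grid, hours (regular).
#' @param e_canopy Transpiration series, l h-1, on the same grid.
#' @param initial_mass Starting mass, kg.
#' @param noise_sd Measurement noise SD, kg (>= 0).
#' @param seed Optional integer seed.
#' @return Mass series, kg.
#' @export
simulate_lysimeter <- function(t_h, e_canopy, initial_mass = 1000,
                               noise_sd = 0, seed = NULL) {
  stopifnot(length(t_h) == length(e_canopy))
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  n <- length(t_h)
  cum <- c(0, cumsum((e_canopy[-1] + e_canopy[-n]) / 2 * diff(t_h)))
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
  initial_mass - cum + noise
}

#' Simulate a complete two-species experiment
#'
#' @param protocol An [ecotron_protocol()].
#' @param truths Named list of [true_params()] (one per species).
#' @param seed Overrides the per-species seeds (species i gets
#'   `seed + i - 1`).
#' @return List with `env`, `leaf`, `canopy`, `chamber` data frames (species
#'   stacked) and the `protocol`/`truths` used.
#' @export
simulate_experiment <- function(protocol = ecotron_protocol(),
                                truths = species_defaults(), seed = NULL) {
  env <- generate_environment(protocol)
  if (!is.null(seed))
    for (i in seq_along(truths)) truths[[i]]$seed <- as.integer(seed) + i - 1L
  sims <- lapply(truths, function(tr) simulate_fluxes(env, tr, protocol))
  list(env = env,
       leaf = do.call(rbind, c(lapply(sims, `[[`, "leaf"),
                               make.row.names = FALSE)),
       canopy = do.call(rbind, c(lapply(sims, `[[`, "canopy"),
                                 make.row.names = FALSE)),
       chamber = do.call(rbind, c(lapply(sims, `[[`, "chamber"),
                                  make.row.names = FALSE)),
       protocol = protocol, truths = truths)
}

#' Write a simulated experiment to CSV files
#'
#' Emits `env.csv`, `leaf.csv`, `canopy.csv`, `chamber.csv` (UTF-8, '.'
#' decimal separator, headers equal to the field names). Byte-identical for
#' identical protocol + truths + seed.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in c("env", "leaf", "canopy", "chamber")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(sim[[nm]], path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    paths[nm] <- path
  }
  invisible(paths)
}
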