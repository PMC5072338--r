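# Shared fixture builders. Everything is generated in code; no data files.

# a protocol small enough for fast tests: 1 entrainment day shown + 48 h
# constant, leaf cadence 4 h, canopy cadence 12 min
small_protocol <- function(...) {
  ecotron_protocol(entrain_days = 1, constant_hours = 48, ...)
}

# fully deterministic truth (no noise, no macrocosm offsets)
noiseless_truth <- function(...) {
  args <- list(noise_sd_leaf = 0, noise_sd_gs = 0, noise_sd_canopy = 0,
               noise_sd_e = 0, macro_sd = 0)
  do.call(true_params, utils::modifyList(args, list(...)))
}

# leaf data merged with drivers for model fitting, one species
sim_leaf_data <- function(truth = true_params(), protocol = small_protocol()) {
  env <- generate_environment(protocol)
  sim <- simulate_fluxes(env, truth, protocol)
  merge_leaf_env(sim$leaf, env)
}

# hand-built smooth_fit carcass for operations that only read grid/fitted
# fields (phase_extrema, significance_segments)
fake_smooth <- function(grid_t, fitted, se = rep(0, length(grid_t)),
                        deriv = NULL, significant = NULL) {
  structure(list(model = NULL, grid_t = grid_t, fitted = fitted,
                 se_fitted = se, deriv = deriv,
                 deriv_lo95 = deriv, deriv_hi95 = deriv,
                 significant = significant,
                 data = data.frame(t_h = grid_t, value = fitted,
                                   macrocosm = factor(1)),
                 macrocosm_levels = "1", edf = NA, ar1_rho_hat = NA),
            class = "smooth_fit")
}

# minimal environment table with a constant phase starting at t0
fake_env <- function(t0 = 132, t_end = 180, step = 0.2,
                     lights_on = 6, lights_off = 18) {
  t_h <- seq(t0 - 24, t_end, by = step)
  h <- t_h %% 24
  data.frame(t_h = t_h,
             phase = ifelse(t_h >= t0, "constant", "entrainment"),
             subjective_day = h >= lights_on & h < lights_off)
}
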