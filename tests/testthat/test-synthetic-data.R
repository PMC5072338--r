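# Ecotron-like generator: protocol geometry, ground-truth structure, noise
# determinism.

test_that("environment honours the protocol and freezes drivers at noon", {
  env <- generate_environment(ecotron_protocol())
  onset <- min(env$t_h[env$phase == "constant"])
  expect_equal(onset %% 24, 12)  # constant phase starts at solar noon
  at_onset <- env[env$t_h == onset, ]
  expect_equal(at_onset$par, 500)
  expect_equal(at_onset$tair_c, 28)
  expect_equal(at_onset$vpd_kpa, 1.7)
  # any two constant-phase samples are identical in the drivers
  const <- env[env$phase == "constant", ]
  for (v in c("par", "tair_c", "vpd_kpa"))
    expect_equal(length(unique(const[[v]])), 1)
  # entrainment ranges and photoperiod
  ent <- env[env$phase == "entrainment", ]
  expect_true(all(ent$par %in% c(0, 500)))
  expect_equal(mean(ent$par > 0), 0.5, tolerance = 0.01)
  expect_true(all(ent$tair_c >= 19 - 1e-9 & ent$tair_c <= 28 + 1e-9))
  expect_true(all(ent$vpd_kpa >= 0.5 - 1e-9 & ent$vpd_kpa <= 1.7 + 1e-9))
  expect_equal(range(ent$tair_c), c(19, 28))
  # subjective day matches the lit window of entrainment
  expect_equal(env$subjective_day, env$t_h %% 24 >= 6 & env$t_h %% 24 < 18)
})

test_that("degenerate durations and invalid settings are handled", {
  env0 <- generate_environment(ecotron_protocol(constant_hours = 0))
  expect_true(all(env0$phase == "entrainment"))
  expect_error(ecotron_protocol(step_h = 0), "positive")
  expect_error(ecotron_protocol(entrain_days = 0), "entrain_days")
  expect_error(ecotron_protocol(constant_hours = -1), "constant_hours")
})

test_that("noiseless fluxes are constant without an oscillator and periodic with one", {
  protocol <- small_protocol()
  env <- generate_environment(protocol)
  # no oscillator, no assimilation rhythm -> constant-phase fluxes constant
  tr0 <- noiseless_truth(amp_a = 0, osc = oscillator_params(4, 0))
  sim0 <- simulate_fluxes(env, tr0, protocol)
  leaf_const <- merge(sim0$leaf, env[, c("t_h", "phase")], by = "t_h")
  leaf_const <- leaf_const[leaf_const$phase == "constant", ]
  expect_lt(diff(range(leaf_const$gs)), 1e-12)
  expect_lt(diff(range(leaf_const$a_leaf)), 1e-12)
  can0 <- merge(sim0$canopy, env[, c("t_h", "phase")], by = "t_h")
  expect_lt(diff(range(can0$a_canopy[can0$phase == "constant"])), 1e-12)
  # with g1f = 1, gs repeats after 24 h to machine precision
  tr1 <- noiseless_truth()
  sim1 <- simulate_fluxes(env, tr1, protocol)
  m1 <- sim1$leaf[sim1$leaf$macrocosm_id == 1, ]
  const_t <- env$t_h[env$phase == "constant"]
  t_pairs <- intersect(m1$t_h[m1$t_h %in% const_t],
                       m1$t_h[m1$t_h %in% const_t] + 24)
  expect_gt(length(t_pairs), 3)
  expect_equal(m1$gs[match(t_pairs, m1$t_h)],
               m1$gs[match(t_pairs - 24, m1$t_h)], tolerance = 1e-12)
  # assimilation is zero whenever PAR is zero
  dark_t <- env$t_h[env$par == 0]
  expect_true(all(m1$a_leaf[m1$t_h %in% dark_t] == 0))
})

test_that("canopy circadian amplitude is the leaf amplitude times dilution", {
  protocol <- small_protocol(leaf_step_h = 0.2)  # same cadence for both
  env <- generate_environment(protocol)
  tr <- noiseless_truth(amp_a = 0.3, dilution = 0.5,
                        osc = oscillator_params(4, 0))
  sim <- simulate_fluxes(env, tr, protocol)
  const_t <- env$t_h[env$phase == "constant"]
  a_l <- sim$leaf$a_leaf[sim$leaf$macrocosm_id == 1 &
                           sim$leaf$t_h %in% const_t]
  a_c <- sim$canopy$a_canopy[sim$canopy$macrocosm_id == 1 &
                               sim$canopy$t_h %in% const_t]
  expect_equal(diff(range(a_c)) / diff(range(a_l)), 0.5, tolerance = 1e-10)
})

test_that("canopy constant-phase range grows with the dilution multiplier", {
  protocol <- small_protocol()
  env <- generate_environment(protocol)
  const_t <- env$t_h[env$phase == "constant"]
  ranges <- vapply(c(0.2, 0.5, 0.8, 1.0), function(d) {
    sim <- simulate_fluxes(env, noiseless_truth(dilution = d), protocol)
    a <- sim$canopy$a_canopy[sim$canopy$macrocosm_id == 1 &
                               sim$canopy$t_h %in% const_t]
    diff(range(a))
  }, 0)
  expect_true(all(diff(ranges) > 0))
})

test_that("lysimeter mass integrates transpiration exactly and is seeded", {
  tt <- seq(0, 10, by = 0.1)
  expect_equal(simulate_lysimeter(tt, rep(0, length(tt)), 100),
               rep(100, length(tt)))
  m <- simulate_lysimeter(tt, rep(0.4, length(tt)), 100)
  expect_equal(m[1] - m[length(m)], 4.0)
  m1 <- simulate_lysimeter(tt, rep(0.4, length(tt)), 100, noise_sd = 0.05,
                           seed = 7)
  m2 <- simulate_lysimeter(tt, rep(0.4, length(tt)), 100, noise_sd = 0.05,
                           seed = 7)
  expect_identical(m1, m2)
  expect_error(simulate_lysimeter(tt, rep(0.4, length(tt)), 100,
                                  noise_sd = -1), "noise_sd")
})

test_that("identical protocol and seed give byte-identical CSV output", {
  protocol <- small_protocol()
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(simulate_experiment(protocol, seed = 99), d1)
  write_simulation(simulate_experiment(protocol, seed = 99), d2)
  for (f in c("env.csv", "leaf.csv", "canopy.csv", "chamber.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("the circadian gs amplitude is recoverable by harmonic regression", {
  # Monte Carlo: the constant-phase gs series regressed on sin/cos of a 24 h
  # harmonic recovers the (noiseless) fundamental amplitude without bias
  protocol <- small_protocol()
  env <- generate_environment(protocol)
  const <- env$phase == "constant"
  # oracle: project the noiseless signal on the same harmonics
  tr0 <- noiseless_truth()
  sim0 <- simulate_fluxes(env, tr0, protocol)
  g0 <- sim0$leaf[sim0$leaf$macrocosm_id == 1, ]
  g0 <- g0[g0$t_h %in% env$t_h[const], ]
  harm <- function(t) cbind(s = sin(2 * pi * t / 24), c = cos(2 * pi * t / 24))
  amp_of <- function(t, y) {
    cf <- coef(lm(y ~ harm(t)))
    sqrt(cf[2]^2 + cf[3]^2)
  }
  amp_true <- amp_of(g0$t_h, g0$gs)
  amps <- vapply(1:50, function(r) {
    tr <- true_params(seed = 1000L + r)
    sim <- simulate_fluxes(env, tr, protocol)
    g <- sim$leaf[sim$leaf$macrocosm_id == 1, ]
    g <- g[g$t_h %in% env$t_h[const], ]
    amp_of(g$t_h, g$gs)
  }, 0)
  expect_lt(abs(mean(amps) - amp_true), 3 * sd(amps) / sqrt(length(amps)))
})
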