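# AIC machinery, exact least-squares fitting, and the scheme runner.

test_that("AIC, delta-AIC and Akaike weights match closed forms", {
  expect_equal(aic(0, 2), 4)
  expect_equal(aic(-10, 3), 26)
  expect_equal(akaike_weights(100), 1)
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(0.73106, 0.26894), tolerance = 1e-5)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(aic(numeric(0), 1), "empty")
  expect_error(delta_aic(numeric(0)), "empty")
})

test_that("weights equal brute-force normalization of relative likelihoods", {
  set.seed(31)
  for (i in 1:20) {
    aics <- runif(sample(2:10, 1), 50, 120)
    # brute force: literal loop over models
    rel <- numeric(length(aics))
    for (j in seq_along(aics)) rel[j] <- exp(-0.5 * (aics[j] - min(aics)))
    expect_equal(akaike_weights(aics), rel / sum(rel), tolerance = 1e-12)
    d <- delta_aic(aics)
    expect_true(all(d >= 0))
    expect_equal(sum(d == 0), sum(aics == min(aics)))
  }
})

test_that("noiseless Medlyn data is recovered to numerical precision", {
  set.seed(41)
  drv <- data.frame(a_leaf = runif(40, 2, 20), ca_umol_mol = 400,
                    vpd_kpa = runif(40, 0.4, 2), tair_c = 25,
                    t_h = seq(0, 78, by = 2))
  spec <- stomatal_spec("Med", g0 = TRUE)
  drv$gs <- predict_gs(spec, list(g0 = 0.01, g1 = 4), drv)
  fit <- suppressWarnings(fit_spec(spec, drv))
  expect_equal(unname(fit$estimates["g0"]), 0.01, tolerance = 1e-6)
  expect_equal(unname(fit$estimates["g1"]), 4, tolerance = 1e-6)
  # refitting identical data is deterministic
  fit2 <- suppressWarnings(fit_spec(spec, drv))
  expect_identical(fit$estimates, fit2$estimates)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("oscillator parameters are recovered and the reflection is resolved", {
  drv <- data.frame(a_leaf = rep(15, 72), ca_umol_mol = 400, vpd_kpa = 1.7,
                    tair_c = 28, t_h = seq(0, 71, by = 1))
  spec <- stomatal_spec("Med", oscillator = TRUE)
  for (g1p_true in c(0.5, 2.0, 4.5)) {
    drv$gs <- predict_gs(spec, list(g1m = 4, g1a = 0.8, g1p = g1p_true), drv)
    fit <- suppressWarnings(fit_spec(spec, drv, g1m_source = 4))
    expect_equal(unname(fit$estimates["g1a"]), 0.8, tolerance = 1e-8)
    expect_equal(unname(fit$estimates["g1p"]), g1p_true, tolerance = 1e-8)
    expect_gte(unname(fit$estimates["g1a"]), 0)
    expect_true(fit$estimates["g1p"] >= 0 && fit$estimates["g1p"] < 2 * pi)
  }
})

test_that("under a null oscillator the estimated amplitude is calibrated", {
  # With g1a = 0 truth, (a, b) are bivariate normal around zero, so
  # g1a_hat/SE is approximately Rayleigh(1): P(<= 2) = 1 - exp(-2) = 0.865,
  # P(<= 2.45) = 0.95. Check both empirical proportions with binomial slack
  # (3 sigma at 50 replicates), and that the amplitude is small in absolute
  # terms relative to the mean slope.
  set.seed(53)
  env <- generate_environment(small_protocol())
  ratio <- vapply(1:50, function(r) {
    tr <- true_params(osc = oscillator_params(4, 0), ar1_rho = 0,
                      seed = 2000L + r)
    sim <- simulate_fluxes(env, tr, small_protocol())
    d <- merge_leaf_env(sim$leaf, env)
    base <- fit_spec(stomatal_spec("Med", g0 = TRUE), d)
    fit <- fit_spec(stomatal_spec("Med", g0 = TRUE, oscillator = TRUE), d,
                    g1m_source = base)
    unname(fit$estimates["g1a"] / fit$se["g1a"])
  }, 0)
  expect_gt(mean(ratio <= 2), 0.865 - 3 * sqrt(0.865 * 0.135 / 50))
  expect_gt(mean(ratio <= 2.45), 0.95 - 3 * sqrt(0.95 * 0.05 / 50))
})

test_that("the oscillator fit never has a worse likelihood than its base model", {
  # exact nesting: the base model is the oscillator model at a = b = 0
  set.seed(61)
  env <- generate_environment(small_protocol())
  for (r in 1:5) {
    tr <- true_params(seed = 3000L + r)
    sim <- simulate_fluxes(env, tr, small_protocol())
    d <- merge_leaf_env(sim$leaf, env)
    for (fam in c("Med", "Leu", "Bal")) for (g0 in c(FALSE, TRUE)) {
      base <- fit_spec(stomatal_spec(fam, g0 = g0), d)
      osc <- fit_spec(stomatal_spec(fam, g0 = g0, oscillator = TRUE), d,
                      g1m_source = base)
      expect_gte(osc$loglik, base$loglik - 1e-8)
    }
  }
})

test_that("noiseless null data leaves nothing for the oscillator to absorb", {
  set.seed(71)
  drv <- data.frame(a_leaf = runif(40, 2, 20), ca_umol_mol = 400,
                    vpd_kpa = runif(40, 0.4, 2), tair_c = 25,
                    t_h = seq(0, 78, by = 2))
  drv$gs <- predict_gs(stomatal_spec("Med"), list(g1 = 4), drv)
  base <- suppressWarnings(fit_spec(stomatal_spec("Med"), drv))
  osc <- suppressWarnings(
    fit_spec(stomatal_spec("Med", oscillator = TRUE), drv,
             g1m_source = base))
  expect_lt(osc$sse, 1e-20)
  expect_lt(base$sse, 1e-20)
  expect_lt(unname(osc$estimates["g1a"]), 1e-10)
})

test_that("validation R2 is the squared correlation of observed vs predicted", {
  obs <- c(1, 3, 2, 5, 4, 6)
  expect_equal(validation_r2(obs, obs), 1)
  expect_equal(validation_r2(obs, 2 * obs + 3), 1)
  expect_warning(r <- validation_r2(obs, rep(2, 6)), "zero variance")
  expect_true(is.nan(r))
})

test_that("run_scheme fits per species, pools validation, and ranks by AIC", {
  env <- generate_environment(small_protocol())
  sims <- lapply(list(noiseless_truth(species = "bean"),
                      noiseless_truth(species = "cotton", amax = 17)),
                 function(tr) simulate_fluxes(env, tr, small_protocol()))
  leaf <- do.call(rbind, lapply(sims, `[[`, "leaf"))
  d <- merge_leaf_env(leaf, env)
  rep <- run_scheme("cha_con", d)
  tab <- rep$table
  expect_equal(nrow(tab), 12)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_true(all(tab$delta_aic >= 0))
  expect_equal(sum(tab$delta_aic == 0), 1)
  expect_equal(tab$aic, -2 * tab$loglik + 2 * tab$p)
  # the generating model family predicts noiseless validation data almost
  # perfectly (not exactly: g1m is inherited from the non-oscillator fit,
  # which absorbs part of the oscillation, so the refit is near- but not
  # fully exact)
  expect_gt(tab$r2_validation[tab$model == "Med+g0+Osc"], 0.95)
  # per-species fits exist for both species
  expect_setequal(names(rep$fits), c("bean", "cotton"))
  # an empty window is a named error
  d_ent <- d[d$phase == "entrainment", ]
  expect_error(run_scheme("cha_con", d_ent), "Cha")
})
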