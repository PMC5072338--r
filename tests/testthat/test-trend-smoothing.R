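# Penalized-spline smoothing, derivatives, and significance segmentation.

test_that("a constant series yields a constant smooth with no significant trend", {
  f <- suppressWarnings(
    fit_smooth(data.frame(t_h = seq(0, 72, by = 0.5), value = 7.3), k = 10))
  expect_lt(max(abs(f$fitted - 7.3)), 1e-8)
  expect_equal(f$edf, 1, tolerance = 0.2)
  expect_false(any(f$significant))
  expect_equal(nrow(significance_segments(f)), 0)
})

test_that("a noiseless sinusoid at canopy cadence is recovered within 1% of amplitude", {
  tt <- seq(0, 72, by = 0.2)
  truthf <- function(t) 10 + 3 * sin(2 * pi * t / 24)
  f <- fit_smooth(data.frame(t_h = tt, value = truthf(tt)), k = 20,
                  ar1 = FALSE)
  expect_lt(max(abs(f$fitted - truthf(f$grid_t))) / 3, 0.01)
})

test_that("the derivative of an exactly linear series is its slope", {
  tt <- seq(0, 72, by = 0.5)
  f <- suppressWarnings(
    fit_smooth(data.frame(t_h = tt, value = 2 + 0.31 * tt), k = 10))
  expect_lt(max(abs(f$deriv - 0.31)), 1e-8)
})

test_that("macrocosm offsets shift intercepts but not the smooth's shape", {
  tt <- seq(0, 72, by = 1)
  set.seed(5)
  base <- 10 + 3 * sin(2 * pi * tt / 24) + rnorm(length(tt), 0, 0.3)
  delta <- 1.7
  d <- rbind(data.frame(t_h = tt, value = base, macrocosm_id = 1),
             data.frame(t_h = tt, value = base + delta, macrocosm_id = 2))
  f <- fit_smooth(d, k = 15, ar1 = FALSE)
  ints <- f$macrocosm_intercepts
  expect_equal(unname(ints[grep("macrocosm", names(ints))]), delta,
               tolerance = 1e-6)
  # derivative identical to the single-macrocosm fit of the same signal
  f1 <- fit_smooth(data.frame(t_h = tt, value = base, macrocosm_id = 1),
                   k = 15, ar1 = FALSE)
  expect_equal(f$deriv, f1$deriv, tolerance = 0.02 * max(abs(f1$deriv)))
})

test_that("the penalized fit solves the generalized ridge problem", {
  # oracle: at the selected smoothing parameter, coefficients must equal the
  # direct solve of (X'X + lambda S) beta = X'y
  set.seed(3)
  tt <- sort(runif(40, 0, 10))
  y <- sin(tt) + rnorm(40, 0, 0.2)
  f <- fit_smooth(data.frame(t_h = tt, value = y), k = 8, ar1 = FALSE,
                  compute_derivative = FALSE)
  m <- f$model
  X <- predict(m, newdata = data.frame(t_h = tt, macrocosm = factor(1)),
               type = "lpmatrix")
  S <- matrix(0, ncol(X), ncol(X))
  idx <- m$smooth[[1]]$first.para:m$smooth[[1]]$last.para
  S[idx, idx] <- m$smooth[[1]]$S[[1]]
  beta_ridge <- solve(crossprod(X) + m$sp[1] * S, crossprod(X, y))
  expect_lt(max(abs(beta_ridge - coef(m))), 1e-8)
})

test_that("high-SNR sinusoid: significance covers the cycle except near extrema", {
  tt <- seq(0, 72, by = 0.2)
  set.seed(9)
  y <- 10 + 3 * sin(2 * pi * tt / 24) + rnorm(length(tt), 0, 0.15)
  f <- fit_smooth(data.frame(t_h = tt, value = y), k = 20, ar1 = FALSE)
  expect_gt(mean(f$significant), 0.6)
  # derivative CI must include zero at the analytic extrema (t = 6 + 12k)
  extrema <- seq(6, 66, by = 12)
  nearest <- vapply(extrema, function(e) which.min(abs(f$grid_t - e)), 1L)
  expect_true(all(!f$significant[nearest]))
  seg <- significance_segments(f)
  expect_true(all(seg$direction %in% c("increasing", "decreasing")))
  # consecutive segments alternate direction around each extremum
  expect_true(all(seg$direction[-1] != seg$direction[-nrow(seg)]))
})

test_that("significance segmentation follows the mask", {
  g <- seq(0, 10, length.out = 11)
  # all-false mask -> no segments
  f0 <- fake_smooth(g, rep(0, 11), deriv = rep(0, 11),
                    significant = rep(FALSE, 11))
  expect_equal(nrow(significance_segments(f0)), 0)
  # one contiguous significant block with matching endpoints
  mask <- g >= 3 & g <= 6
  f1 <- fake_smooth(g, g, deriv = rep(1, 11), significant = mask)
  seg <- significance_segments(f1)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$t_start, seg$t_end), c(3, 6))
  expect_equal(seg$direction, "increasing")
})

test_that("AR(1) residual correlation is estimated by the plug-in refit", {
  set.seed(17)
  tt <- seq(0, 72, by = 0.25)
  y <- 5 + as.numeric(arima.sim(list(ar = 0.7), length(tt))) * 0.5
  f <- fit_smooth(data.frame(t_h = tt, value = y), k = 20, ar1 = TRUE)
  expect_gt(f$ar1_rho_hat, 0.3)
  f_no <- fit_smooth(data.frame(t_h = tt, value = y), k = 20, ar1 = FALSE)
  expect_true(is.na(f_no$ar1_rho_hat))
})

test_that("smoothing rejects malformed input", {
  expect_error(fit_smooth(data.frame(t_h = 1:5, value = 1:5), k = 10),
               "k \\+ 3|too few")
  f <- fit_smooth(data.frame(t_h = seq(0, 72, 0.5),
                             value = sin(seq(0, 72, 0.5))), k = 10)
  expect_error(derivative_with_ci(f, eps = 0), "eps")
})
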