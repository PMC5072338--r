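# Fitting the stomatal model grid and ranking it by AIC / Akaike weights.
#
# All twelve model variants are linear in their free parameters once the
# oscillator sinusoid is expanded:
#   g1a sin(2 pi t/24 + g1p) * x = a (x sin th) + b (x cos th),
#   a = g1a cos g1p, b = g1a sin g1p,
# so every fit is an exact ordinary least-squares problem (the global
# Gaussian MLE) and no iterative optimizer, multi-start or convergence
# tolerance is needed. g1a = sqrt(a^2 + b^2) >= 0 and g1p = atan2(b, a)
# mod 2 pi resolve the sign/phase reflection symmetry; standard errors
# follow by the delta method. Oscillator variants inherit g1m from the
# corresponding non-oscillator fit (same family, same g0 option) and keep
# the frequency fixed at one cycle per 24 h; g0, when present, is
# re-estimated.

#' Fit one stomatal model specification
#'
#' Minimizes the Gaussian negative log-likelihood (equivalently the SSE) of
#' observed gs against [predict_gs()]. The log-likelihood is evaluated at
#' the MLE with `sigma^2 = SSE/n`. The structural parameter count `p`
#' excludes `sigma` (a constant offset common to all models, so AIC
#' differences are unaffected).
#'
#' @param spec A [stomatal_spec()].
#' @param data Data frame with `gs` plus the driver columns of
#'   [predict_gs()] (`a_leaf`, `ca_umol_mol`, `vpd_kpa`, `tair_c`, `t_h`).
#' @param g1m_source For oscillator specs: the fitted non-oscillator model
#'   of the same family/g0 option (a `gs_fit`), or a numeric g1 value, from
#'   which the fixed mean slope g1m is taken.
#' @return An object of class `gs_fit`: `spec`, `estimates`, `se`, `loglik`,
#'   `p`, `aic`, `sse`, `n`, `g1m` (oscillator specs only).
#' @export
fit_spec <- function(spec, data, g1m_source = NULL) {
  stopifnot(inherits(spec, "stomatal_spec"), is.data.frame(data))
  n <- nrow(data)
  tr <- gs_driver_terms(spec, data)
  p_struct <- as.integer(spec$g0) + (if (spec$oscillator) 2L else 1L)
  if (n < p_struct + 2) stopf("need at least p + 2 = %d points", p_struct + 2)

  if (!spec$oscillator) {
    y <- data$gs - tr$offset
    fm <- if (spec$g0) stats::lm(y ~ x, data = data.frame(y = y, x = tr$x))
          else stats::lm(y ~ x - 1, data = data.frame(y = y, x = tr$x))
    cf <- stats::coef(fm); se <- sqrt(diag(stats::vcov(fm)))
    est <- if (spec$g0) c(g0 = unname(cf[1]), g1 = unname(cf[2]))
           else c(g1 = unname(cf[1]))
    ses <- if (spec$g0) c(g0 = unname(se[1]), g1 = unname(se[2]))
           else c(g1 = unname(se[1]))
    extra <- list()
  } else {
    if (is.null(g1m_source))
      stopf("oscillator specs need g1m_source (non-oscillator fit or value)")
    g1m <- if (inherits(g1m_source, "gs_fit")) {
      unname(g1m_source$estimates["g1"])
    } else as.numeric(g1m_source)
    th <- 2 * pi * data$t_h / 24
    u <- tr$x * sin(th); v <- tr$x * cos(th)
    y <- data$gs - tr$offset - g1m * tr$x
    dd <- data.frame(y = y, u = u, v = v)
    fm <- if (spec$g0) stats::lm(y ~ u + v, data = dd)
          else stats::lm(y ~ u + v - 1, data = dd)
    cf <- stats::coef(fm); V <- stats::vcov(fm)
    i <- if (spec$g0) 2:3 else 1:2
    a <- unname(cf[i[1]]); b <- unname(cf[i[2]])
    g1a <- sqrt(a^2 + b^2)
    g1p <- atan2(b, a) %% (2 * pi)
    # delta method: grad(g1a) = (a, b)/g1a ; grad(g1p) = (-b, a)/g1a^2
    Vab <- V[i, i]
    se_g1a <- if (g1a > 0) sqrt(drop(t(c(a, b) / g1a) %*% Vab %*% (c(a, b) / g1a)))
              else sqrt(mean(diag(Vab)))
    se_g1p <- if (g1a > 0) sqrt(drop(t(c(-b, a) / g1a^2) %*% Vab %*% (c(-b, a) / g1a^2)))
              else Inf
    est <- c(if (spec$g0) c(g0 = unname(cf[1])), g1a = g1a, g1p = g1p)
    ses <- c(if (spec$g0) c(g0 = sqrt(V[1, 1])), g1a = se_g1a, g1p = se_g1p)
    extra <- list(g1m = g1m)
  }

  sse <- sum(stats::resid(fm)^2)
  ll <- -0.5 * n * (log(2 * pi * sse / n) + 1)
  out <- c(list(spec = spec, estimates = est, se = ses, loglik = ll,
                p = p_struct, aic = aic(ll, p_struct), sse = sse, n = n,
                converged = TRUE), extra)
  structure(out, class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("<gs_fit>", format(x$spec), sprintf("| n = %d | AIC = %.2f\n", x$n, x$aic))
  print(round(rbind(estimate = x$estimates, se = x$se), 5))
  invisible(x)
}

#' Predict gs from a fitted model
#'
#' @param object A `gs_fit`.
#' @param newdata Driver data frame (see [predict_gs()]).
#' @param ... Unused.
#' @return Predicted gs, mol m-2 s-1.
#' @export
predict.gs_fit <- function(object, newdata, ...) {
  pars <- as.list(object$estimates)
  if (object$spec$oscillator) pars$g1m <- object$g1m
  predict_gs(object$spec, pars, newdata)
}

#' Akaike information criterion
#'
#' `AIC = -2 L(MLE) + 2 p`.
#'
#' @param loglik Maximized log-likelihood(s).
#' @param p Parameter count(s).
#' @return AIC value(s).
#' @export
aic <- function(loglik, p) {
  if (length(loglik) == 0) stopf("empty input")
  -2 * loglik + 2 * p
}

#' AIC differences to the best model
#'
#' @param aics AIC values of a compared model set.
#' @return `aics - min(aics)`; non-negative with at least one zero.
#' @export
delta_aic <- function(aics) {
  if (length(aics) == 0) stopf("empty input")
  aics - min(aics)
}

#' Akaike weights
#'
#' The conditional probability of each model within the compared set: the
#' relative likelihood `exp(-0.5 dAIC)` normalized to sum to one.
#'
#' @param aics AIC values of a compared model set.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  rl <- exp(-0.5 * delta_aic(aics))
  rl / sum(rl)
}

#' Validation R-squared
#'
#' Squared Pearson correlation of the observed-versus-predicted regression
#' (invariant to scale and offset of the predictions).
#'
#' @param observed,predicted Numeric vectors (>= 3 pairs).
#' @return R2 in [0, 1]; `NaN` with a warning if either vector has zero
#'   variance.
#' @export
validation_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("zero variance in observed or predicted values; R2 undefined")
    return(NaN)
  }
  stats::cor(observed, predicted)^2
}

#' Calibration/validation split schemes
#'
#' The three runs: calibrate and validate on the entire set (`"all"`);
#' calibrate under changing (entrainment) conditions, validate under
#' constant (`"cha_con"`); and the reverse (`"con_cha"`).
#'
#' @param name One of `"all"`, `"cha_con"`, `"con_cha"`.
#' @return List of class `split_scheme` with `name`, `label`, `calibration`
#'   and `validation` phase selectors.
#' @export
split_scheme <- function(name = c("all", "cha_con", "con_cha")) {
  name <- match.arg(name)
  win <- switch(name,
    all = list(cal = c("entrainment", "constant"),
               val = c("entrainment", "constant"), label = "All→All"),
    cha_con = list(cal = "entrainment", val = "constant",
                   label = "Cha→Con"),
    con_cha = list(cal = "constant", val = "entrainment",
                   label = "Con→Cha"))
  structure(list(name = name, label = win$label, calibration = win$cal,
                 validation = win$val), class = "split_scheme")
}

#' Attach environmental drivers and phase labels to leaf observations
#'
#' @param leaf Leaf observations (`t_h`, `species`, `macrocosm_id`,
#'   `a_leaf`, `gs`).
#' @param env Environment table from [generate_environment()].
#' @return Leaf data merged with `vpd_kpa`, `tair_c`, `ca_umol_mol`,
#'   `phase`, `subjective_day`.
#' @export
merge_leaf_env <- function(leaf, env) {
  m <- merge(leaf, env[, c("t_h", "vpd_kpa", "tair_c", "ca_umol_mol",
                           "phase", "subjective_day")],
             by = "t_h", sort = FALSE)
  m[order(m$species, m$macrocosm_id, m$t_h), ]
}

#' Fit and rank the model grid under one calibration/validation scheme
#'
#' Fits every specification independently per species on the calibration
#' window (oscillator specs inherit g1m from the corresponding
#' non-oscillator fit on the same window), predicts the validation window,
#' pools species for the validation R2, and ranks specs by AIC
#' (log-likelihoods and parameter counts summed over species) with delta-AIC
#' and Akaike weights computed within the scheme.
#'
#' @param scheme A [split_scheme()] or its name.
#' @param leaf_data Output of [merge_leaf_env()] (must contain `gs`,
#'   drivers, `species`, `phase`).
#' @param grid Model grid (default [model_grid()]).
#' @return Object of class `scheme_report`: `table` (one row per spec:
#'   `model`, `family`, `g0`, `oscillator`, `loglik`, `p`, `aic`,
#'   `delta_aic`, `weight`, `r2_validation`), `fits` (per species), and the
#'   `scheme`.
#' @export
run_scheme <- function(scheme, leaf_data, grid = model_grid()) {
  if (is.character(scheme)) scheme <- split_scheme(scheme)
  stopifnot(inherits(scheme, "split_scheme"))
  species <- unique(leaf_data$species)
  cal_all <- leaf_data[leaf_data$phase %in% scheme$calibration, ]
  val_all <- leaf_data[leaf_data$phase %in% scheme$validation, ]
  if (nrow(cal_all) == 0 || nrow(val_all) == 0)
    stopf("scheme '%s' selects an empty calibration or validation window",
          scheme$label)

  fits <- lapply(species, function(sp) {
    cal <- cal_all[cal_all$species == sp, ]
    sp_fits <- list()
    for (nm in names(grid)) {
      g <- grid[[nm]]
      src <- if (g$oscillator) {
        base_nm <- paste0(g$family, if (g$g0) "+g0")
        sp_fits[[base_nm]]
      }
      sp_fits[[nm]] <- fit_spec(g, cal, g1m_source = src)
    }
    sp_fits
  })
  names(fits) <- species

  rows <- lapply(names(grid), function(nm) {
    ll <- sum(vapply(species, function(sp) fits[[sp]][[nm]]$loglik, 0))
    p <- sum(vapply(species, function(sp) fits[[sp]][[nm]]$p, 0L))
    obs <- numeric(); pred <- numeric()
    for (sp in species) {
      val <- val_all[val_all$species == sp, ]
      obs <- c(obs, val$gs)
      pred <- c(pred, predict(fits[[sp]][[nm]], val))
    }
    g <- grid[[nm]]
    data.frame(model = nm, family = g$family, g0 = g$g0,
               oscillator = g$oscillator, loglik = ll, p = p,
               aic = aic(ll, p),
               r2_validation = validation_r2(obs, pred))
  })
  tab <- do.call(rbind, rows)
  tab$delta_aic <- delta_aic(tab$aic)
  tab$weight <- akaike_weights(tab$aic)
  tab <- tab[order(tab$delta_aic), ]
  rownames(tab) <- NULL
  structure(list(scheme = scheme, table = tab, fits = fits),
            class = "scheme_report")
}

#' @export
print.scheme_report <- function(x, ...) {
  cat("<scheme_report>", x$scheme$label, "\n")
  tab <- x$table
  tab$loglik <- round(tab$loglik, 2); tab$aic <- round(tab$aic, 2)
  tab$delta_aic <- round(tab$delta_aic, 2)
  tab$weight <- round(tab$weight, 4)
  tab$r2_validation <- round(tab$r2_validation, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
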