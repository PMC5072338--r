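# Quantification of clock-driven variation: flux ranges under entrainment
# versus constant conditions, taken from the extrema of the fitted smooth
# (not the raw data), with the zero-floor convention for the entrainment
# minimum and an optional recomputation restricted to the subjective day.

#' Phase windows of an experiment
#'
#' Derives the analysis windows from the environment table: the entrainment
#' window is the final 24 h before constant onset (the diurnal cycle shown
#' alongside the free-running phase), the constant window runs from onset to
#' the end, and the subjective-day intervals are the constant-phase hours
#' that were lit during entrainment.
#'
#' @param env Output of [generate_environment()] (or any table with `t_h`,
#'   `phase`, `subjective_day`).
#' @return List with `entrain = c(start, end)`, `constant = c(start, end)`
#'   and `subjective_day`, a 2-column matrix of intervals.
#' @export
env_windows <- function(env) {
  if (!any(env$phase == "constant"))
    stopf("environment has no constant phase")
  t0 <- min(env$t_h[env$phase == "constant"])
  t_end <- max(env$t_h)
  const <- env[env$phase == "constant", ]
  sd_rle <- rle(const$subjective_day)
  ends <- cumsum(sd_rle$lengths); starts <- ends - sd_rle$lengths + 1
  keep <- sd_rle$values
  subj <- cbind(start = const$t_h[starts[keep]], end = const$t_h[ends[keep]])
  list(entrain = c(t0 - 24, t0), constant = c(t0, t_end),
       subjective_day = subj)
}

# logical grid mask for a window given as c(start,end) or an interval matrix
window_mask <- function(grid_t, window) {
  if (is.matrix(window)) {
    Reduce(`|`, lapply(seq_len(nrow(window)), function(i)
      grid_t >= window[i, 1] & grid_t <= window[i, 2]))
  } else {
    grid_t >= window[1] & grid_t <= window[2]
  }
}

#' Extrema of a fitted smooth over a window
#'
#' Maximum and minimum of the GAMM-predicted curve (grid resolution as set
#' in [fit_smooth()]), with the fitted-value standard errors at the argmax
#' and argmin. Negative fitted values can be cropped at zero first
#' (assimilation and conductance are non-negative quantities; negative
#' dark-time estimates lack biological meaning).
#'
#' @param fit A `smooth_fit`.
#' @param window `c(start, end)` in hours, or a 2-column matrix of intervals
#'   (the union is used).
#' @param crop_zero Floor the fitted curve at 0 before taking extrema?
#' @return List `max`, `min`, `se_max`, `se_min`, `t_max`, `t_min`.
#' @export
phase_extrema <- function(fit, window, crop_zero = FALSE) {
  stopifnot(inherits(fit, "smooth_fit"))
  m <- window_mask(fit$grid_t, window)
  if (!any(m)) stopf("window is disjoint from the fitted grid")
  f <- fit$fitted[m]
  if (crop_zero) f <- pmax(f, 0)
  se <- fit$se_fitted[m]; tt <- fit$grid_t[m]
  i_max <- which.max(f); i_min <- which.min(f)
  list(max = f[i_max], min = f[i_min],
       se_max = se[i_max], se_min = se[i_min],
       t_max = tt[i_max], t_min = tt[i_min])
}

#' Percent clock-driven variation
#'
#' `100 * range_const / range_entrain`, reported to two decimals (half-up).
#' With the zero floor on (the convention for assimilation, which is zero in
#' the dark, and for conductance/transpiration, whose nocturnal values are
#' forced to zero for this calculation), the entrainment range is
#' `max_entrain - 0`; this enlarges the denominator and so under-estimates
#' the clock share whenever the true entrainment minimum is above zero.
#'
#' @param range_const Fitted range under constant conditions.
#' @param max_entrain Fitted maximum under entrainment.
#' @param min_entrain Fitted minimum under entrainment (ignored when
#'   flooring).
#' @param floor_entrain_min_to_zero Apply the zero-floor rule?
#' @return Percentage, rounded to 2 decimals.
#' @export
clock_percentage <- function(range_const, max_entrain, min_entrain = 0,
                             floor_entrain_min_to_zero = TRUE) {
  range_entrain <- if (floor_entrain_min_to_zero) max_entrain
                   else max_entrain - min_entrain
  if (range_entrain <= 0) stopf("entrainment range must be positive")
  round_half_up(100 * range_const / range_entrain, 2)
}

#' Range summary for one flux series
#'
#' Applies [phase_extrema()] to the entrainment and constant windows and
#' computes the percent clock-driven variation under the zero-floor rule.
#'
#' @param fit A `smooth_fit` of the flux over the displayed window
#'   (final entrainment day + constant phase).
#' @param env Environment table covering the fit.
#' @param process,species,scale Labels copied into the output row.
#' @param floor_entrain_min_to_zero Zero-floor the entrainment minimum?
#' @param crop_zero Crop negative fitted values before extrema?
#' @return One-row data frame: labels, `max_entrain`, `min_entrain`,
#'   `range_entrain`, `max_const`, `min_const`, `range_const`, `pct_clock`.
#' @export
clock_range_summary <- function(fit, env, process = "carbon_assimilation",
                                species = "bean", scale = "leaf",
                                floor_entrain_min_to_zero = TRUE,
                                crop_zero = TRUE) {
  w <- env_windows(env)
  ex_e <- phase_extrema(fit, w$entrain, crop_zero = crop_zero)
  ex_c <- phase_extrema(fit, w$constant, crop_zero = crop_zero)
  min_e <- if (floor_entrain_min_to_zero) 0 else ex_e$min
  data.frame(
    process = process, species = species, scale = scale,
    max_entrain = ex_e$max, min_entrain = min_e,
    range_entrain = ex_e$max - min_e,
    max_const = ex_c$max, min_const = ex_c$min,
    range_const = ex_c$max - ex_c$min,
    pct_clock = clock_percentage(ex_c$max - ex_c$min, ex_e$max, ex_e$min,
                                 floor_entrain_min_to_zero)
  )
}

#' Clock share recomputed over the subjective day only
#'
#' Quantifying the clock share over the full 24 h free-running cycle can
#' overstate its daytime relevance: no canopy assimilation occurs at night,
#' and transpiration is lower in a real night than in the subjective night.
#' This restricts the constant-phase extrema to the subjective-day grid
#' points (the hours that were lit during entrainment) before forming the
#' ratio; the entrainment denominator is unchanged.
#'
#' @param fit A `smooth_fit` covering entrainment and constant windows.
#' @param env Environment table covering the fit.
#' @param floor_entrain_min_to_zero,crop_zero As in [clock_range_summary()].
#' @return Percentage, rounded to 2 decimals.
#' @export
subjective_day_percentage <- function(fit, env,
                                      floor_entrain_min_to_zero = TRUE,
                                      crop_zero = TRUE) {
  w <- env_windows(env)
  if (nrow(w$subjective_day) == 0) stopf("empty subjective-day window")
  ex_e <- phase_extrema(fit, w$entrain, crop_zero = crop_zero)
  ex_s <- phase_extrema(fit, w$subjective_day, crop_zero = crop_zero)
  clock_percentage(ex_s$max - ex_s$min, ex_e$max, ex_e$min,
                   floor_entrain_min_to_zero)
}
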