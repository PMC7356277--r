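# Thermal time, Beta canopy dynamics and cumulative radiation interception.
#
# Canopy cover is modelled on thermal time t (degree-days above a base
# temperature) with the determinate Beta growth form up to its peak
#
#   cc(t) = cc_max * (1 + (te - t)/(te - tm)) * (t/te)^(te/(te - tm)),  t <= te
#
# where tm is the thermal time of maximum growth rate and te the thermal time
# at peak cover, followed by a linear senescent decline
#
#   cc(t) = cc_max + decline_slope * (t - te),  t > te,  clipped to [0, 1].
#
# The cover curve doubles as the fraction f of incident PAR intercepted by the
# canopy, from which cumulative intercepted PAR and the interception
# efficiency epsilon_i = 100 * PARint / PARinc are integrated daily.

#' Beta canopy-dynamics parameters
#'
#' @param cc_max peak canopy-cover fraction, in `(0, 1]`.
#' @param tm thermal time of maximum canopy growth rate, degree-days; `0 < tm < te`.
#' @param te thermal time at peak cover, degree-days.
#' @param decline_slope post-peak linear senescence slope, cover per
#'   degree-day, `<= 0`.
#' @return an object of class `beta_params`.
#' @export
#' @examples
#' p <- beta_params(0.9, 500, 900, -4e-4)
#' beta_canopy_cover(c(0, 500, 900), p)
beta_params <- function(cc_max, tm, te, decline_slope = 0) {
  assert_that(is_number(cc_max) && cc_max > 0 && cc_max <= 1,
              "cc_max must lie in (0, 1]")
  assert_that(is_number(tm) && is_number(te) && tm > 0 && tm < te,
              "need 0 < tm < te")
  assert_that(is_number(decline_slope) && decline_slope <= 0,
              "decline_slope must be <= 0")
  structure(list(cc_max = cc_max, tm = tm, te = te,
                 decline_slope = decline_slope),
            class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf(
    "Beta canopy parameters: cc_max = %.4g, tm = %.4g, te = %.4g degree-days, decline = %.3g per degree-day\n",
    x$cc_max, x$tm, x$te, x$decline_slope))
  invisible(x)
}

#' Thermal time accumulation
#'
#' Daily increment `max(0, (tmin + tmax)/2 - t_base)`, accumulated over the
#' weather series.
#'
#' @param weather a weather series (see [generate_weather()]) with columns
#'   `dap`, `tmin`, `tmax`.
#' @param t_base base temperature, degrees C. Default 2, a common value for
#'   potato development.
#' @return a `data.frame` with columns `dap`, `increment` and cumulative `tt`
#'   (degree-days, non-decreasing).
#' @export
thermal_time <- function(weather, t_base = 2) {
  assert_that(nrow(weather) > 0, "weather series is empty")
  inc <- pmax(0, (weather$tmin + weather$tmax) / 2 - t_base)
  data.frame(dap = weather$dap, increment = inc, tt = cumsum(inc))
}

#' Evaluate the canopy-cover curve
#'
#' Beta growth form below `te`, linear decline above, clipped to `[0, 1]`.
#'
#' @param t thermal time(s), degree-days, `>= 0`.
#' @param params a [beta_params()] object.
#' @return canopy-cover fraction(s) in `[0, 1]`.
#' @export
beta_canopy_cover <- function(t, params) {
  assert_that(all(t >= 0), "thermal time must be non-negative")
  cc_max <- params$cc_max
  tm <- params$tm
  te <- params$te
  shape <- te / (te - tm)
  cc <- ifelse(t <= te,
               cc_max * (1 + (te - t) / (te - tm)) * (t / te)^shape,
               cc_max + params$decline_slope * (t - te))
  pmin(pmax(cc, 0), 1)
}

#' Interception fraction
#'
#' The fraction f of incident PAR intercepted by the canopy, equated with
#' canopy cover (cover is a good estimate of the intercepted PAR fraction).
#'
#' @inheritParams beta_canopy_cover
#' @return f in `[0, 1]`.
#' @export
interception_fraction <- function(params, t) beta_canopy_cover(t, params)

#' Fit the Beta canopy curve to flight observations
#'
#' Joint bounded least-squares fit of the piecewise curve (Beta rising phase
#' plus linear post-peak decline) to per-flight canopy cover on thermal time.
#' A data-driven start and two fixed perturbations of it are each optimized
#' (Nelder-Mead with box penalty, then an L-BFGS-B polish); the best fit is
#' returned. On noiseless data from the model family the fit recovers the
#' generating parameters to optimizer precision.
#'
#' @param points a [canopy_points()] series (columns `dap`, `cc`); at least 5
#'   flights.
#' @param thermal a [thermal_time()] table covering all flight daps.
#' @param lower,upper optional named bounds for `cc_max`, `tm_frac` (= tm/te),
#'   `te`, `decline_slope`.
#' @return a list of class `beta_fit` with elements `params`
#'   ([beta_params()]), `sse`, `rmse`, `n`, `n_decline` (flights after the
#'   fitted peak) and `convergence`.
#' @export
fit_beta_canopy <- function(points, thermal, lower = NULL, upper = NULL) {
  assert_that(nrow(points) >= 5, "need at least 5 canopy points")
  tt <- thermal$tt[match(points$dap, thermal$dap)]
  assert_that(!anyNA(tt), "every flight dap must be inside the thermal-time table")
  cc <- points$cc

  i_max <- which.max(cc)
  assert_that(i_max < length(cc),
              "need at least one flight after the empirical cover maximum")
  tt_max <- max(tt)
  lo <- c(cc_max = 0.01, tm_frac = 0.05, te = min(tt[tt > 0]),
          decline_slope = -0.05)
  hi <- c(cc_max = 1.0, tm_frac = 0.95, te = 2 * tt_max, decline_slope = 0)
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)

  obj <- function(p) {
    pars <- list(cc_max = p[1], tm = p[2] * p[3], te = p[3],
                 decline_slope = p[4])
    class(pars) <- "beta_params"
    sum((beta_canopy_cover(tt, pars) - cc)^2)
  }

  # empirical start: peak cover, peak position, half-way inflection, and the
  # crude post-peak slope
  slope0 <- if (i_max < length(cc)) {
    min(0, (cc[length(cc)] - cc[i_max]) / (tt[length(tt)] - tt[i_max]))
  } else -1e-4
  start0 <- c(min(max(cc), 1), 0.5, tt[i_max], slope0)
  starts <- list(start0,
                 start0 * c(1.00, 0.70, 0.85, 1.5),
                 start0 * c(0.95, 1.30, 1.15, 0.5))
  fits <- lapply(starts, function(s) {
    s <- pmin(pmax(s, lo), hi)
    optim_boxed(s, obj, lo, hi)
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  p <- best$par
  params <- beta_params(p[1], p[2] * p[3], p[3], min(p[4], 0))
  structure(list(params = params,
                 sse = best$value,
                 rmse = sqrt(best$value / length(cc)),
                 n = length(cc),
                 n_decline = sum(tt > params$te),
                 convergence = best$convergence %||% 0L),
            class = "beta_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("Beta canopy fit on %d flights (rmse %.3g)\n", x$n, x$rmse))
  print(x$params)
  invisible(x)
}

#' Cumulative incident PAR
#'
#' Sum of daily incident PAR over a closed dap interval.
#'
#' @param weather weather series with columns `dap`, `par_inc`.
#' @param from_dap,to_dap closed integration bounds, days after planting.
#' @return cumulative PAR, MJ m^-2.
#' @export
cumulative_par <- function(weather, from_dap = 1L, to_dap = max(weather$dap)) {
  assert_that(from_dap >= min(weather$dap) && to_dap <= max(weather$dap) &&
                from_dap <= to_dap,
              "dap range [%s, %s] outside weather series", from_dap, to_dap)
  sel <- weather$dap >= from_dap & weather$dap <= to_dap
  sum(weather$par_inc[sel])
}

#' Cumulative intercepted PAR and interception efficiency
#'
#' Integrates daily intercepted PAR, `PARint = sum f(t) * PARinc(t)` over
#' dap 1 to harvest, and the interception efficiency
#' `epsilon_i = 100 * PARint / PARinc`.
#'
#' @param weather weather series (daily PAR and temperatures).
#' @param params a [beta_params()] object describing the canopy.
#' @param harvest_dap last day of integration (harvest), days after planting.
#' @param t_base base temperature for the thermal-time mapping.
#' @return a list of class `radiation_summary` with `par_inc_cum`,
#'   `par_int_cum` (MJ m^-2) and `epsilon_i` (percent).
#' @export
radiation_summary <- function(weather, params, harvest_dap, t_base = 2) {
  assert_that(harvest_dap >= min(weather$dap) && harvest_dap <= max(weather$dap),
              "harvest dap %s outside weather series", harvest_dap)
  th <- thermal_time(weather, t_base)
  sel <- weather$dap >= 1 & weather$dap <= harvest_dap
  f <- interception_fraction(params, th$tt[sel])
  par_int <- sum(f * weather$par_inc[sel])
  par_inc <- cumulative_par(weather, 1L, harvest_dap)
  out <- structure(list(par_inc_cum = par_inc, par_int_cum = par_int,
                        epsilon_i = 100 * par_int / par_inc),
                   class = "radiation_summary")
  assert_that(out$par_int_cum <= out$par_inc_cum + 1e-9,
              "intercepted PAR exceeds incident PAR")
  out
}

#' @export
print.radiation_summary <- function(x, ...) {
  cat(sprintf(
    "PARinc = %.1f MJ m-2, PARint = %.1f MJ m-2, epsilon_i = %.1f%%\n",
    x$par_inc_cum, x$par_int_cum, x$epsilon_i))
  invisible(x)
}
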