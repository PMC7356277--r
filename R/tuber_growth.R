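# Radiation-driven tuber growth with Gompertz partitioning.
#
# Daily total dry biomass per square metre accumulates as
# RUE * f(t) * PARinc(t); tuber dry mass is the running biomass times the
# Gompertz partition fraction a_max * exp(-exp(-b * (tt - tu))), whose maximum
# partition rate falls at thermal time tu (the tuberization-precocity proxy:
# lower tu = earlier tuberization). Harvest index is tuber mass over total
# biomass at harvest. Calibration minimizes the mean relative error between
# observed and simulated tuber dry mass.

#' Gompertz tuber-partitioning parameters
#'
#' @param a_max asymptotic partition fraction, in `(0, 1]` (keeps tuber mass
#'   below total biomass).
#' @param b partition rate, per degree-day, `> 0`.
#' @param tu thermal time at the maximum tuber partitioning rate (Gompertz
#'   inflection), degree-days, `> 0`.
#' @return an object of class `gompertz_params`.
#' @export
gompertz_params <- function(a_max, b, tu) {
  assert_that(is_number(a_max) && a_max > 0 && a_max <= 1,
              "a_max must lie in (0, 1]")
  assert_that(is_number(b) && b > 0, "b must be positive")
  assert_that(is_number(tu) && tu > 0, "tu must be positive")
  structure(list(a_max = a_max, b = b, tu = tu), class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf(
    "Gompertz partition: a_max = %.3g, b = %.3g per degree-day, tu = %.4g degree-days\n",
    x$a_max, x$b, x$tu))
  invisible(x)
}

#' Gompertz partition fraction
#'
#' `a_max * exp(-exp(-b * (tt - tu)))`; equals `a_max / e` at `tt = tu` and
#' approaches `a_max` asymptotically.
#'
#' @param tt thermal time(s), degree-days, `>= 0`.
#' @param params a [gompertz_params()] object.
#' @return partition fraction(s) in `(0, a_max)`.
#' @export
gompertz_partition <- function(tt, params) {
  assert_that(all(tt >= 0), "thermal time must be non-negative")
  params$a_max * exp(-exp(-params$b * (tt - params$tu)))
}

# Normalize the f-curve argument: accept beta_params, a beta_fit, or a
# function of thermal time.
as_f_curve <- function(f) {
  if (inherits(f, "beta_fit")) f <- f$params
  if (inherits(f, "beta_params")) {
    p <- f
    return(function(tt) beta_canopy_cover(tt, p))
  }
  assert_that(is.function(f), "f must be beta_params, beta_fit or a function(tt)")
  f
}

#' Simulate radiation-driven tuber growth
#'
#' Accumulates daily total dry biomass `rue * f(t) * par_inc(t)` (g m^-2,
#' converted to g per plant through the plant area) and partitions it into
#' tubers with the Gompertz fraction at each day's thermal time.
#'
#' @param weather weather series covering dap 1 to `harvest_dap`.
#' @param f interception-fraction curve: a [beta_params()] / `beta_fit`
#'   object, or a function of thermal time returning values in `[0, 1]`.
#' @param rue radiation use efficiency, g dry biomass per MJ intercepted PAR.
#' @param gompertz a [gompertz_params()] object.
#' @param plant_area ground area per plant, m^2 (default 0.78).
#' @param harvest_dap harvest day, days after planting.
#' @param t_base base temperature for thermal time.
#' @return a list of class `growth_result` with `tb` (total dry biomass,
#'   g per plant), `ty_sim` (dry tuber mass, g per plant), `hi` (harvest
#'   index), and a daily `trajectory` data frame (`dap`, `tt`, `tb`, `tuber`).
#' @export
simulate_growth <- function(weather, f, rue, gompertz, plant_area = 0.78,
                            harvest_dap = max(weather$dap), t_base = 2) {
  assert_that(is_number(rue) && rue > 0, "rue must be positive")
  assert_that(is_number(plant_area) && plant_area > 0,
              "plant_area must be positive")
  assert_that(harvest_dap >= 1 && harvest_dap <= max(weather$dap),
              "harvest dap %s beyond weather series", harvest_dap)
  fcur <- as_f_curve(f)
  th <- thermal_time(weather, t_base)
  sel <- weather$dap >= 1 & weather$dap <= harvest_dap
  tt <- th$tt[sel]
  fday <- fcur(tt)
  tb_m2 <- cumsum(rue * fday * weather$par_inc[sel])
  tb <- tb_m2 * plant_area
  tuber <- tb * gompertz_partition(tt, gompertz)
  n <- length(tb)
  structure(list(
    tb = tb[n],
    ty_sim = tuber[n],
    hi = if (tb[n] > 0) tuber[n] / tb[n] else NA_real_,
    trajectory = data.frame(dap = weather$dap[sel], tt = tt,
                            tb = tb, tuber = tuber)),
    class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat(sprintf(
    "Growth result: TB = %.1f g/plant, TY = %.1f g/plant, HI = %.3f\n",
    x$tb, x$ty_sim, x$hi))
  invisible(x)
}

#' Calibrate the growth model against tuber-mass observations
#'
#' Fits radiation use efficiency and Gompertz partition parameters by
#' minimizing the mean relative error `mean(|sim - obs| / obs)` between
#' observed and simulated dry tuber mass, with seeded multi-start bounded
#' Nelder-Mead (L-BFGS-B polish). Because RUE and `a_max` enter simulated
#' tuber mass only through their product, `a_max` is held fixed by default;
#' any subset of parameters can be fixed.
#'
#' @param obs data frame of observations with columns `dap` and `ty_obs`
#'   (dry tuber mass, g per plant, `> 0`).
#' @param weather,f,plant_area,t_base as in [simulate_growth()].
#' @param start named list of starting values (`rue`, `a_max`, `b`, `tu`).
#' @param lower,upper named numeric bounds for the same parameters.
#' @param fixed character vector of parameter names held at their `start`
#'   values (default `"a_max"`).
#' @param seed integer seed driving the random multi-starts.
#' @param n_starts number of starts (the supplied start plus `n_starts - 1`
#'   draws uniform within the bounds).
#' @return a list of class `growth_calibration` with `rue`,
#'   `gompertz` ([gompertz_params()]), `mre` (mean relative error, fraction),
#'   `mre_percent`, `fitted` (simulated mass at the observation daps),
#'   `free` and `convergence`.
#' @export
calibrate_growth <- function(obs, weather, f,
                             start = list(rue = 2, a_max = 0.8, b = 0.004,
                                          tu = 450),
                             lower = c(rue = 0.1, a_max = 0.3, b = 5e-4,
                                       tu = 100),
                             upper = c(rue = 6, a_max = 1, b = 0.05,
                                       tu = 1500),
                             fixed = "a_max",
                             plant_area = 0.78, t_base = 2,
                             seed = 1L, n_starts = 5L) {
  assert_that(nrow(obs) >= 1, "need at least one observation")
  assert_that(all(obs$ty_obs > 0),
              "tuber-mass observations must be strictly positive")
  assert_that(all(obs$dap >= 1 & obs$dap <= max(weather$dap)),
              "observation daps must lie inside the weather series")
  par_names <- c("rue", "a_max", "b", "tu")
  start <- unlist(start)[par_names]
  assert_that(!anyNA(start), "start must name rue, a_max, b and tu")
  lower <- lower[par_names]
  upper <- upper[par_names]
  assert_that(all(start >= lower & start <= upper),
              "bounds must contain the starting values")
  free <- setdiff(par_names, fixed)
  assert_that(length(free) > 0, "at least one parameter must be free")

  fcur <- as_f_curve(f)
  th <- thermal_time(weather, t_base)
  sel <- weather$dap >= 1 & weather$dap <= max(obs$dap)
  tt <- th$tt[sel]
  # cumulative intercepted PAR * area: biomass per plant is rue * this
  cum_int <- cumsum(fcur(tt) * weather$par_inc[sel]) * plant_area
  idx <- match(obs$dap, weather$dap[sel])

  sim_at_obs <- function(p) {
    gp <- list(a_max = p[["a_max"]], b = p[["b"]], tu = p[["tu"]])
    class(gp) <- "gompertz_params"
    p[["rue"]] * cum_int[idx] * gompertz_partition(tt[idx], gp)
  }
  mre_of <- function(p_free) {
    p <- start
    p[free] <- p_free
    mean(abs(sim_at_obs(p) - obs$ty_obs) / obs$ty_obs)
  }

  # candidate starts: the user start, the best cells of a coarse (b, tu) grid
  # with rue profiled out (median observed/modelled ratio), and one seeded
  # random draw. The grid guards against the step-like local basin at high b.
  start_mat <- rbind(start[free])
  grid_free <- intersect(c("b", "tu"), free)
  if (length(grid_free) > 0 && n_starts > 2) {
    bs <- if ("b" %in% grid_free) {
      exp(seq(log(lower[["b"]]), log(upper[["b"]]), length.out = 12))
    } else start[["b"]]
    tus <- if ("tu" %in% grid_free) {
      seq(lower[["tu"]], upper[["tu"]], length.out = 15)
    } else start[["tu"]]
    grid <- expand.grid(b = bs, tu = tus)
    grid$rue <- start[["rue"]]
    grid_val <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      p <- start
      p[["b"]] <- grid$b[g]
      p[["tu"]] <- grid$tu[g]
      if ("rue" %in% free) {
        p[["rue"]] <- 1
        m <- sim_at_obs(p)
        p[["rue"]] <- min(max(stats::median(obs$ty_obs / m), lower[["rue"]]),
                          upper[["rue"]])
        grid$rue[g] <- p[["rue"]]
      }
      grid_val[g] <- mean(abs(sim_at_obs(p) - obs$ty_obs) / obs$ty_obs)
    }
    top <- order(grid_val)[seq_len(min(n_starts - 2L, nrow(grid)))]
    for (g in top) {
      s <- start
      s[["b"]] <- grid$b[g]
      s[["tu"]] <- grid$tu[g]
      if ("rue" %in% free) s[["rue"]] <- grid$rue[g]
      start_mat <- rbind(start_mat, s[free])
    }
  }
  if (n_starts > nrow(start_mat)) {
    extra <- withr::with_seed(seed, {
      t(replicate(n_starts - nrow(start_mat),
                  stats::runif(length(free), lower[free], upper[free])))
    })
    colnames(extra) <- free
    start_mat <- rbind(start_mat, extra)
  }
  fits <- apply(start_mat, 1L, function(s) {
    optim_boxed(s, mre_of, lower[free], upper[free])
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  p_hat <- start
  p_hat[free] <- best$par
  structure(list(
    rue = unname(p_hat[["rue"]]),
    gompertz = gompertz_params(p_hat[["a_max"]], p_hat[["b"]], p_hat[["tu"]]),
    mre = best$value,
    mre_percent = 100 * best$value,
    fitted = sim_at_obs(p_hat),
    free = free,
    convergence = best$convergence %||% 0L),
    class = "growth_calibration")
}

#' @export
print.growth_calibration <- function(x, ...) {
  cat(sprintf("Growth calibration (free: %s): RUE = %.3f g/MJ, MRE = %.2f%%\n",
              paste(x$free, collapse = ", "), x$rue, x$mre_percent))
  print(x$gompertz)
  invisible(x)
}

#' Extract tuberization precocity (tu)
#'
#' Returns the thermal time of maximum tuber partitioning rate and, when a
#' thermal-time table is supplied, its day-after-planting equivalent by
#' inverse lookup (linear interpolation). Higher tu means lower tuberization
#' precocity (later maturity).
#'
#' @param params a [gompertz_params()] object (or a `growth_calibration`).
#' @param thermal optional [thermal_time()] table for the dap conversion.
#' @return a list with `tu` (degree-days), `dap` (or `NA`), and
#'   `beyond_span` flag (`TRUE`, with a warning, when tu exceeds the
#'   simulated thermal-time span).
#' @export
extract_tu <- function(params, thermal = NULL) {
  if (inherits(params, "growth_calibration")) params <- params$gompertz
  tu <- params$tu
  dap <- NA_real_
  beyond <- FALSE
  if (!is.null(thermal)) {
    if (tu > max(thermal$tt)) {
      beyond <- TRUE
      warning("tu lies beyond the simulated thermal-time span", call. = FALSE)
    } else {
      dap <- stats::approx(thermal$tt, thermal$dap, xout = tu, ties = "ordered")$y
    }
  }
  list(tu = tu, dap = dap, beyond_span = beyond)
}
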