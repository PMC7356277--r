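# Synthetic field-trial generator.
#
# Emulates the structure of an augmented-design potato trial in a Lima winter
# season: daily weather drawn around published monthly means, 20 test
# accessions plus 4 replicated checks in 4 blocks, 13 weekly multispectral
# flights whose plot reflectances mix fixed vegetation and soil endmember
# spectra according to the model canopy cover, and harvest observations
# forward-simulated with the radiation-driven growth model. Every generator
# is deterministic under its seed, so the full analysis pipeline can be
# exercised — and its parameter recovery measured — without external data.

#' Monthly weather profile of the 2017 Lima winter season
#'
#' Average daily values (mean and standard error) of the environmental
#' conditions per calendar month, July-November: maximum/minimum temperature
#' (degrees C), solar radiation and PAR (MJ m^-2 d^-1), relative humidity (%)
#' and vapour pressure deficit (kPa).
#'
#' @return a `data.frame` with one row per month (7-11) and `*_mean` / `*_se`
#'   columns for `tmax`, `tmin`, `solar`, `par`, `rh`, `vpd`.
#' @export
lima_winter_profile <- function() {
  profile <- data.frame(
    month      = 7:11,
    tmax_mean  = c(19.8, 19.2, 19.0, 21.5, 22.1),
    tmax_se    = c(0.29, 0.27, 0.38, 0.30, 0.26),
    tmin_mean  = c(15.3, 14.3, 14.0, 14.6, 15.2),
    tmin_se    = c(0.14, 0.10, 0.08, 0.08, 0.19),
    solar_mean = c(8.5, 8.8, 9.4, 16.8, 16.1),
    solar_se   = c(0.77, 0.69, 0.96, 0.68, 0.73),
    par_mean   = c(3.7, 3.6, 3.8, 7.2, 6.8),
    par_se     = c(0.27, 0.27, 0.36, 0.27, 0.29),
    rh_mean    = c(85.4, 88.7, 91.2, 89.6, 86.2),
    rh_se      = c(0.61, 0.57, 0.59, 0.46, 0.57),
    vpd_mean   = c(0.24, 0.18, 0.14, 0.17, 0.24),
    vpd_se     = c(0.01, 0.01, 0.01, 0.01, 0.01))
  validate_weather_profile(profile)
  profile
}

validate_weather_profile <- function(profile) {
  need <- c("month", "tmax_mean", "tmax_se", "tmin_mean", "tmin_se",
            "solar_mean", "solar_se", "par_mean", "par_se")
  assert_that(all(need %in% names(profile)),
              "profile missing columns: %s",
              paste(setdiff(need, names(profile)), collapse = ", "))
  num <- unlist(profile[setdiff(need, "month")])
  assert_that(all(is.finite(num)), "profile means/SEs must be finite")
  assert_that(all(profile$par_mean <= profile$solar_mean),
              "monthly PAR mean cannot exceed solar radiation mean")
  invisible(profile)
}

days_in_month <- function(dates) {
  first <- as.Date(format(dates, "%Y-%m-01"))
  vapply(seq_along(first), function(i) {
    as.integer(format(seq(first[i], by = "1 month", length.out = 2)[2] - 1,
                      "%d"))
  }, integer(1))
}

#' Generate a daily weather series
#'
#' Draws daily values around each calendar month's mean. The daily standard
#' deviation is reconstructed from the printed standard error of the monthly
#' mean as `SE * sqrt(days in month)`, scaled by `dispersion`; draws are
#' truncated at physical bounds (PAR >= 0, tmin <= tmax). Day 1 after
#' planting (dap 1) is the day following `planting_date`.
#'
#' @param profile monthly profile, see [lima_winter_profile()].
#' @param planting_date planting day (`Date` or ISO string).
#' @param n_days length of the series (>= 1), days.
#' @param dispersion multiplier on the reconstructed daily SD; 0 yields the
#'   monthly means exactly.
#' @param seed integer seed (same seed, same series).
#' @return a `data.frame` of class `weather_series` with columns `dap`,
#'   `date`, `par_inc` (MJ m^-2 d^-1), `tmin`, `tmax` (degrees C).
#' @export
#' @examples
#' w <- generate_weather(n_days = 10, dispersion = 0, seed = 1)
#' w$par_inc # July mean PAR every day
generate_weather <- function(profile = lima_winter_profile(),
                             planting_date = as.Date("2017-07-05"),
                             n_days = 141L, dispersion = 1, seed = 1L) {
  assert_that(n_days >= 1, "n_days must be >= 1")
  validate_weather_profile(profile)
  planting_date <- as.Date(planting_date)
  dates <- planting_date + seq_len(n_days)
  months <- as.integer(format(dates, "%m"))
  missing <- setdiff(unique(months), profile$month)
  assert_that(length(missing) == 0,
              "months absent from profile: %s", paste(missing, collapse = ", "))
  i <- match(months, profile$month)
  dim_ <- days_in_month(dates)
  sd_of <- function(se) se[i] * sqrt(dim_) * dispersion

  draws <- withr::with_seed(seed, {
    list(par  = stats::rnorm(n_days, profile$par_mean[i], sd_of(profile$par_se)),
         tmin = stats::rnorm(n_days, profile$tmin_mean[i], sd_of(profile$tmin_se)),
         tmax = stats::rnorm(n_days, profile$tmax_mean[i], sd_of(profile$tmax_se)))
  })
  par_inc <- pmax(0, draws$par)
  tmax <- pmax(draws$tmax, draws$tmin) # physical bound: tmin <= tmax
  tmin <- pmin(draws$tmax, draws$tmin)
  out <- data.frame(dap = seq_len(n_days), date = dates,
                    par_inc = par_inc, tmin = tmin, tmax = tmax)
  class(out) <- c("weather_series", "data.frame")
  out
}

#' Generate an augmented block design
#'
#' Every check appears once in every block; each test (new) entry appears in
#' exactly one block; block sizes are equal. Entries carry a species label,
#' ploidy and a harvest day (121 or 141 dap), emulating harvests staggered by
#' senescence stage.
#'
#' @param n_new number of unreplicated test accessions.
#' @param n_checks number of replicated check varieties.
#' @param n_blocks number of blocks.
#' @param new_per_block test entries per block; must satisfy
#'   `n_new = n_blocks * new_per_block`.
#' @param plant_area ground area per plant, m^2.
#' @param seed integer seed for the randomization.
#' @return a `data.frame` of class `trial_design` with one row per plot:
#'   `accession`, `species`, `ploidy`, `is_check`, `block`, `harvest_dap`;
#'   attributes `n_blocks` and `plant_area`.
#' @export
generate_design <- function(n_new = 20L, n_checks = 4L, n_blocks = 4L,
                            new_per_block = 5L, plant_area = 0.78,
                            seed = 1L) {
  assert_that(n_new == n_blocks * new_per_block,
              "n_new (%d) must equal n_blocks * new_per_block (%d)",
              n_new, n_blocks * new_per_block)
  species_pool <- c("S. tuberosum subsp. andigenum" = 4L,
                    "S. tuberosum subsp. tuberosum" = 4L,
                    "S. stenotomum" = 2L,
                    "S. phureja" = 2L,
                    "S. chaucha" = 3L,
                    "S. juzepczukii" = 3L,
                    "S. curtilobum" = 5L)
  new_ids <- sprintf("ACC%02d", seq_len(n_new))
  check_ids <- sprintf("CHK%d", seq_len(n_checks))

  drawn <- withr::with_seed(seed, {
    list(block_of_new = rep(seq_len(n_blocks), each = new_per_block)[
           sample.int(n_new)],
         sp_new = sample(names(species_pool), n_new, replace = TRUE,
                         prob = c(0.5, 0.1, 0.1, 0.08, 0.08, 0.08, 0.06)),
         harvest_new = sample(c(121L, 141L), n_new, replace = TRUE),
         harvest_check = sample(c(121L, 141L), n_checks, replace = TRUE))
  })
  new_df <- data.frame(accession = new_ids,
                       species = drawn$sp_new,
                       ploidy = unname(species_pool[drawn$sp_new]),
                       is_check = FALSE,
                       block = drawn$block_of_new,
                       harvest_dap = drawn$harvest_new)
  check_df <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    data.frame(accession = check_ids,
               species = "improved variety",
               ploidy = 4L,
               is_check = TRUE,
               block = b,
               harvest_dap = drawn$harvest_check)
  }))
  out <- rbind(new_df, check_df)
  out <- out[order(out$block, out$is_check, out$accession), ]
  rownames(out) <- NULL
  attr(out, "n_blocks") <- n_blocks
  attr(out, "plant_area") <- plant_area
  class(out) <- c("trial_design", "data.frame")
  validate_design(out)
  out
}

validate_design <- function(design) {
  blocks <- sort(unique(design$block))
  checks <- unique(design$accession[design$is_check])
  for (b in blocks) {
    in_b <- design$accession[design$is_check & design$block == b]
    assert_that(setequal(in_b, checks) && !anyDuplicated(in_b),
                "every check must appear exactly once in block %s", b)
  }
  new_tab <- table(design$accession[!design$is_check])
  assert_that(all(new_tab == 1),
              "every test accession must appear in exactly one block")
  sizes <- table(design$block)
  assert_that(length(unique(sizes)) == 1, "block sizes must be equal")
  invisible(design)
}

#' Default parameter ranges for accession ground truth
#'
#' Ranges anchored to values reported for diverse potato germplasm: RUE
#' 1.0-3.6 g MJ^-1, tu 356.3-556.3 degree-days, asymptotic partition fraction
#' giving harvest indices of about 0.6-0.9, post-peak cover decline producing
#' NDVI senescence slopes of about -0.006 to -0.002 per day.
#'
#' @return a named list of `c(low, high)` ranges: `rue`, `cc_max`, `te`,
#'   `tm_frac`, `decline_slope`, `a_max`, `b`, `tu`, `a_mean`, `delta_leaf`.
#' @export
default_truth_ranges <- function() {
  list(rue = c(1.0, 3.6),
       cc_max = c(0.35, 0.95),
       te = c(700, 1100),
       tm_frac = c(0.40, 0.60),
       decline_slope = c(-7e-4, -2.3e-4),
       a_max = c(0.63, 0.93),
       b = c(0.002, 0.006),
       tu = c(356.3, 556.3),
       a_mean = c(17, 26.6),
       delta_leaf = c(21, 23))
}

#' Generate accession ground truth
#'
#' Draws one true parameter record per accession, uniform within the
#' configured ranges. A shared latent factor links radiation use efficiency
#' positively with a shallower senescence decline and negatively with tu,
#' emulating the field association between senescence delay, earliness and
#' yield; `link = 0` makes all draws independent.
#'
#' @param design a [generate_design()] object.
#' @param ranges named ranges, see [default_truth_ranges()]. Collapsing a
#'   range to a point fixes that parameter for every accession.
#' @param link weight in `[0, 1]` of the shared latent factor (default 0.5).
#' @param seed integer seed.
#' @return a `data.frame` of class `accession_truth`, one row per accession:
#'   `accession`, `is_check`, `rue_true`, `cc_max`, `tm`, `te`,
#'   `decline_slope`, `a_max`, `b`, `tu`, `a_mean`, `delta_leaf`.
#' @export
generate_truth <- function(design, ranges = default_truth_ranges(),
                           link = 0.5, seed = 1L) {
  acc <- unique(design$accession)
  assert_that(length(acc) > 0, "design has no accessions")
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    assert_that(length(r) == 2 && r[1] <= r[2],
                "range %s must be c(low, high) with low <= high", nm)
  }
  pos <- c("rue", "cc_max", "te", "tm_frac", "a_max", "b", "tu")
  for (nm in pos) {
    assert_that(ranges[[nm]][1] > 0, "range %s must be positive", nm)
  }
  n <- length(acc)
  u <- withr::with_seed(seed, {
    m <- matrix(stats::runif(n * 10L), n, 10L)
    colnames(m) <- c("rue", "cc_max", "te", "tm_frac", "decline", "a_max",
                     "b", "tu", "a_mean", "delta_leaf")
    m
  })
  scale_to <- function(u, r) r[1] + u * (r[2] - r[1])
  # shared latent factor: u[, "rue"] also pulls decline toward shallow (high)
  # and tu toward early (low)
  u_dec <- link * u[, "rue"] + (1 - link) * u[, "decline"]
  u_tu <- link * (1 - u[, "rue"]) + (1 - link) * u[, "tu"]
  te <- scale_to(u[, "te"], ranges$te)
  out <- data.frame(
    accession = acc,
    is_check = design$is_check[match(acc, design$accession)],
    rue_true = scale_to(u[, "rue"], ranges$rue),
    cc_max = scale_to(u[, "cc_max"], ranges$cc_max),
    tm = scale_to(u[, "tm_frac"], ranges$tm_frac) * te,
    te = te,
    decline_slope = scale_to(u_dec, ranges$decline_slope),
    a_max = scale_to(u[, "a_max"], ranges$a_max),
    b = scale_to(u[, "b"], ranges$b),
    tu = scale_to(u_tu, ranges$tu),
    a_mean = scale_to(u[, "a_mean"], ranges$a_mean),
    delta_leaf = scale_to(u[, "delta_leaf"], ranges$delta_leaf))
  assert_that(all(out$rue_true > 0), "rue_true must be positive")
  class(out) <- c("accession_truth", "data.frame")
  out
}

truth_beta <- function(truth_row) {
  beta_params(truth_row$cc_max, truth_row$tm, truth_row$te,
              truth_row$decline_slope)
}

truth_gompertz <- function(truth_row) {
  gompertz_params(truth_row$a_max, truth_row$b, truth_row$tu)
}

#' Endmember reflectance spectra
#'
#' Fixed vegetation and soil three-band reflectances used to mix synthetic
#' plot spectra: they give NDVI of about 0.72 over full canopy and 0.11 over
#' bare soil, cleanly separable by a SAVI threshold of 0.3.
#'
#' @return a list with named numeric vectors `vegetation` and `soil`
#'   (`green`, `red`, `nir` reflectances in `[0, 1]`).
#' @export
endmember_spectra <- function() {
  list(vegetation = c(green = 0.10, red = 0.08, nir = 0.50),
       soil = c(green = 0.18, red = 0.20, nir = 0.25))
}

#' Generate per-flight canopy reflectance observations
#'
#' For each flight, builds a plot raster in which a fraction of pixels equal
#' to the model canopy cover carries the vegetation spectrum and the rest the
#' soil spectrum, adds truncated Gaussian reflectance noise, and derives the
#' canopy-cover / NDVI series with the imaging module (SAVI segmentation and
#' plot-mean NDVI). All reflectances are clipped to `[0, 1]`.
#'
#' @param truth_row one row of [generate_truth()].
#' @param weather weather series covering all flights.
#' @param flight_daps flight days after planting (default 13 weekly flights).
#' @param noise_sd per-pixel reflectance noise SD (reflectance units).
#' @param seed integer seed.
#' @param t_base base temperature for thermal time.
#' @param patch_dim raster side length in pixels.
#' @param spectra endmember spectra, see [endmember_spectra()].
#' @param threshold,L segmentation settings, see [segment_canopy_cover()].
#' @param keep_rasters keep the simulated rasters in the result.
#' @return a list with `reflectance` (data frame `dap`, `green`, `red`,
#'   `nir` plot means), `points` (a [canopy_points()] series), `cc_true`
#'   (model cover at each flight) and optionally `rasters`.
#' @export
generate_canopy_observations <- function(truth_row, weather,
                                         flight_daps = seq(21L, 105L, by = 7L),
                                         noise_sd = 0.01, seed = 1L,
                                         t_base = 2, patch_dim = 64L,
                                         spectra = endmember_spectra(),
                                         threshold = 0.3, L = 0.5,
                                         keep_rasters = FALSE) {
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(all(flight_daps >= 1 & flight_daps <= max(weather$dap)),
              "flight daps must lie inside the weather series")
  th <- thermal_time(weather, t_base)
  beta <- truth_beta(truth_row)
  cc_true <- beta_canopy_cover(th$tt[match(flight_daps, th$dap)], beta)
  n_pix <- patch_dim^2

  rasters <- withr::with_seed(seed, {
    lapply(cc_true, function(cc) {
      n_veg <- round(cc * n_pix)
      veg_pos <- sample.int(n_pix, n_veg)
      mk_band <- function(band) {
        base <- rep(spectra$soil[[band]], n_pix)
        base[veg_pos] <- spectra$vegetation[[band]]
        if (noise_sd > 0) base <- base + stats::rnorm(n_pix, 0, noise_sd)
        matrix(pmin(pmax(base, 0), 1), patch_dim, patch_dim)
      }
      list(green = mk_band("green"), red = mk_band("red"), nir = mk_band("nir"))
    })
  })
  reflectance <- data.frame(
    dap = flight_daps,
    green = vapply(rasters, function(r) mean(r$green), numeric(1)),
    red = vapply(rasters, function(r) mean(r$red), numeric(1)),
    nir = vapply(rasters, function(r) mean(r$nir), numeric(1)))
  points <- extract_canopy_points(rasters, flight_daps,
                                  threshold = threshold, L = L)
  out <- list(reflectance = reflectance, points = points, cc_true = cc_true)
  if (keep_rasters) out$rasters <- rasters
  out
}

#' Generate harvest (and mid-season) tuber-mass observations
#'
#' Forward-simulates the growth model with the accession's true parameters to
#' each observation day and applies multiplicative lognormal noise with the
#' requested coefficient of variation (mean-preserving; observations stay
#' strictly positive). `noise_cv = 0` returns the simulated mass exactly.
#'
#' @param truth_row one row of [generate_truth()].
#' @param weather weather series covering the harvest.
#' @param harvest_dap the plot's harvest day.
#' @param obs_daps observation days (default: the harvest day only).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param plant_area,t_base as in [simulate_growth()].
#' @return a `data.frame` with columns `dap`, `ty_true` (simulated) and
#'   `ty_obs` (noisy), g per plant.
#' @export
generate_harvest <- function(truth_row, weather, harvest_dap,
                             obs_daps = harvest_dap, noise_cv = 0.1,
                             seed = 1L, plant_area = 0.78, t_base = 2) {
  assert_that(noise_cv >= 0, "noise_cv must be non-negative")
  assert_that(all(obs_daps >= 1 & obs_daps <= max(weather$dap)),
              "observation daps beyond the weather series")
  sim <- simulate_growth(weather, truth_beta(truth_row), truth_row$rue_true,
                         truth_gompertz(truth_row), plant_area,
                         harvest_dap = max(obs_daps), t_base = t_base)
  ty_true <- sim$trajectory$tuber[match(obs_daps, sim$trajectory$dap)]
  factor <- if (noise_cv > 0) {
    s <- sqrt(log(1 + noise_cv^2))
    withr::with_seed(seed, exp(stats::rnorm(length(obs_daps), -s^2 / 2, s)))
  } else rep(1, length(obs_daps))
  data.frame(dap = obs_daps, ty_true = ty_true, ty_obs = ty_true * factor)
}

#' Simulate a complete synthetic trial
#'
#' Bundles weather, design, accession truth, per-plot canopy observations and
#' tuber-mass observations. Sub-seeds for each generator and plot are derived
#' deterministically from the master seed.
#'
#' @param n_new,n_checks,n_blocks,new_per_block design dimensions, see
#'   [generate_design()].
#' @param planting_date,n_days,dispersion weather settings, see
#'   [generate_weather()].
#' @param ranges,link truth settings, see [generate_truth()].
#' @param flight_daps,noise_sd,patch_dim canopy settings, see
#'   [generate_canopy_observations()].
#' @param obs_frac fractions of each plot's harvest day at which tuber-mass
#'   observations are taken (the last must be 1; default four points).
#' @param noise_cv tuber-mass observation noise, see [generate_harvest()].
#' @param a_sd,delta_sd plot-level measurement SD of the season-average net
#'   photosynthesis rate and leaf carbon-isotope discrimination (noisy
#'   constants per accession, no within-season dynamics).
#' @param plot_jitter lognormal SD of the per-plot perturbation of peak
#'   canopy cover and senescence slope (stand-establishment variability
#'   between replicate plots of the same accession); `0` makes replicate
#'   plots share the accession's exact canopy.
#' @param plant_area,t_base physical settings.
#' @param seed master integer seed.
#' @return a list of class `synthetic_trial` with `weather`, `design`,
#'   `truth`, `plots` (per-plot list: `accession`, `block`, `harvest_dap`,
#'   `canopy`, `harvest`), and the generation `settings`.
#' @export
simulate_trial <- function(n_new = 20L, n_checks = 4L, n_blocks = 4L,
                           new_per_block = 5L,
                           planting_date = as.Date("2017-07-05"),
                           n_days = 141L, dispersion = 1,
                           ranges = default_truth_ranges(), link = 0.5,
                           flight_daps = seq(21L, 105L, by = 7L),
                           noise_sd = 0.01, patch_dim = 64L,
                           obs_frac = c(0.5, 0.65, 0.8, 1),
                           noise_cv = 0.1, a_sd = 1.5, delta_sd = 0.3,
                           plot_jitter = 0.04,
                           plant_area = 0.78, t_base = 2,
                           seed = 1L) {
  assert_that(abs(obs_frac[length(obs_frac)] - 1) < 1e-12,
              "the last observation fraction must be 1 (the harvest)")
  seeds <- derive_seeds(seed, 4L)
  weather <- generate_weather(planting_date = planting_date, n_days = n_days,
                              dispersion = dispersion, seed = seeds[1])
  design <- generate_design(n_new, n_checks, n_blocks, new_per_block,
                            plant_area, seed = seeds[2])
  truth <- generate_truth(design, ranges, link, seed = seeds[3])
  plot_seeds <- derive_seeds(seeds[4], 4L * nrow(design))

  plots <- lapply(seq_len(nrow(design)), function(i) {
    entry <- design[i, ]
    tr <- truth[truth$accession == entry$accession, ]
    # per-plot realized canopy: stand-establishment jitter on peak cover and
    # senescence slope, shared by the reflectance and growth simulations
    if (plot_jitter > 0) {
      jit <- withr::with_seed(plot_seeds[4 * i - 3],
                              exp(stats::rnorm(2, 0, plot_jitter)))
      tr$cc_max <- min(tr$cc_max * jit[1], 1)
      tr$decline_slope <- tr$decline_slope * jit[2]
    }
    canopy <- generate_canopy_observations(
      tr, weather, flight_daps, noise_sd, seed = plot_seeds[4 * i - 2],
      t_base = t_base, patch_dim = patch_dim)
    obs_daps <- unique(round(obs_frac * entry$harvest_dap))
    harvest <- generate_harvest(tr, weather, entry$harvest_dap,
                                obs_daps = obs_daps, noise_cv = noise_cv,
                                seed = plot_seeds[4 * i - 1],
                                plant_area = plant_area, t_base = t_base)
    phys <- withr::with_seed(plot_seeds[4 * i], {
      c(a = tr$a_mean + stats::rnorm(1, 0, a_sd),
        delta_leaf = tr$delta_leaf + stats::rnorm(1, 0, delta_sd))
    })
    list(accession = entry$accession, block = entry$block,
         is_check = entry$is_check, harvest_dap = entry$harvest_dap,
         plot_truth = tr, canopy = canopy, harvest = harvest,
         a_obs = unname(phys["a"]), delta_leaf_obs = unname(phys["delta_leaf"]))
  })
  structure(list(weather = weather, design = design, truth = truth,
                 plots = plots,
                 settings = list(plant_area = plant_area, t_base = t_base,
                                 noise_sd = noise_sd, noise_cv = noise_cv,
                                 flight_daps = flight_daps,
                                 obs_frac = obs_frac, seed = seed)),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "Synthetic trial: %d plots (%d accessions, %d blocks), %d flights, %d weather days\n",
    length(x$plots), nrow(x$truth), attr(x$design, "n_blocks"),
    length(x$settings$flight_daps), nrow(x$weather)))
  invisible(x)
}
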