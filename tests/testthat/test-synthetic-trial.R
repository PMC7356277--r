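test_that("dispersion 0 reproduces the monthly means exactly", {
  w <- generate_weather(n_days = 10, dispersion = 0, seed = 99)
  expect_equal(w$par_inc, rep(3.7, 10)) # July PAR mean
  expect_equal(w$tmin, rep(15.3, 10))
  expect_equal(w$tmax, rep(19.8, 10))
  expect_equal(w$dap, 1:10)
  expect_equal(w$date[1], as.Date("2017-07-06")) # dap 1 is the day after planting
})

test_that("weather generation is seed-deterministic and physically bounded", {
  a <- generate_weather(n_days = 141, seed = 12)
  b <- generate_weather(n_days = 141, seed = 12)
  expect_identical(a, b)
  c <- generate_weather(n_days = 141, seed = 13)
  expect_false(identical(a$par_inc, c$par_inc))
  expect_true(all(a$par_inc >= 0))
  expect_true(all(a$tmin <= a$tmax))
  expect_error(generate_weather(n_days = 0), ">= 1")
  # one-day boundary
  expect_equal(nrow(generate_weather(n_days = 1, seed = 1)), 1L)
  # a 141-day season spans July-November months only
  expect_true(all(as.integer(format(a$date, "%m")) %in% 7:11))
})

test_that("long-run monthly weather means approach the profile", {
  w <- generate_weather(n_days = 141, dispersion = 1, seed = 202)
  prof <- lima_winter_profile()
  months <- as.integer(format(w$date, "%m"))
  for (m in unique(months)) {
    sel <- months == m
    n <- sum(sel)
    if (n < 10) next
    row <- prof[prof$month == m, ]
    # sample mean within 4 reconstructed standard errors of the monthly mean
    se_day <- row$par_se * sqrt(mean(days_in_month(w$date[sel])))
    expect_lt(abs(mean(w$par_inc[sel]) - row$par_mean), 4 * se_day / sqrt(n))
  }
})

test_that("augmented design satisfies its structural invariants", {
  d <- generate_design(seed = 5)
  expect_equal(nrow(d), 36L) # 20 new + 4 checks x 4 blocks
  expect_equal(attr(d, "n_blocks"), 4L)
  expect_equal(attr(d, "plant_area"), 0.78)
  expect_true(all(d$harvest_dap %in% c(121L, 141L)))
  # each check once per block
  for (b in 1:4) {
    expect_setequal(d$accession[d$is_check & d$block == b],
                    sprintf("CHK%d", 1:4))
  }
  # each new entry exactly once overall, 5 per block
  expect_true(all(table(d$accession[!d$is_check]) == 1))
  expect_true(all(table(d$block[!d$is_check]) == 5))
  expect_identical(generate_design(seed = 5), d)
  # minimal design
  tiny <- generate_design(n_new = 1, n_checks = 1, n_blocks = 1,
                          new_per_block = 1, seed = 1)
  expect_equal(nrow(tiny), 2L)
  expect_error(generate_design(n_new = 7, n_blocks = 2, new_per_block = 3),
               "must equal")
})

test_that("accession truth respects ranges, links and determinism", {
  d <- generate_design(seed = 2)
  tr <- generate_truth(d, seed = 7)
  rng <- default_truth_ranges()
  expect_equal(nrow(tr), 24L)
  expect_true(all(tr$rue_true >= rng$rue[1] & tr$rue_true <= rng$rue[2]))
  expect_true(all(tr$cc_max >= rng$cc_max[1] & tr$cc_max <= rng$cc_max[2]))
  expect_true(all(tr$tu >= rng$tu[1] & tr$tu <= rng$tu[2]))
  expect_true(all(tr$tm > 0 & tr$tm < tr$te))
  expect_true(all(tr$decline_slope <= 0))
  expect_identical(generate_truth(d, seed = 7), tr)
  # collapsed range pins the parameter
  rng2 <- rng
  rng2$rue <- c(2.5, 2.5)
  tr2 <- generate_truth(d, rng2, seed = 7)
  expect_true(all(tr2$rue_true == 2.5))
  # latent link: high-RUE accessions tuberize earlier on average
  trl <- generate_truth(d, link = 1, seed = 8)
  expect_lt(stats::cor(trl$rue_true, trl$tu), -0.9)
})

test_that("noiseless canopy observations recover the model cover to pixel quantization", {
  w <- generate_weather(n_days = 120, dispersion = 0, seed = 1)
  d <- generate_design(n_new = 1, n_checks = 1, n_blocks = 1,
                       new_per_block = 1, seed = 1)
  tr <- generate_truth(d, seed = 3)[1, ]
  obs <- generate_canopy_observations(tr, w, noise_sd = 0, seed = 4)
  expect_equal(nrow(obs$points), 13L) # 13 weekly flights
  # segmentation returns exactly the rounded pixel fraction of the true cover
  expect_true(all(abs(obs$points$cc - obs$cc_true) <= 0.5 / 4096 + 1e-12))
  # NDVI rises with canopy and the series peaks where cover peaks
  expect_equal(which.max(obs$points$ndvi), which.max(obs$cc_true))
  expect_error(generate_canopy_observations(tr, w, flight_daps = c(7, 150)),
               "inside the weather")
})

test_that("a pure-soil scene yields zero cover and soil NDVI", {
  w <- constant_weather(60)
  d <- generate_design(n_new = 1, n_checks = 1, n_blocks = 1,
                       new_per_block = 1, seed = 1)
  tr <- generate_truth(d, seed = 3)[1, ]
  tr$cc_max <- 1e-6 # effectively no canopy all season
  obs <- generate_canopy_observations(tr, w, flight_daps = c(7, 14, 21),
                                      noise_sd = 0, seed = 2)
  expect_equal(obs$points$cc, rep(0, 3))
  sp <- endmember_spectra()
  soil_ndvi <- compute_ndvi(sp$soil[["nir"]], sp$soil[["red"]])
  expect_equal(obs$points$ndvi, rep(soil_ndvi, 3), tolerance = 1e-10)
})

test_that("harvest observations are exact without noise and match the target CV with it", {
  w <- generate_weather(n_days = 141, seed = 6)
  d <- generate_design(seed = 6)
  tr <- generate_truth(d, seed = 6)[1, ]
  clean <- generate_harvest(tr, w, 121, noise_cv = 0, seed = 1)
  sim <- simulate_growth(w, truth_beta(tr), tr$rue_true, truth_gompertz(tr),
                         harvest_dap = 121)
  expect_equal(clean$ty_obs, sim$ty_sim)
  expect_equal(clean$ty_true, clean$ty_obs)
  # Monte-Carlo: multiplicative noise is mean-preserving with CV near 0.1
  noisy <- generate_harvest(tr, w, 121, obs_daps = rep(121, 400),
                            noise_cv = 0.1, seed = 10)
  expect_true(all(noisy$ty_obs > 0))
  expect_lt(abs(mean(noisy$ty_obs) / sim$ty_sim - 1), 0.02)
  cv_hat <- stats::sd(noisy$ty_obs) / mean(noisy$ty_obs)
  expect_lt(abs(cv_hat / 0.1 - 1), 0.3)
  expect_error(generate_harvest(tr, w, 121, obs_daps = 200), "beyond")
})

test_that("a full synthetic trial is coherent and reproducible", {
  tr <- simulate_trial(seed = 4)
  expect_s3_class(tr, "synthetic_trial")
  expect_equal(length(tr$plots), 36L)
  expect_equal(nrow(tr$truth), 24L)
  expect_equal(nrow(tr$weather), 141L)
  # every plot's observation days end at its harvest day
  for (pl in tr$plots) {
    expect_equal(max(pl$harvest$dap), pl$harvest_dap)
    expect_equal(nrow(pl$canopy$points), 13L)
    expect_true(all(pl$harvest$ty_obs > 0))
  }
  expect_output(print(tr), "36 plots")
  tr2 <- simulate_trial(seed = 4)
  expect_identical(tr$plots[[9]]$harvest, tr2$plots[[9]]$harvest)
  expect_identical(tr$plots[[9]]$canopy$points, tr2$plots[[9]]$canopy$points)
  expect_error(simulate_trial(obs_frac = c(0.5, 0.9)), "must be 1")
})

test_that("plot jitter perturbs replicate plots while zero jitter keeps them identical", {
  base <- list(n_new = 2, n_checks = 2, n_blocks = 2, new_per_block = 1,
               n_days = 141, flight_daps = seq(21, 91, by = 14),
               noise_sd = 0, noise_cv = 0, seed = 3)
  still <- do.call(simulate_trial, c(base, list(plot_jitter = 0)))
  jit <- do.call(simulate_trial, c(base, list(plot_jitter = 0.04)))
  chk <- function(trial, acc) {
    idx <- which(vapply(trial$plots, function(p) p$accession == acc, logical(1)))
    lapply(trial$plots[idx], function(p) p$canopy$points$cc)
  }
  cc_still <- chk(still, "CHK1")
  cc_jit <- chk(jit, "CHK1")
  expect_identical(cc_still[[1]], cc_still[[2]])
  expect_false(identical(cc_jit[[1]], cc_jit[[2]]))
})
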