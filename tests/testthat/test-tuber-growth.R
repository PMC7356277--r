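test_that("Gompertz partition obeys its closed form and limits", {
  g <- gompertz_params(0.85, 0.004, 450)
  expect_equal(gompertz_partition(450, g), 0.85 / exp(1))
  expect_lt(gompertz_partition(0, g), 0.85 / exp(1))
  expect_equal(gompertz_partition(1e6, g), 0.85)
  tt <- seq(0, 2000, by = 10)
  p <- gompertz_partition(tt, g)
  expect_true(all(diff(p) > 0)) # strictly increasing
  expect_true(all(p > 0 & p < 0.85 + 1e-12))
  expect_error(gompertz_params(1.2, 0.004, 450), "\\(0, 1\\]")
  expect_error(gompertz_params(0.8, -1, 450), "positive")
  expect_error(gompertz_params(0.8, 0.004, -5), "positive")
})

test_that("growth simulation matches a hand calculation under constant forcing", {
  w <- constant_weather(10, par = 5, tmin = 12, tmax = 20) # increment 14/day
  g <- gompertz_params(0.8, 0.01, 70)
  sim <- simulate_growth(w, step_canopy(1), rue = 2, g, plant_area = 0.78,
                         harvest_dap = 10)
  # biomass: 2 g/MJ * 1.0 * 5 MJ/m2/day * 10 days * 0.78 m2 = 78 g/plant
  expect_equal(sim$tb, 78)
  expect_equal(sim$ty_sim, 78 * gompertz_partition(140, g))
  expect_equal(sim$hi, gompertz_partition(140, g))
  expect_equal(nrow(sim$trajectory), 10L)
  # tuber never exceeds biomass along the whole trajectory
  expect_true(all(sim$trajectory$tuber <= sim$trajectory$tb))
  expect_true(all(diff(sim$trajectory$tb) >= 0))
})

test_that("growth scales linearly in RUE and interception fraction", {
  w <- generate_weather(n_days = 120, seed = 5)
  g <- gompertz_params(0.8, 0.004, 450)
  full <- simulate_growth(w, step_canopy(1), 2, g, harvest_dap = 120)
  half_f <- simulate_growth(w, step_canopy(0.5), 2, g, harvest_dap = 120)
  half_rue <- simulate_growth(w, step_canopy(1), 1, g, harvest_dap = 120)
  expect_equal(half_f$tb, full$tb / 2)
  expect_equal(half_rue$tb, full$tb / 2)
  expect_equal(half_f$hi, full$hi) # HI depends only on thermal time pattern
  expect_error(simulate_growth(w, step_canopy(1), 2, g, harvest_dap = 121),
               "beyond")
  expect_error(simulate_growth(w, step_canopy(1), -1, g), "positive")
})

test_that("noiseless calibration recovers the generating parameters", {
  w <- generate_weather(n_days = 141, seed = 11)
  beta <- beta_params(0.85, 450, 880, -4e-4)
  for (case in list(c(rue = 1.4, b = 0.0025, tu = 380),
                    c(rue = 2.8, b = 0.005, tu = 520))) {
    g <- gompertz_params(0.8, case[["b"]], case[["tu"]])
    daps <- c(61, 79, 97, 121)
    sim <- simulate_growth(w, beta, case[["rue"]], g, harvest_dap = 121)
    obs <- data.frame(dap = daps,
                      ty_obs = sim$trajectory$tuber[match(daps,
                                                          sim$trajectory$dap)])
    cal <- calibrate_growth(obs, w, beta,
                            start = list(rue = 2, a_max = 0.8, b = 0.004,
                                         tu = 450))
    expect_lt(abs(cal$rue / case[["rue"]] - 1), 0.01)
    expect_lt(abs(cal$gompertz$tu / case[["tu"]] - 1), 0.01)
    expect_lt(cal$mre_percent, 0.1)
    expect_equal(cal$gompertz$a_max, 0.8) # fixed by default
  }
})

test_that("calibration validates inputs and honors the fixed set", {
  w <- generate_weather(n_days = 100, seed = 1)
  beta <- beta_params(0.8, 400, 800, -3e-4)
  obs <- data.frame(dap = c(60, 80, 100), ty_obs = c(50, 120, 200))
  expect_error(calibrate_growth(obs[0, ], w, beta), "at least one")
  expect_error(
    calibrate_growth(data.frame(dap = 60, ty_obs = -1), w, beta), "positive")
  expect_error(
    calibrate_growth(data.frame(dap = 150, ty_obs = 10), w, beta), "inside")
  expect_error(
    calibrate_growth(obs, w, beta, fixed = c("rue", "a_max", "b", "tu")),
    "at least one parameter")
  cal <- calibrate_growth(obs, w, beta, fixed = c("a_max", "b"))
  expect_setequal(cal$free, c("rue", "tu"))
  expect_equal(cal$gompertz$b, 0.004) # held at its start
})

test_that("tu extraction converts thermal time to days after planting", {
  w <- constant_weather(100, tmin = 12, tmax = 20) # 14 dd/day
  th <- thermal_time(w)
  g <- gompertz_params(0.8, 0.004, 420)
  out <- extract_tu(g, th)
  expect_equal(out$tu, 420)
  expect_equal(out$dap, 30) # 420 / 14
  expect_false(out$beyond_span)
  expect_warning(out2 <- extract_tu(gompertz_params(0.8, 0.004, 5000), th),
                 "beyond")
  expect_true(out2$beyond_span)
  expect_true(is.na(out2$dap))
  # without a table only tu is reported
  expect_true(is.na(extract_tu(g)$dap))
})
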