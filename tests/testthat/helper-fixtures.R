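# Shared fixtures, all built in code.

# Weather with constant temperatures and PAR: thermal increment
# (tmin + tmax)/2 - t_base per day.
constant_weather <- function(n_days, par = 5, tmin = 12, tmax = 20) {
  structure(data.frame(dap = seq_len(n_days),
                       date = as.Date("2017-07-05") + seq_len(n_days),
                       par_inc = par, tmin = tmin, tmax = tmax),
            class = c("weather_series", "data.frame"))
}

# A step-like canopy: full (or fractional) interception from the first day.
# te is made negligible so every simulated day sits on the flat segment.
step_canopy <- function(level = 1) {
  beta_params(cc_max = level, tm = 1e-7, te = 2e-7, decline_slope = 0)
}

# Raster with an exact number of vegetation pixels, endmember spectra.
mixture_raster <- function(n_veg, n_pix = 64^2, dim_side = 64,
                           spectra = endmember_spectra()) {
  stopifnot(n_veg <= n_pix)
  mk <- function(band) {
    v <- rep(spectra$soil[[band]], n_pix)
    if (n_veg > 0) v[seq_len(n_veg)] <- spectra$vegetation[[band]]
    matrix(v, dim_side, n_pix / dim_side)
  }
  list(green = mk("green"), red = mk("red"), nir = mk("nir"))
}

# Random augmented design + normal trait values for DAU property tests.
random_dau_case <- function(seed, n_blocks = 3, n_checks = 3, new_per_block = 4) {
  withr::with_seed(seed, {
    n_new <- n_blocks * new_per_block
    design <- data.frame(
      accession = c(sprintf("N%02d", seq_len(n_new)),
                    rep(sprintf("C%d", seq_len(n_checks)), n_blocks)),
      block = c(rep(seq_len(n_blocks), each = new_per_block),
                rep(seq_len(n_blocks), each = n_checks)),
      is_check = rep(c(FALSE, TRUE), c(n_new, n_blocks * n_checks)))
    block_eff <- rnorm(n_blocks, 0, 3)
    acc_eff <- rnorm(n_new + n_checks, 0, 5)
    names(acc_eff) <- unique(design$accession)
    y <- 50 + acc_eff[design$accession] + block_eff[design$block] +
      rnorm(nrow(design), 0, 1)
    list(design = design, y = unname(y))
  })
}

# Least-squares oracle for adjusted means: accession + block fixed effects,
# predictions averaged over all blocks.
lm_adjusted_means <- function(design, y) {
  df <- data.frame(accession = design$accession,
                   block = factor(design$block), y = y)
  fit <- stats::lm(y ~ accession + block, data = df)
  grid <- expand.grid(accession = unique(df$accession),
                      block = levels(df$block))
  pred <- stats::predict(fit, grid)
  tapply(pred, grid$accession, mean)
}
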