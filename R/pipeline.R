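# Pipeline orchestration and validated table I/O.
#
# run_pipeline() chains the full analysis over a synthetic (or user-supplied)
# trial: canopy extraction -> Beta canopy fit -> radiation interception ->
# growth-model calibration -> efficiencies -> trait table -> augmented-design
# adjusted means -> correlations, PCA, Ward clusters and yield-on-PC
# regression. All randomness flows from the seeds in the configuration; a
# rerun with the same configuration reproduces every number.

#' Pipeline configuration
#'
#' @param seed master seed driving trial generation and calibration starts.
#' @param n_new,n_checks,n_blocks,new_per_block trial dimensions.
#' @param noise_sd reflectance noise SD; `0` for a noiseless trial.
#' @param noise_cv tuber-mass observation noise CV; `0` for noiseless.
#' @param plot_jitter per-plot canopy variability, see [simulate_trial()].
#' @param dispersion weather day-to-day dispersion multiplier.
#' @param threshold,L SAVI segmentation settings.
#' @param t_base base temperature, degrees C.
#' @param plant_area ground area per plant, m^2.
#' @param patch_dim plot raster side, pixels.
#' @param obs_frac tuber observation times as fractions of harvest day.
#' @param fix_a_max calibrate with the Gompertz asymptote fixed at each
#'   accession's configured value (the asymptote is not identifiable from
#'   tuber mass alone; see [calibrate_growth()]).
#' @param n_pcs number of principal components retained for clustering and
#'   regression.
#' @param k_clusters number of Ward groups.
#' @param outdir optional directory for CSV/JSON outputs.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_new = 20L, n_checks = 4L,
                            n_blocks = 4L, new_per_block = 5L,
                            noise_sd = 0.01, noise_cv = 0.1,
                            plot_jitter = 0.04, dispersion = 1,
                            threshold = 0.3, L = 0.5, t_base = 2,
                            plant_area = 0.78, patch_dim = 64L,
                            obs_frac = c(0.5, 0.65, 0.8, 1),
                            fix_a_max = TRUE, n_pcs = 3L, k_clusters = 3L,
                            outdir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, accession = NULL, expr) {
  tryCatch(expr, error = function(e) {
    where <- if (is.null(accession)) name else
      sprintf("%s [accession %s]", name, accession)
    abort("pipeline stage '%s' failed: %s", where, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a trial, analyses every plot, and assembles the
#' trait table and multivariate statistics.
#'
#' @param config a [pipeline_config()].
#' @param trial optional pre-built [simulate_trial()] bundle; by default one
#'   is generated from the configuration.
#' @return a list of class `rue_pipeline`: `trial`, `plot_results` (per-plot
#'   data frame), `trait_table` (adjusted means per accession), `dau`
#'   (per-trait [dau_analysis()] results), `correlations`, `pca`, `clusters`,
#'   `regression`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), trial = NULL) {
  cfg <- config
  if (is.null(trial)) {
    trial <- stage("simulate", NULL, simulate_trial(
      n_new = cfg$n_new, n_checks = cfg$n_checks, n_blocks = cfg$n_blocks,
      new_per_block = cfg$new_per_block, dispersion = cfg$dispersion,
      noise_sd = cfg$noise_sd, noise_cv = cfg$noise_cv,
      plot_jitter = cfg$plot_jitter,
      patch_dim = cfg$patch_dim, obs_frac = cfg$obs_frac,
      plant_area = cfg$plant_area, t_base = cfg$t_base, seed = cfg$seed))
  }
  weather <- trial$weather
  th <- thermal_time(weather, cfg$t_base)
  cal_seeds <- derive_seeds(cfg$seed + 1L, length(trial$plots))

  rows <- lapply(seq_along(trial$plots), function(i) {
    pl <- trial$plots[[i]]
    acc <- pl$accession
    fit <- stage("fit-canopy", acc,
                 fit_beta_canopy(pl$canopy$points, th))
    rad <- stage("interception", acc,
                 radiation_summary(weather, fit$params, pl$harvest_dap,
                                   cfg$t_base))
    tr <- trial$truth[trial$truth$accession == acc, ]
    start <- list(rue = 2,
                  a_max = if (cfg$fix_a_max) tr$a_max else 0.8,
                  b = 0.004, tu = 450)
    cal <- stage("calibrate", acc, calibrate_growth(
      pl$harvest[, c("dap", "ty_obs")], weather, fit$params, start = start,
      fixed = if (cfg$fix_a_max) "a_max" else character(0),
      plant_area = cfg$plant_area, t_base = cfg$t_base,
      seed = cal_seeds[i]))
    growth <- stage("simulate-growth", acc, simulate_growth(
      weather, fit$params, cal$rue, cal$gompertz, cfg$plant_area,
      pl$harvest_dap, cfg$t_base))
    slp <- stage("ndvi-slope", acc, ndvi_senescence_slope(pl$canopy$points))
    ty_obs <- pl$harvest$ty_obs[which.max(pl$harvest$dap)]
    eff <- stage("efficiencies", acc, efficiency_set(
      acc, rad, growth, ty = ty_obs, plant_area = cfg$plant_area))
    data.frame(accession = acc, block = pl$block, is_check = pl$is_check,
               harvest_dap = pl$harvest_dap,
               ty = ty_obs, tb = growth$tb, hi = growth$hi,
               rue = cal$rue, mre_percent = cal$mre_percent,
               tu = cal$gompertz$tu,
               epsilon_i = eff$epsilon_i, epsilon_c = eff$epsilon_c,
               epsilon_p = eff$epsilon_p, par_int = eff$par_int,
               ndvi_slp = slp$slope,
               a = pl$a_obs %||% tr$a_mean,
               delta_leaf = pl$delta_leaf_obs %||% tr$delta_leaf)
  })
  plot_results <- do.call(rbind, rows)

  traits <- c("ty", "epsilon_i", "epsilon_c", "epsilon_p", "a", "delta_leaf",
              "ndvi_slp", "tu")
  dau <- lapply(stats::setNames(traits, traits), function(tr_name) {
    stage(paste0("dau-", tr_name), NULL,
          dau_analysis(plot_results, plot_results[[tr_name]]))
  })
  trait_table <- Reduce(function(a, b) merge(a, b, by = c("accession", "is_check")),
                        lapply(traits, function(tr_name) {
                          am <- dau[[tr_name]]$adjusted_means
                          stats::setNames(am[c("accession", "is_check", "adjusted")],
                                          c("accession", "is_check", tr_name))
                        }))

  pca_traits <- c("epsilon_i", "epsilon_c", "epsilon_p", "a", "delta_leaf",
                  "ndvi_slp", "tu")
  correlations <- stage("correlations", NULL,
                        pearson_matrix(trait_table, c("ty", pca_traits)))
  pca <- stage("pca", NULL, trait_pca(trait_table, pca_traits))
  retained <- pca$scores[, seq_len(cfg$n_pcs), drop = FALSE]
  clusters <- stage("cluster", NULL, ward_cluster(retained, cfg$k_clusters))
  keep <- match(rownames(retained), trait_table$accession)
  regression <- stage("regression", NULL,
                      regress_on_pcs(trait_table$ty[keep], pca$scores,
                                     cfg$n_pcs))

  manifest <- list(package = "potatoRUE",
                   version = as.character(utils::packageVersion("potatoRUE")),
                   seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg), "outdir")])
  out <- structure(list(trial = trial, plot_results = plot_results,
                        trait_table = trait_table, dau = dau,
                        correlations = correlations, pca = pca,
                        clusters = clusters, regression = regression,
                        manifest = manifest),
                   class = "rue_pipeline")
  if (!is.null(cfg$outdir)) write_pipeline_outputs(out, cfg$outdir)
  out
}

#' @export
print.rue_pipeline <- function(x, ...) {
  cat(sprintf("Radiation-efficiency pipeline: %d plots, %d accessions\n",
              nrow(x$plot_results), nrow(x$trait_table)))
  print(x$pca)
  print(x$regression)
  invisible(x)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(
    df, file.path(outdir, name), row.names = FALSE)
  w(result$trial$weather, "weather.csv")
  w(as.data.frame(result$trial$design), "design.csv")
  w(result$plot_results, "plot_results.csv")
  w(result$trait_table, "trait_table.csv")
  w(as.data.frame(result$correlations), "correlations.csv")
  w(as.data.frame(result$pca$loadings), "pca_loadings.csv")
  w(data.frame(accession = names(result$clusters$assignments),
               group = result$clusters$assignments), "clusters.csv")
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

# ---- validated table I/O ----------------------------------------------------

check_columns <- function(df, schema, what, path) {
  missing <- setdiff(names(schema), names(df))
  assert_that(length(missing) == 0, "%s file '%s' missing column(s): %s",
              what, path, paste(missing, collapse = ", "))
  for (col in names(schema)) {
    v <- df[[col]]
    assert_that(is.numeric(v) || schema[[col]]$type != "numeric",
                "%s file '%s': column %s must be numeric", what, path, col)
    bad <- which(!schema[[col]]$ok(v))
    assert_that(length(bad) == 0, "%s file '%s': row %d, column %s: %s",
                what, path, if (length(bad)) bad[1] else 0L, col,
                schema[[col]]$msg)
  }
  invisible(df)
}

#' Read a validated weather table
#'
#' Expects columns `dap`, `par_inc`, `tmin`, `tmax`; validation errors name
#' the offending row and column.
#'
#' @param path CSV file path.
#' @return a `weather_series` data frame.
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path)
  schema <- list(
    dap = list(type = "numeric", ok = function(v) is.finite(v) & v >= 1,
               msg = "dap must be >= 1"),
    par_inc = list(type = "numeric", ok = function(v) is.finite(v) & v >= 0,
                   msg = "par_inc must be >= 0"),
    tmin = list(type = "numeric", ok = function(v) is.finite(v),
                msg = "tmin must be finite"),
    tmax = list(type = "numeric", ok = function(v) is.finite(v),
                msg = "tmax must be finite"))
  check_columns(df, schema, "weather", path)
  bad <- which(df$tmin > df$tmax)
  assert_that(length(bad) == 0,
              "weather file '%s': row %d, column tmin: tmin exceeds tmax",
              path, if (length(bad)) bad[1] else 0L)
  gaps <- which(diff(df$dap) != 1)
  assert_that(length(gaps) == 0,
              "weather file '%s': row %d, column dap: daps must increase by 1",
              path, if (length(gaps)) gaps[1] + 1L else 0L)
  class(df) <- c("weather_series", "data.frame")
  df
}

#' Write a weather table
#'
#' @param weather a `weather_series` data frame.
#' @param path CSV file path.
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(as.data.frame(weather), path, row.names = FALSE)
  invisible(path)
}

#' Read a validated plot-reflectance table
#'
#' Expects columns `dap`, `green`, `red`, `nir` (plot-mean reflectances in
#' `[0, 1]`), one row per flight.
#'
#' @param path CSV file path.
#' @return a data frame of per-flight plot reflectances.
#' @export
read_reflectance_csv <- function(path) {
  df <- utils::read.csv(path)
  in01 <- function(v) is.finite(v) & v >= 0 & v <= 1
  schema <- list(
    dap = list(type = "numeric", ok = function(v) is.finite(v) & v >= 1,
               msg = "dap must be >= 1"),
    green = list(type = "numeric", ok = in01, msg = "reflectance outside [0, 1]"),
    red = list(type = "numeric", ok = in01, msg = "reflectance outside [0, 1]"),
    nir = list(type = "numeric", ok = in01, msg = "reflectance outside [0, 1]"))
  check_columns(df, schema, "reflectance", path)
  df
}

#' Read a validated canopy-point table
#'
#' Expects columns `dap`, `cc`, `ndvi`.
#'
#' @param path CSV file path.
#' @return a [canopy_points()] series.
#' @export
read_canopy_csv <- function(path) {
  df <- utils::read.csv(path)
  schema <- list(
    dap = list(type = "numeric", ok = function(v) is.finite(v) & v >= 1,
               msg = "dap must be >= 1"),
    cc = list(type = "numeric", ok = function(v) is.finite(v) & v >= 0 & v <= 1,
              msg = "cc outside [0, 1]"),
    ndvi = list(type = "numeric",
                ok = function(v) is.na(v) | (v >= -1 & v <= 1),
                msg = "ndvi outside [-1, 1]"))
  check_columns(df, schema, "canopy", path)
  canopy_points(df$dap, df$cc, df$ndvi)
}

#' Write a canopy-point table
#'
#' @param points a [canopy_points()] series.
#' @param path CSV file path.
#' @export
write_canopy_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}
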