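# Vegetation indices and SAVI-threshold canopy segmentation.
#
# Plots are observed as three-band (green, red, near-infrared) reflectance
# rasters or plot-mean reflectances in [0, 1]. Canopy cover is the fraction of
# pixels whose soil-adjusted vegetation index exceeds a threshold; NDVI is
# summarized as the plot mean of per-pixel values.

#' Normalized difference vegetation index
#'
#' @param nir near-infrared reflectance(s), in `[0, 1]`.
#' @param red red reflectance(s), in `[0, 1]`.
#' @return NDVI = (nir - red) / (nir + red), in `[-1, 1]`. Vectorized.
#' @export
#' @examples
#' compute_ndvi(0.6, 0.1)
compute_ndvi <- function(nir, red) {
  assert_that(all(nir >= 0) && all(red >= 0),
              "reflectances must be non-negative")
  s <- nir + red
  assert_that(all(s > 0), "nir + red must be positive (undefined NDVI)")
  (nir - red) / s
}

#' Soil-adjusted vegetation index
#'
#' @inheritParams compute_ndvi
#' @param L soil-brightness correction factor; 0.5 is the standard value for
#'   intermediate vegetation densities.
#' @return SAVI = (nir - red) (1 + L) / (nir + red + L). Vectorized.
#' @export
compute_savi <- function(nir, red, L = 0.5) {
  assert_that(all(nir >= 0) && all(red >= 0),
              "reflectances must be non-negative")
  assert_that(is_number(L) && L > 0, "L must be a positive scalar")
  (nir - red) * (1 + L) / (nir + red + L)
}

# Coerce a raster given as a [rows, cols, 3] array (bands green, red, nir) or
# a list(green =, red =, nir =) of matrices into the list form.
as_band_list <- function(raster) {
  if (is.list(raster) && all(c("green", "red", "nir") %in% names(raster))) {
    return(raster[c("green", "red", "nir")])
  }
  if (is.array(raster) && length(dim(raster)) == 3L && dim(raster)[3] == 3L) {
    bands <- dimnames(raster)[[3]]
    if (is.null(bands)) bands <- c("green", "red", "nir")
    out <- list(raster[, , 1], raster[, , 2], raster[, , 3])
    names(out) <- bands
    return(out[c("green", "red", "nir")])
  }
  abort("raster must be a [rows, cols, 3] array or a list(green, red, nir)")
}

#' Canopy cover by SAVI-threshold segmentation
#'
#' Classifies each pixel as vegetation when its SAVI strictly exceeds the
#' threshold (ties count as soil) and returns the vegetation fraction.
#'
#' @param raster a `[rows, cols, 3]` array with bands green, red, nir, or a
#'   `list(green =, red =, nir =)` of reflectance matrices.
#' @param threshold SAVI cutoff separating vegetation from soil, or `"otsu"`
#'   for an automatic bimodal threshold.
#' @param L soil factor passed to [compute_savi()].
#' @return canopy-cover fraction in `[0, 1]`.
#' @export
segment_canopy_cover <- function(raster, threshold = 0.3, L = 0.5) {
  bands <- as_band_list(raster)
  n <- length(bands$nir)
  assert_that(n > 0, "empty raster")
  savi <- compute_savi(as.numeric(bands$nir), as.numeric(bands$red), L)
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(savi)
  assert_that(is_number(threshold), "threshold must be finite or \"otsu\"")
  mean(savi > threshold)
}

# Otsu's method on a 256-bin histogram of index values.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Plot-mean NDVI
#'
#' Arithmetic mean of per-pixel NDVI over a plot raster, optionally restricted
#' to a logical mask.
#'
#' @inheritParams segment_canopy_cover
#' @param mask optional logical matrix selecting pixels; `NULL` uses the whole
#'   plot.
#' @return mean NDVI of the selected region.
#' @export
plot_mean_index <- function(raster, mask = NULL) {
  bands <- as_band_list(raster)
  nir <- as.numeric(bands$nir)
  red <- as.numeric(bands$red)
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    assert_that(length(keep) == length(nir), "mask dimensions must match raster")
    nir <- nir[keep]
    red <- red[keep]
  }
  assert_that(length(nir) > 0, "empty region")
  mean(compute_ndvi(nir, red))
}

#' Extract per-flight canopy points from rasters
#'
#' Applies [segment_canopy_cover()] and [plot_mean_index()] to one raster per
#' flight, producing the canopy-cover / NDVI time series consumed by the
#' canopy-dynamics fit.
#'
#' @param rasters list of per-flight rasters (see [segment_canopy_cover()]).
#' @param daps integer days after planting of each flight.
#' @inheritParams segment_canopy_cover
#' @return a `data.frame` with columns `dap`, `cc`, `ndvi` (one row per
#'   flight), of class `canopy_points`.
#' @export
extract_canopy_points <- function(rasters, daps, threshold = 0.3, L = 0.5) {
  assert_that(length(rasters) == length(daps),
              "one raster per flight dap required")
  cc <- vapply(rasters, segment_canopy_cover, numeric(1),
               threshold = threshold, L = L)
  ndvi <- vapply(rasters, plot_mean_index, numeric(1))
  canopy_points(daps, cc, ndvi)
}

#' Construct a canopy-point series
#'
#' @param dap integer days after planting (one per flight).
#' @param cc canopy-cover fractions in `[0, 1]`.
#' @param ndvi plot-mean NDVI values in `[-1, 1]`.
#' @return a validated `canopy_points` data frame.
#' @export
canopy_points <- function(dap, cc, ndvi = NA_real_) {
  df <- data.frame(dap = as.integer(dap), cc = cc, ndvi = ndvi)
  assert_that(!anyDuplicated(df$dap), "one canopy point per flight dap")
  assert_that(all(df$cc >= 0 & df$cc <= 1), "cc must lie in [0, 1]")
  assert_that(all(is.na(df$ndvi) | (df$ndvi >= -1 & df$ndvi <= 1)),
              "ndvi must lie in [-1, 1]")
  df <- df[order(df$dap), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("canopy_points", "data.frame")
  df
}
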