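#' Calibrate a thermal raster against ground targets
#'
#' Ordinary least-squares line mapping camera digital numbers (DN) to target
#' temperatures measured by ground thermoradiometers. Applied pixel-wise it
#' converts DN rasters to deg C.
#'
#' @param dn digital numbers of the calibration targets (>= 2, not constant)
#' @param temperature matching target temperatures (deg C)
#' @return list of class `thermal_calibration`: `slope`, `intercept`,
#'   `r_squared`, `n`
#' @export
calibrate_thermal <- function(dn, temperature) {
  if (length(dn) != length(temperature))
    stopf("'dn' and 'temperature' must have the same length")
  if (length(dn) < 2) stopf("need at least 2 calibration targets")
  if (sd(dn) == 0) stopf("constant DN across targets: singular fit")
  fit <- lm(temperature ~ dn)
  r2 <- if (sd(temperature) == 0) 1 else cor(dn, temperature)^2
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n = length(dn)),
            class = "thermal_calibration")
}

#' @describeIn calibrate_thermal convert a DN raster to deg C
#' @param r a [phen_raster()] of digital numbers
#' @param cal a `thermal_calibration`
#' @export
apply_thermal_calibration <- function(r, cal) {
  stopifnot(inherits(r, "phen_raster"), inherits(cal, "thermal_calibration"))
  phen_raster(cal$intercept + cal$slope * r$values,
              xmin = r$xmin, ymin = r$ymin, pixel_size = r$pixel_size)
}

#' Per-pixel vegetation indices from a reflectance stack
#'
#' Computes NDVI, GNDVI, MCARI2 and PRI from the 850/675/570/530 nm bands:
#' \itemize{
#' \item NDVI = (rho850 - rho675) / (rho850 + rho675)
#' \item GNDVI = (rho850 - rho570) / (rho850 + rho570) (570 nm green; the
#'   530 nm band is reserved for PRI; configurable via `gndvi_green`)
#' \item PRI = (rho530 - rho570) / (rho530 + rho570)
#' \item MCARI2 = 1.5 (2.5 (rho850 - rho675) - 1.3 (rho850 - rho570)) /
#'   sqrt((2 rho850 + 1)^2 - (6 rho850 - 5 sqrt(rho675)) - 0.5)
#' }
#' Pixels whose denominator vanishes are set to `NA`.
#'
#' @param stack a [band_stack()] with the six standard bands
#' @param gndvi_green wavelength (nm) of the green band used by GNDVI
#' @return named list of index matrices (`NDVI`, `GNDVI`, `MCARI2`, `PRI`)
#' @export
compute_indices <- function(stack, gndvi_green = 570) {
  stopifnot(inherits(stack, "band_stack"))
  nir <- get_band(stack, 850)
  red <- get_band(stack, 675)
  g570 <- get_band(stack, 570)
  g530 <- get_band(stack, 530)
  green <- get_band(stack, gndvi_green)
  nd <- function(a, b) {
    den <- a + b
    out <- (a - b) / den
    out[den == 0] <- NA
    out
  }
  mc_den <- (2 * nir + 1)^2 - (6 * nir - 5 * sqrt(red)) - 0.5
  mc_den <- suppressWarnings(sqrt(mc_den))
  mcari2 <- 1.5 * (2.5 * (nir - red) - 1.3 * (nir - g570)) / mc_den
  mcari2[!is.finite(mcari2)] <- NA
  list(NDVI = nd(nir, red), GNDVI = nd(nir, green), MCARI2 = mcari2,
       PRI = nd(g530, g570))
}

#' Classify vegetation pixels by NDVI threshold
#'
#' A pixel is vegetation when its NDVI exceeds the threshold (default 0.3);
#' the mask restricts canopy-temperature statistics to foliage.
#'
#' @inheritParams compute_indices
#' @param threshold NDVI cut-off
#' @return logical matrix (`TRUE` = vegetation; `NA` NDVI gives `FALSE`)
#' @export
classify_vegetation <- function(stack, threshold = 0.3) {
  ndvi <- compute_indices(stack)$NDVI
  mask <- ndvi > threshold
  mask[is.na(mask)] <- FALSE
  mask
}

#' Extract the buffer-zone pixels around one tree
#'
#' Collects every pixel whose centre lies within `radius` of the tree centre
#' (default 0.70 m, the buffer radius of the study this package models), with
#' its band reflectances, surface temperature and vegetation flag.
#'
#' @inheritParams compute_indices
#' @param thermal a [phen_raster()] of surface temperatures (deg C)
#' @param center numeric `c(x, y)` tree centre in meters
#' @param radius buffer radius in meters
#' @param ndvi_threshold vegetation classification threshold
#' @param tree_id identifier copied into the result
#' @return data frame of class `tree_pixel_set`: one row per buffer pixel
#'   with columns `x`, `y`, one per band, `t_surf`, `ndvi`, `vegetation`;
#'   attributes `tree_id`, `radius`, `pix_num` (vegetation pixel count).
#'   Empty (buffer outside the raster) gives a zero-row frame with a warning.
#' @export
extract_buffer <- function(stack, thermal, center, radius = 0.70,
                           ndvi_threshold = 0.3, tree_id = NA_character_) {
  stopifnot(inherits(stack, "band_stack"), inherits(thermal, "phen_raster"))
  if (!identical(dim(stack$bands[[1]]), dim(thermal$values)))
    stopf("band stack and thermal raster shapes differ")
  cc <- raster_centers(thermal)
  sel <- (cc$x - center[1])^2 + (cc$y - center[2])^2 <= radius^2
  idx <- which(sel)
  if (length(idx) == 0)
    warnf("buffer at (%g, %g) contains no pixel (outside raster?)",
          center[1], center[2])
  ind <- compute_indices(stack)
  df <- data.frame(x = cc$x[idx], y = cc$y[idx])
  for (b in names(stack$bands)) df[[paste0("b", b)]] <- stack$bands[[b]][idx]
  df$t_surf <- thermal$values[idx]
  df$ndvi <- ind$NDVI[idx]
  df$gndvi <- ind$GNDVI[idx]
  df$mcari2 <- ind$MCARI2[idx]
  df$pri <- ind$PRI[idx]
  df$vegetation <- !is.na(df$ndvi) & df$ndvi > ndvi_threshold
  attr(df, "tree_id") <- tree_id
  attr(df, "radius") <- radius
  attr(df, "pix_num") <- sum(df$vegetation)
  class(df) <- c("tree_pixel_set", "data.frame")
  df
}

#' Canopy temperature statistics for one tree
#'
#' Mean and sample (n - 1) standard deviation of the surface-to-air
#' temperature difference over the vegetation pixels of the buffer.
#'
#' @param pixels a [extract_buffer()] result
#' @param t_air mean air temperature during acquisition (deg C)
#' @return list `mean`, `sd` (deg C; `NA` with zero vegetation pixels) and
#'   `n` (vegetation pixel count)
#' @export
tree_temperature <- function(pixels, t_air) {
  stopifnot(inherits(pixels, "tree_pixel_set"))
  dt <- pixels$t_surf[pixels$vegetation] - t_air
  if (length(dt) == 0)
    return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(dt), sd = if (length(dt) > 1) sd(dt) else NA_real_,
       n = length(dt))
}

#' Construct or fit the WDI trapezoid
#'
#' The Water Deficit Index is read off a trapezoid in (NDVI, Tsurf - Tair)
#' space whose four corners are the saturated-bare-soil, well-watered-
#' vegetation, dry-bare-soil and water-stressed-vegetation conditions. In
#' automatic mode the NDVI edge abscissae are percentiles of the pixel NDVI
#' distribution and the wet/dry edges are straight lines fitted through
#' per-NDVI-bin temperature percentiles. In manual mode the four vertex
#' temperatures are supplied directly (e.g. values estimated on another
#' flight).
#'
#' @param ndvi per-pixel NDVI values (soil and vegetation together)
#' @param dt per-pixel Tsurf - Tair (deg C)
#' @param vertices manual mode: `c(t_sat_soil, t_ww_veg, t_dry_soil,
#'   t_ws_veg)` in deg C
#' @param ndvi_edges NDVI abscissae of the soil and vegetation edges; in
#'   automatic mode taken as the `ndvi_probs` percentiles
#' @param ndvi_probs percentiles defining the soil/vegetation edges
#' @param temp_probs per-bin temperature percentiles tracing the wet and dry
#'   edges
#' @param n_bins number of NDVI bins for the edge fits
#' @param min_bin_n minimum pixels for a bin to enter the edge regression
#' @return object of class `wdi_trapezoid` with fields `t_sat_soil`,
#'   `t_ww_veg`, `t_dry_soil`, `t_ws_veg`, `ndvi_soil`, `ndvi_veg`, `mode`
#' @export
fit_trapezoid <- function(ndvi = NULL, dt = NULL, vertices = NULL,
                          ndvi_edges = NULL, ndvi_probs = c(0.05, 0.95),
                          temp_probs = c(0.025, 0.975), n_bins = 20,
                          min_bin_n = 5) {
  if (!is.null(vertices)) {
    if (length(vertices) != 4)
      stopf("manual mode needs 4 vertex temperatures (t_sat_soil, t_ww_veg, t_dry_soil, t_ws_veg)")
    if (is.null(ndvi_edges)) ndvi_edges <- c(0.05, 0.9)
    trap <- list(t_sat_soil = vertices[1], t_ww_veg = vertices[2],
                 t_dry_soil = vertices[3], t_ws_veg = vertices[4],
                 ndvi_soil = ndvi_edges[1], ndvi_veg = ndvi_edges[2],
                 mode = "manual")
    return(validate_trapezoid(trap))
  }
  ok <- is.finite(ndvi) & is.finite(dt)
  ndvi <- ndvi[ok]; dt <- dt[ok]
  if (length(ndvi) < 100)
    stopf("trapezoid fit needs >= 100 pixels spanning soil and vegetation (got %d)",
          length(ndvi))
  edges <- quantile(ndvi, ndvi_probs, names = FALSE)
  if (diff(edges) <= 0)
    stopf("pixels do not span an NDVI range (all at one NDVI?)")
  brk <- seq(edges[1], edges[2], length.out = n_bins + 1)
  bin <- cut(ndvi, brk, include.lowest = TRUE, labels = FALSE)
  ctr <- (brk[-1] + brk[-length(brk)]) / 2
  stats <- lapply(seq_len(n_bins), function(b) {
    v <- dt[which(bin == b)]
    if (length(v) < min_bin_n) return(NULL)
    q <- quantile(v, temp_probs, names = FALSE)
    # percentile pair extrapolated to the 0/100 edges under the trapezoid's
    # own uniform-fill model, so interior percentiles do not bias the edges
    # inward while staying robust to stray pixels (unlike a raw min/max)
    slope <- (q[2] - q[1]) / (temp_probs[2] - temp_probs[1])
    data.frame(ndvi = ctr[b],
               wet = q[1] - temp_probs[1] * slope,
               dry = q[2] + (1 - temp_probs[2]) * slope)
  })
  stats <- do.call(rbind, stats)
  if (is.null(stats) || nrow(stats) < 3)
    stopf("trapezoid fit needs >= 3 usable NDVI bins (got %d)",
          if (is.null(stats)) 0 else nrow(stats))
  wet_fit <- lm(wet ~ ndvi, data = stats)
  dry_fit <- lm(dry ~ ndvi, data = stats)
  at <- function(fit, x) unname(coef(fit)[1] + coef(fit)[2] * x)
  trap <- list(t_sat_soil = at(wet_fit, edges[1]),
               t_ww_veg = at(wet_fit, edges[2]),
               t_dry_soil = at(dry_fit, edges[1]),
               t_ws_veg = at(dry_fit, edges[2]),
               ndvi_soil = edges[1], ndvi_veg = edges[2], mode = "auto")
  validate_trapezoid(trap)
}

validate_trapezoid <- function(trap) {
  if (trap$ndvi_soil >= trap$ndvi_veg)
    stopf("trapezoid geometry error: ndvi_soil must be < ndvi_veg")
  if (trap$t_sat_soil >= trap$t_dry_soil || trap$t_ww_veg >= trap$t_ws_veg)
    stopf("trapezoid geometry error: wet edge lies above the dry edge")
  structure(trap, class = "wdi_trapezoid")
}

#' @export
print.wdi_trapezoid <- function(x, ...) {
  cat(sprintf(paste0("<wdi_trapezoid> (%s) soil NDVI %.3f: wet %.2f / dry ",
                     "%.2f degC; veg NDVI %.3f: wet %.2f / dry %.2f degC\n"),
              x$mode, x$ndvi_soil, x$t_sat_soil, x$t_dry_soil, x$ndvi_veg,
              x$t_ww_veg, x$t_ws_veg))
  invisible(x)
}

#' Water Deficit Index
#'
#' Position of a pixel (or of a tree's mean NDVI / mean Tsurf - Tair) between
#' the wet and dry edges of the trapezoid: 0 = maximal transpiration (on the
#' wet edge), 1 = no transpiration (on the dry edge). Values are clipped to
#' \[0, 1\] since observed pixels may fall slightly outside the fitted
#' trapezoid.
#'
#' @param ndvi NDVI value(s)
#' @param dt Tsurf - Tair value(s) in deg C
#' @param trap a [fit_trapezoid()] result
#' @return WDI value(s) in \[0, 1\]
#' @export
compute_wdi <- function(ndvi, dt, trap) {
  stopifnot(inherits(trap, "wdi_trapezoid"))
  f <- (ndvi - trap$ndvi_soil) / (trap$ndvi_veg - trap$ndvi_soil)
  # convex form so the vertices are reproduced exactly at the edges
  t_wet <- (1 - f) * trap$t_sat_soil + f * trap$t_ww_veg
  t_dry <- (1 - f) * trap$t_dry_soil + f * trap$t_ws_veg
  span <- t_dry - t_wet
  if (any(span <= 1e-12))
    stopf("degenerate trapezoid edge: T_dry = T_wet at NDVI %g",
          ndvi[which(span <= 1e-12)[1]])
  pmin(pmax((dt - t_wet) / span, 0), 1)
}

#' Per-tree imagery summary
#'
#' Full imagery stage for a set of trees: buffer extraction, vegetation
#' classification, temperature statistics, mean multispectral indices (over
#' all buffer pixels) and WDI evaluated at the tree's mean NDVI and mean
#' Tsurf - Tair (vegetation pixels).
#'
#' @inheritParams extract_buffer
#' @param trees data frame with columns `tree_id`, `x`, `y`
#' @param t_air mean air temperature (deg C)
#' @param trap a [fit_trapezoid()] result, or `NULL` to fit one automatically
#'   from all raster pixels
#' @return data frame: `tree_id`, `pix_num`, `t_diff_mean`, `t_diff_sd`,
#'   `NDVI`, `GNDVI`, `MCARI2`, `PRI`, `WDI`
#' @export
tree_summary <- function(stack, thermal, trees, t_air, radius = 0.70,
                         ndvi_threshold = 0.3, trap = NULL) {
  if (is.null(trap)) {
    ind <- compute_indices(stack)
    trap <- fit_trapezoid(ndvi = as.vector(ind$NDVI),
                          dt = as.vector(thermal$values) - t_air)
  }
  rows <- lapply(seq_len(nrow(trees)), function(i) {
    px <- extract_buffer(stack, thermal, c(trees$x[i], trees$y[i]),
                         radius = radius, ndvi_threshold = ndvi_threshold,
                         tree_id = trees$tree_id[i])
    tstat <- tree_temperature(px, t_air)
    mean_ndvi <- mean(px$ndvi, na.rm = TRUE)
    wdi <- if (is.na(tstat$mean)) NA_real_ else
      compute_wdi(mean_ndvi, tstat$mean, trap)
    data.frame(tree_id = trees$tree_id[i], pix_num = attr(px, "pix_num"),
               t_diff_mean = tstat$mean, t_diff_sd = tstat$sd,
               NDVI = mean_ndvi, GNDVI = mean(px$gndvi, na.rm = TRUE),
               MCARI2 = mean(px$mcari2, na.rm = TRUE),
               PRI = mean(px$pri, na.rm = TRUE), WDI = wdi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
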