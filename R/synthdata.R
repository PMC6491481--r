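#' Specification of a synthetic tree crown
#'
#' Describes one simulated crown: leaves are planar disks of fixed radius
#' scattered inside an ellipsoidal envelope, optionally clumped into clusters.
#' The ground-truth total leaf area (TLA) is `n_leaves * pi * leaf_radius^2`
#' and the envelope volume is `4/3 * pi * a * b * c`.
#'
#' @param n_leaves number of leaf disks (>= 0)
#' @param leaf_radius disk radius in meters (> 0)
#' @param semi_axes ellipsoid semi-axes (a, b, c) in meters
#' @param clumping dispersion parameter in \[0, 1\]: 0 = leaves uniform in the
#'   envelope, 1 = all leaves drawn from a few Gaussian clusters
#' @param n_clusters number of clump centres used when `clumping > 0`
#' @param points_per_leaf LiDAR-like returns sampled on each disk
#' @param seed integer seed (generation is bit-reproducible under a fixed seed)
#' @return object of class `crown_spec`
#' @export
crown_spec <- function(n_leaves = 1000, leaf_radius = 0.05,
                       semi_axes = c(1, 1, 1.2), clumping = 0,
                       n_clusters = 8, points_per_leaf = 5, seed = NULL) {
  chk_num(n_leaves, "n_leaves", lower = 0)
  chk_num(leaf_radius, "leaf_radius", lower = 0, strict = TRUE)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stopf("'semi_axes' must be three positive lengths")
  chk_num(clumping, "clumping", lower = 0)
  if (clumping > 1) stopf("'clumping' must be in [0, 1]")
  structure(list(n_leaves = as.integer(n_leaves), leaf_radius = leaf_radius,
                 semi_axes = semi_axes, clumping = clumping,
                 n_clusters = as.integer(n_clusters),
                 points_per_leaf = as.integer(points_per_leaf), seed = seed),
            class = "crown_spec")
}

# uniform sample inside an ellipsoid with the given semi-axes
runif_ellipsoid <- function(n, semi_axes) {
  d <- matrix(rnorm(3 * n), ncol = 3)
  d <- d / sqrt(rowSums(d^2)) * runif(n)^(1 / 3)
  sweep(d, 2, semi_axes, `*`)
}

#' Generate a synthetic crown point cloud with known ground truth
#'
#' Stand-in for a terrestrial-LiDAR scan of one crown: leaf disks with random
#' orientation are placed inside the envelope and `points_per_leaf` returns
#' are sampled uniformly on each disk.
#'
#' @param spec a [crown_spec()]
#' @param tree_id identifier attached to the returned cloud
#' @return list with `cloud` (a [point_cloud()], carrying the per-leaf area as
#'   `leaf_area_weight / points_per_leaf`) and `truth` (list: `TLA` m^2,
#'   `envelope_volume` m^3, `leaf_centers`)
#' @export
generate_crown <- function(spec, tree_id = NA_character_) {
  stopifnot(inherits(spec, "crown_spec"))
  if (spec$n_leaves == 0L)
    stopf("empty crown: n_leaves = 0 (volume computations need >= 4 non-coplanar points)")
  res <- with_seed_opt(spec$seed, {
    n <- spec$n_leaves
    centers <- runif_ellipsoid(n, spec$semi_axes)
    if (spec$clumping > 0 && n > 1) {
      k <- max(1L, spec$n_clusters)
      cl_centers <- runif_ellipsoid(k, spec$semi_axes * 0.8)
      clumped <- runif(n) < spec$clumping
      assign_k <- sample.int(k, n, replace = TRUE)
      sdc <- 0.12 * mean(spec$semi_axes)
      clump_pos <- cl_centers[assign_k, , drop = FALSE] +
        matrix(rnorm(3 * n, sd = sdc), ncol = 3)
      centers[clumped, ] <- clump_pos[clumped, , drop = FALSE]
    }
    # random unit normal per leaf, orthonormal frame, points on the disk
    nv <- matrix(rnorm(3 * n), ncol = 3)
    nv <- nv / sqrt(rowSums(nv^2))
    ref <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
    flip <- abs(nv[, 3]) > 0.9
    ref[flip, ] <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3)
    e1 <- ref - nv * rowSums(ref * nv)
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- cbind(nv[, 2] * e1[, 3] - nv[, 3] * e1[, 2],
                nv[, 3] * e1[, 1] - nv[, 1] * e1[, 3],
                nv[, 1] * e1[, 2] - nv[, 2] * e1[, 1])
    m <- spec$points_per_leaf
    rr <- spec$leaf_radius * sqrt(runif(n * m))
    th <- runif(n * m, 0, 2 * pi)
    li <- rep(seq_len(n), each = m)
    pts <- centers[li, , drop = FALSE] +
      e1[li, , drop = FALSE] * (rr * cos(th)) +
      e2[li, , drop = FALSE] * (rr * sin(th))
    list(pts = pts, centers = centers)
  })
  tla <- spec$n_leaves * pi * spec$leaf_radius^2
  cloud <- point_cloud(res$pts, tree_id = tree_id,
                       leaf_area_weight = tla / nrow(res$pts))
  list(cloud = cloud,
       truth = list(TLA = tla,
                    envelope_volume = 4 / 3 * pi * prod(spec$semi_axes),
                    leaf_centers = res$centers))
}

#' Specification of a synthetic orchard for raster generation
#'
#' Trees sit on a regular planting grid (default 5 m between rows, 2 m within
#' rows, the design this package models); each tree paints a circular canopy
#' footprint into six reflectance bands and one thermal band, over a soil
#' background. Vegetation and soil reflectances are separated so that an NDVI
#' threshold classifies them cleanly.
#'
#' @param n_rows,trees_per_row planting grid size
#' @param spacing c(between-row, within-row) distances in meters
#' @param pixel_size raster resolution in meters (must be < canopy radius)
#' @param canopy_radius canopy footprint radius in meters (scalar or per tree)
#' @param tree_temperature true canopy surface temperature in deg C (scalar or
#'   per tree)
#' @param air_temperature deg C
#' @param soil_temperature_range deg C range for soil pixels
#' @param band_noise_sd reflectance noise SD (all bands)
#' @param thermal_noise_sd deg C noise SD on canopy pixels
#' @param seed integer seed
#' @return object of class `orchard_design`
#' @export
orchard_design <- function(n_rows = 2, trees_per_row = 10, spacing = c(5, 2),
                           pixel_size = 0.10, canopy_radius = 0.6,
                           tree_temperature = 30, air_temperature = 27.5,
                           soil_temperature_range = c(42, 50),
                           band_noise_sd = 0.01, thermal_noise_sd = 0.3,
                           seed = NULL) {
  if (any(spacing <= 0)) stopf("'spacing' must be positive")
  chk_num(pixel_size, "pixel_size", lower = 0, strict = TRUE)
  if (any(canopy_radius >= min(spacing) / 2))
    warnf("canopy radius >= spacing/2: neighbouring canopies overlap")
  if (any(pixel_size >= canopy_radius))
    stopf("pixel_size (%g) must be smaller than the canopy radius", pixel_size)
  structure(list(n_rows = as.integer(n_rows),
                 trees_per_row = as.integer(trees_per_row), spacing = spacing,
                 pixel_size = pixel_size, canopy_radius = canopy_radius,
                 tree_temperature = tree_temperature,
                 air_temperature = air_temperature,
                 soil_temperature_range = soil_temperature_range,
                 band_noise_sd = band_noise_sd,
                 thermal_noise_sd = thermal_noise_sd, seed = seed),
            class = "orchard_design")
}

# mean reflectance per band (nm) for vegetation and soil; soil is low-NIR /
# high-red so NDVI separates the classes at the default 0.3 threshold
synth_reflectance <- function() {
  data.frame(band = c("450", "530", "570", "675", "730", "850"),
             veg  = c(0.04, 0.08, 0.10, 0.05, 0.30, 0.45),
             soil = c(0.12, 0.15, 0.18, 0.22, 0.25, 0.28))
}

#' Generate synthetic multispectral + thermal orchard rasters
#'
#' Stand-in for airborne acquisition: returns a six-band reflectance stack, a
#' thermal raster in deg C and a ground-truth table with, per tree, the
#' centre coordinates, the true mean canopy temperature and the true count of
#' vegetation pixels (pixel centres inside the canopy disc).
#'
#' @param design an [orchard_design()]
#' @return list `stack` ([band_stack()]), `thermal` ([phen_raster()]),
#'   `truth` (data frame), `air_temperature`
#' @export
generate_orchard_images <- function(design) {
  stopifnot(inherits(design, "orchard_design"))
  n_trees <- design$n_rows * design$trees_per_row
  ps <- design$pixel_size
  margin <- max(design$canopy_radius) + 1
  width <- max(design$n_rows - 1, 0) * design$spacing[1] + 2 * margin
  height <- max(design$trees_per_row - 1, 0) * design$spacing[2] + 2 * margin
  nx <- ceiling(width / ps)
  ny <- ceiling(height / ps)
  # tree centres on the grid
  truth <- NULL
  if (n_trees > 0) {
    rows <- rep(seq_len(design$n_rows), each = design$trees_per_row)
    pos <- rep(seq_len(design$trees_per_row), design$n_rows)
    truth <- data.frame(
      tree_id = sprintf("T%03d", seq_len(n_trees)),
      x = margin + (rows - 1) * design$spacing[1],
      y = margin + (pos - 1) * design$spacing[2],
      canopy_radius = rep_len(design$canopy_radius, n_trees),
      true_temperature = rep_len(design$tree_temperature, n_trees),
      stringsAsFactors = FALSE)
  }
  refl <- synth_reflectance()
  # pixel-centre coordinates (row 1 at ymin, see phen_raster)
  cx <- (seq_len(nx) - 0.5) * ps
  cy <- (seq_len(ny) - 0.5) * ps
  px <- matrix(cx, ny, nx, byrow = TRUE)
  py <- matrix(cy, ny, nx)
  veg_owner <- matrix(0L, ny, nx) # 0 = soil, else tree index
  if (n_trees > 0) {
    for (i in seq_len(n_trees)) {
      inside <- (px - truth$x[i])^2 + (py - truth$y[i])^2 <
        truth$canopy_radius[i]^2
      veg_owner[inside] <- i
    }
    truth$true_pix_num <- vapply(seq_len(n_trees),
                                 function(i) sum(veg_owner == i), integer(1))
  }
  out <- with_seed_opt(design$seed, {
    bands <- list()
    for (b in seq_len(nrow(refl))) {
      base <- ifelse(veg_owner > 0, refl$veg[b], refl$soil[b])
      vals <- base + matrix(rnorm(ny * nx, sd = design$band_noise_sd), ny, nx)
      bands[[refl$band[b]]] <- pmin(pmax(vals, 0), 1)
    }
    soil_t <- matrix(runif(ny * nx, design$soil_temperature_range[1],
                           design$soil_temperature_range[2]), ny, nx)
    tt <- soil_t
    if (n_trees > 0) {
      ttree <- truth$true_temperature[pmax(veg_owner, 1L)]
      tt[veg_owner > 0] <- ttree[veg_owner > 0] +
        rnorm(sum(veg_owner > 0), sd = design$thermal_noise_sd)
    }
    list(bands = bands, thermal = tt)
  })
  list(stack = band_stack(out$bands, xmin = 0, ymin = 0, pixel_size = ps),
       thermal = phen_raster(out$thermal, xmin = 0, ymin = 0, pixel_size = ps),
       truth = truth,
       air_temperature = design$air_temperature)
}

#' Ground-truth coefficients for synthetic gas-exchange data
#'
#' True linear model `An = b0 + b1 * P_KO/KC + b2 * (Tleaf - Tair) + eps` per
#' device, with predictor ranges matching a field calibration campaign
#' (P on the 40-260 umol m-2 s-1 scale, leaf-air temperature differences
#' between -2 and +6 deg C, additive noise SD 3 umol m-2 s-1).
#'
#' @param beta matrix (device x 3) of true coefficients (b0, b1, b2); rownames
#'   are device ids
#' @param noise_sd SD of the residual noise on An (umol m-2 s-1)
#' @param p_range,dt_range ranges of P_KO/KC and Tleaf - Tair
#' @param ppfd light level (umol m-2 s-1) used to back-compute fluorescence
#' @param tair air temperature (deg C)
#' @return object of class `ipl_truth`
#' @export
ipl_truth <- function(beta = rbind(LICOR1 = c(-2.0, 0.12, -0.8),
                                   LICOR2 = c(-3.0, 0.10, -0.6)),
                      noise_sd = 3, p_range = c(40, 260),
                      dt_range = c(-2, 6), ppfd = 1500, tair = 28) {
  beta <- as.matrix(beta)
  if (ncol(beta) != 3L) stopf("'beta' needs 3 columns (b0, b1, b2)")
  if (is.null(rownames(beta)))
    rownames(beta) <- paste0("device", seq_len(nrow(beta)))
  chk_num(noise_sd, "noise_sd", lower = 0)
  structure(list(beta = beta, noise_sd = noise_sd, p_range = p_range,
                 dt_range = dt_range, ppfd = ppfd, tair = tair),
            class = "ipl_truth")
}

#' Generate synthetic gas-exchange / fluorescence records
#'
#' Stand-in for an IRGA + fluorimeter calibration campaign. P_KO/KC and
#' Tleaf - Tair are drawn uniformly in their ranges, An follows the true
#' linear model, and the fluorescence channel (Fs, Fm', PPFD) is
#' back-computed so that re-deriving P_KO/KC from the fluorescence fields
#' reproduces the value used for An.
#'
#' @param truth an [ipl_truth()]
#' @param n_records records per device (scalar or one per device); >= 10
#' @param seed integer seed
#' @param constants K_O/K_C temperature response, see [ko_kc_constants()]
#' @return data frame of gas-exchange records (device, Fs, Fm_prime, PPFD,
#'   Tleaf, Tair, An, gs, P_ko_kc_true)
#' @export
generate_gas_exchange <- function(truth, n_records = c(98, 132), seed = NULL,
                                  constants = ko_kc_constants()) {
  stopifnot(inherits(truth, "ipl_truth"))
  devices <- rownames(truth$beta)
  n_records <- rep_len(n_records, length(devices))
  if (any(n_records < 10))
    stopf("need at least 10 records per device for a usable calibration")
  with_seed_opt(seed, {
    recs <- lapply(seq_along(devices), function(d) {
      n <- n_records[d]
      dt <- runif(n, truth$dt_range[1], truth$dt_range[2])
      tleaf <- truth$tair + dt
      p <- runif(n, truth$p_range[1], truth$p_range[2])
      an <- truth$beta[d, 1] + truth$beta[d, 2] * p + truth$beta[d, 3] * dt +
        rnorm(n, sd = truth$noise_sd)
      ratio <- ko_kc_ratio(tleaf, constants)
      jpsii <- p / ratio
      phi <- jpsii / (truth$ppfd * 0.84 * 0.5)
      if (any(phi > 1))
        stopf("back-computed PhiPSII exceeds 1; widen ppfd or narrow p_range")
      fm <- runif(n, 1200, 1800)
      fs <- fm * (1 - phi)
      data.frame(device = devices[d], Fs = fs, Fm_prime = fm,
                 PPFD = truth$ppfd, Tleaf = tleaf, Tair = truth$tair,
                 An = an, gs = 100 + 10 * an + rnorm(n, sd = 20),
                 P_ko_kc_true = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
}

#' Specification of a synthetic quantitative-genetics trial
#'
#' Phenotypes follow `y = mu + G_i + S_j + eps` with genotype effects
#' `G ~ N(0, sigma_g2)`, a fixed watering-scenario effect and residuals
#' `eps ~ N(0, sigma_r2)`. The implied broad-sense heritability of genotype
#' means over `n_rep` replicates, `sigma_g2 / (sigma_g2 + sigma_r2 / n_rep)`,
#' is recorded as ground truth.
#'
#' @param n_genotypes number of genotypes
#' @param n_rep replicates per genotype (split evenly over the two scenarios)
#' @param sigma_g2 genetic variance (>= 0)
#' @param sigma_r2 residual variance (>= 0)
#' @param mu grand mean
#' @param scenario_effect fixed effect of the WD scenario (added to WD trees)
#' @param seed integer seed
#' @return object of class `genetic_design`
#' @export
genetic_design <- function(n_genotypes = 240, n_rep = 4, sigma_g2 = 1,
                           sigma_r2 = 1, mu = 10, scenario_effect = -1,
                           seed = NULL) {
  chk_num(sigma_g2, "sigma_g2", lower = 0)
  chk_num(sigma_r2, "sigma_r2", lower = 0)
  if (n_rep < 1) stopf("'n_rep' must be >= 1")
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_rep = as.integer(n_rep), sigma_g2 = sigma_g2,
                 sigma_r2 = sigma_r2, mu = mu,
                 scenario_effect = scenario_effect, seed = seed),
            class = "genetic_design")
}

#' Generate a synthetic phenotype table with known heritability
#'
#' @param design a [genetic_design()]
#' @param trait trait name recorded in the table
#' @return data frame (genotype, scenario, replicate, trait, value) with
#'   attribute `truth`: list(H2, sigma_g2, sigma_r2, n_rep, genotype_effects)
#' @export
generate_phenotypes <- function(design, trait = "trait") {
  stopifnot(inherits(design, "genetic_design"))
  g <- design$n_genotypes
  n <- design$n_rep
  out <- with_seed_opt(design$seed, {
    geff <- rnorm(g, sd = sqrt(design$sigma_g2))
    scen <- rep_len(c("WW", "WD"), n)
    df <- data.frame(
      genotype = rep(sprintf("G%04d", seq_len(g)), each = n),
      scenario = rep(scen, g),
      replicate = rep(seq_len(n), g),
      trait = trait,
      stringsAsFactors = FALSE)
    df$value <- design$mu + rep(geff, each = n) +
      ifelse(df$scenario == "WD", design$scenario_effect, 0) +
      rnorm(g * n, sd = sqrt(design$sigma_r2))
    list(df = df, geff = geff)
  })
  h2 <- if (design$sigma_g2 == 0 && design$sigma_r2 == 0) NA_real_ else
    design$sigma_g2 / (design$sigma_g2 + design$sigma_r2 / n)
  attr(out$df, "truth") <- list(H2 = h2, sigma_g2 = design$sigma_g2,
                                sigma_r2 = design$sigma_r2, n_rep = n,
                                genotype_effects = setNames(
                                  out$geff, sprintf("G%04d", seq_len(g))))
  out$df
}
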