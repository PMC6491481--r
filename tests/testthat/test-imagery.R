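test_that("thermal calibration recovers the DN-to-temperature line", {
  cal <- calibrate_thermal(c(100, 200), c(20, 40))
  expect_equal(cal$slope, 0.2)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$r_squared, 1)
  # noisy targets on a known line: estimate within 3 SE of the truth
  withr::with_seed(4, {
    dn <- seq(50, 250, length.out = 10)
    temp <- 0.15 * dn + 5 + rnorm(10, sd = 0.2)
  })
  fit <- calibrate_thermal(dn, temp)
  se <- summary(lm(temp ~ dn))$coefficients[2, 2]
  expect_lt(abs(fit$slope - 0.15), 3 * se)
  expect_error(calibrate_thermal(100, 20), "at least 2")
  expect_error(calibrate_thermal(c(100, 100), c(20, 30)), "constant DN")
  # pixel-wise application
  r <- phen_raster(matrix(c(100, 200), 1, 2))
  expect_equal(apply_thermal_calibration(r, cal)$values,
               matrix(c(20, 40), 1, 2))
})

make_stack <- function(b850, b675, b570 = b675, b530 = b675,
                       b450 = b675, b730 = b675) {
  band_stack(list(`450` = b450, `530` = b530, `570` = b570, `675` = b675,
                  `730` = b730, `850` = b850), pixel_size = 1)
}

test_that("vegetation indices follow their closed forms", {
  m <- function(v) matrix(v, 1, 1)
  idx <- compute_indices(make_stack(m(0.5), m(0.1)))
  expect_equal(idx$NDVI[1, 1], 0.4 / 0.6)
  # equal bands null the normalized differences
  idx0 <- compute_indices(make_stack(m(0.3), m(0.3)))
  expect_equal(idx0$NDVI[1, 1], 0)
  expect_equal(idx0$PRI[1, 1], 0)   # 530 = 570 here
  # PRI sign: 530 < 570 gives negative
  idxp <- compute_indices(make_stack(m(0.5), m(0.1), b570 = m(0.12),
                                     b530 = m(0.08)))
  expect_lt(idxp$PRI[1, 1], 0)
  # MCARI2 published form, checked against a hand evaluation
  nir <- 0.45; red <- 0.05; g <- 0.10
  mc <- 1.5 * (2.5 * (nir - red) - 1.3 * (nir - g)) /
    sqrt((2 * nir + 1)^2 - (6 * nir - 5 * sqrt(red)) - 0.5)
  idx2 <- compute_indices(make_stack(m(nir), m(red), b570 = m(g)))
  expect_equal(idx2$MCARI2[1, 1], mc)
  # indices stay in [-1, 1] for valid reflectances (normalized differences)
  withr::with_seed(2, {
    st <- make_stack(matrix(runif(100), 10), matrix(runif(100), 10),
                     b570 = matrix(runif(100), 10),
                     b530 = matrix(runif(100), 10))
  })
  ix <- compute_indices(st)
  for (nm in c("NDVI", "GNDVI", "PRI"))
    expect_true(all(abs(ix[[nm]]) <= 1, na.rm = TRUE))
  # zero denominator flagged missing, not infinite
  izz <- compute_indices(make_stack(m(0), m(0)))
  expect_true(is.na(izz$NDVI[1, 1]))
})

test_that("missing bands and shape mismatches are explicit errors", {
  st <- make_stack(matrix(0.4, 2, 2), matrix(0.1, 2, 2))
  st$bands[["850"]] <- NULL
  expect_error(compute_indices(st), "band 850")
  expect_error(band_stack(list(`850` = matrix(0, 2, 2),
                               `675` = matrix(0, 3, 3))),
               "shape mismatch")
  expect_error(band_stack(list(matrix(0, 2, 2))), "named")
})

test_that("vegetation classification thresholds behave at the extremes", {
  d <- orchard_design(n_rows = 1, trees_per_row = 3, seed = 5)
  img <- generate_orchard_images(d)
  expect_true(all(classify_vegetation(img$stack, threshold = -1)))
  expect_false(any(classify_vegetation(img$stack, threshold = 1)))
  # default threshold separates the synthetic classes exactly (low noise)
  mask <- classify_vegetation(img$stack)
  expect_equal(sum(mask), sum(img$truth$true_pix_num), tolerance = 0.02)
})

test_that("buffer extraction selects pixel centres within the radius", {
  d <- orchard_design(n_rows = 1, trees_per_row = 2, spacing = c(5, 2),
                      pixel_size = 0.1, canopy_radius = 0.6,
                      band_noise_sd = 0, thermal_noise_sd = 0, seed = 6)
  img <- generate_orchard_images(d)
  ctr <- c(img$truth$x[1], img$truth$y[1])
  # radius below one pixel: at most one pixel
  tiny <- suppressWarnings(extract_buffer(img$stack, img$thermal, ctr,
                                          radius = 0.04))
  expect_lte(nrow(tiny), 1)
  # footprint fully inside buffer: pix_num equals the truth count
  px <- extract_buffer(img$stack, img$thermal, ctr, radius = 0.70)
  expect_identical(attr(px, "pix_num"), img$truth$true_pix_num[1])
  expect_true(all((px$x - ctr[1])^2 + (px$y - ctr[2])^2 <= 0.70^2))
  # buffers of trees 2 m apart at 0.70 m radius are disjoint
  px2 <- extract_buffer(img$stack, img$thermal,
                        c(img$truth$x[2], img$truth$y[2]), radius = 0.70)
  key <- function(p) paste(p$x, p$y)
  expect_length(intersect(key(px), key(px2)), 0)
  # empty buffer warns and returns zero rows
  expect_warning(out <- extract_buffer(img$stack, img$thermal,
                                       c(1e3, 1e3)), "no pixel")
  expect_identical(nrow(out), 0L)
  # pix_num invariant under band-order permutation
  st_perm <- band_stack(rev(img$stack$bands),
                        pixel_size = img$stack$pixel_size)
  expect_identical(attr(extract_buffer(st_perm, img$thermal, ctr), "pix_num"),
                   attr(px, "pix_num"))
})

test_that("tree temperature statistics use vegetation pixels and sample SD", {
  d <- orchard_design(n_rows = 1, trees_per_row = 1, band_noise_sd = 0,
                      thermal_noise_sd = 0, tree_temperature = 30,
                      air_temperature = 27, seed = 1)
  img <- generate_orchard_images(d)
  px <- extract_buffer(img$stack, img$thermal,
                       c(img$truth$x[1], img$truth$y[1]))
  tt <- tree_temperature(px, t_air = 27)
  expect_equal(tt$mean, 3.0)
  expect_equal(tt$sd, 0.0)
  # two-pixel arithmetic with the sample (n-1) convention
  fake <- px[1:2, ]
  fake$t_surf <- c(29, 31)
  fake$vegetation <- TRUE
  class(fake) <- class(px)
  tt2 <- tree_temperature(fake, t_air = 28)
  expect_equal(tt2$mean, 2.0)
  expect_equal(tt2$sd, sqrt(2)) # sample SD of {1, 3}
  # zero vegetation pixels: missing values, not an error
  none <- fake
  none$vegetation <- FALSE
  tt3 <- tree_temperature(none, t_air = 28)
  expect_true(is.na(tt3$mean) && is.na(tt3$sd))
})

test_that("manual trapezoid echoes the supplied vertices and validates geometry", {
  tr <- reference_trapezoid()
  expect_equal(tr$t_sat_soil, 0.87)
  expect_equal(tr$t_ww_veg, -1.34)
  expect_equal(tr$t_dry_soil, 21.86)
  expect_equal(tr$t_ws_veg, 5.6)
  expect_error(fit_trapezoid(vertices = c(5, 2, 1, 4)), "wet edge")
  expect_error(fit_trapezoid(vertices = c(1, 2, 3)), "4 vertex")
})

test_that("trapezoid fit recovers a planted trapezoid within 0.5 degC", {
  planted <- reference_trapezoid()
  withr::with_seed(8, {
    n <- 20000
    ndvi <- runif(n)
    tw <- trap_edge(planted, ndvi, "wet")
    td <- trap_edge(planted, ndvi, "dry")
    dt <- tw + runif(n) * (td - tw)
  })
  fit <- fit_trapezoid(ndvi = ndvi, dt = dt)
  for (x in c(planted$ndvi_soil, 0.4, planted$ndvi_veg)) {
    expect_lt(abs(trap_edge(fit, x, "wet") - trap_edge(planted, x, "wet")),
              0.5)
    expect_lt(abs(trap_edge(fit, x, "dry") - trap_edge(planted, x, "dry")),
              0.5)
  }
  expect_error(fit_trapezoid(ndvi = rep(0.5, 200), dt = rnorm(200)),
               "NDVI range|one NDVI")
  expect_error(fit_trapezoid(ndvi = runif(50), dt = rnorm(50)), ">= 100")
})

test_that("WDI interpolates between the wet and dry edges and clips", {
  tr <- reference_trapezoid()
  # corners of the vegetation edge
  expect_equal(compute_wdi(tr$ndvi_veg, -1.34, tr), 0)
  expect_equal(compute_wdi(tr$ndvi_veg, 5.6, tr), 1)
  # midway at any NDVI gives 0.5 by linearity
  for (x in c(0.05, 0.3, 0.62, 0.9)) {
    mid <- (trap_edge(tr, x, "wet") + trap_edge(tr, x, "dry")) / 2
    expect_equal(compute_wdi(x, mid, tr), 0.5)
  }
  # clipping outside the trapezoid
  expect_identical(compute_wdi(0.9, -10, tr), 0)
  expect_identical(compute_wdi(0.9, 50, tr), 1)
  # monotone in dT at fixed NDVI
  w <- compute_wdi(rep(0.5, 50), seq(-5, 25, length.out = 50), tr)
  expect_true(all(diff(w) >= 0))
  # invariant under adding a constant to dT and both edges
  tr2 <- fit_trapezoid(vertices = c(0.87, -1.34, 21.86, 5.6) + 3,
                       ndvi_edges = c(0.05, 0.9))
  expect_equal(compute_wdi(0.5, 4, tr), compute_wdi(0.5, 7, tr2))
})

test_that("per-tree WDI ranks planted stress perfectly without noise", {
  stress_temp <- seq(28, 34, length.out = 6)
  d <- orchard_design(n_rows = 1, trees_per_row = 6, spacing = c(5, 2),
                      pixel_size = 0.1, canopy_radius = 0.6,
                      tree_temperature = stress_temp, band_noise_sd = 0,
                      thermal_noise_sd = 0, seed = 2)
  img <- generate_orchard_images(d)
  # wet edge low enough that no tree clips to 0
  trap <- fit_trapezoid(vertices = c(14, -5, 25, 10),
                        ndvi_edges = c(0.06, 0.8))
  summ <- tree_summary(img$stack, img$thermal,
                       data.frame(tree_id = img$truth$tree_id,
                                  x = img$truth$x, y = img$truth$y),
                       t_air = d$air_temperature, trap = trap)
  expect_equal(cor(summ$WDI, stress_temp, method = "spearman"), 1)
})
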