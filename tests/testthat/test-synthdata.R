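test_that("crown generation satisfies its closed-form ground truth", {
  cr <- generate_crown(crown_spec(n_leaves = 1000, leaf_radius = 0.05,
                                  seed = 1))
  expect_equal(cr$truth$TLA, 1000 * pi * 0.05^2)       # ~7.854 m^2
  expect_equal(cr$truth$envelope_volume, 4 / 3 * pi * 1 * 1 * 1.2)
  expect_identical(nrow(cr$cloud$points), 5000L)
  # leaf centres stay inside the envelope (uniform, no clumping)
  s <- sweep(cr$truth$leaf_centers, 2, c(1, 1, 1.2), `/`)
  expect_true(all(rowSums(s^2) <= 1 + 1e-9))
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- generate_crown(crown_spec(200, 0.04, seed = 42))
  b <- generate_crown(crown_spec(200, 0.04, seed = 42))
  expect_identical(a$cloud$points, b$cloud$points)
  d <- orchard_design(seed = 9)
  expect_identical(generate_orchard_images(d)$thermal$values,
                   generate_orchard_images(d)$thermal$values)
  tr <- ipl_truth()
  expect_identical(generate_gas_exchange(tr, c(20, 20), seed = 5),
                   generate_gas_exchange(tr, c(20, 20), seed = 5))
  gd <- genetic_design(20, 4, seed = 8)
  expect_identical(generate_phenotypes(gd), generate_phenotypes(gd))
})

test_that("empty or invalid crown specs are rejected", {
  expect_error(generate_crown(crown_spec(n_leaves = 0, seed = 1)),
               "empty crown")
  expect_error(crown_spec(leaf_radius = 0), "leaf_radius")
  expect_error(crown_spec(semi_axes = c(1, -1, 1)), "semi_axes")
  expect_error(crown_spec(clumping = 2), "clumping")
})

test_that("dense ellipsoid crown has near-analytic hull volume", {
  cr <- generate_crown(crown_spec(n_leaves = 4000, leaf_radius = 0.03,
                                  semi_axes = c(2, 1, 1),
                                  points_per_leaf = 5, seed = 42))
  expect_equal(convex_hull_volume(cr$cloud), 4 / 3 * pi * 2,
               tolerance = 0.05)
})

test_that("orchard rasters carry a consistent per-tree truth table", {
  d <- orchard_design(n_rows = 2, trees_per_row = 5, pixel_size = 0.1,
                      canopy_radius = 0.6, tree_temperature = 29:38,
                      band_noise_sd = 0, thermal_noise_sd = 0, seed = 3)
  img <- generate_orchard_images(d)
  expect_identical(nrow(img$truth), 10L)
  # noiseless: vegetation mask equals the truth footprint per tree
  mask <- classify_vegetation(img$stack)
  expect_identical(sum(mask), sum(img$truth$true_pix_num))
  # footprint discretization: pixel count within one pixel ring of the
  # continuous disc area
  area_px <- pi * d$canopy_radius^2 / d$pixel_size^2
  ring <- 2 * pi * d$canopy_radius / d$pixel_size + 4
  expect_true(all(abs(img$truth$true_pix_num - area_px) <= ring))
  # noiseless mean recovered temperature is exact
  px <- extract_buffer(img$stack, img$thermal,
                       c(img$truth$x[4], img$truth$y[4]), radius = 0.70,
                       tree_id = img$truth$tree_id[4])
  tt <- tree_temperature(px, t_air = d$air_temperature)
  expect_equal(tt$mean, img$truth$true_temperature[4] - d$air_temperature)
  expect_equal(tt$sd, 0)
})

test_that("with thermal noise the recovered mean respects the CLT bound", {
  d <- orchard_design(n_rows = 1, trees_per_row = 4, pixel_size = 0.06,
                      canopy_radius = 0.65, tree_temperature = 31,
                      thermal_noise_sd = 0.5, seed = 12)
  img <- generate_orchard_images(d)
  for (i in seq_len(4)) {
    px <- extract_buffer(img$stack, img$thermal,
                         c(img$truth$x[i], img$truth$y[i]))
    tt <- tree_temperature(px, t_air = d$air_temperature)
    expect_gte(tt$n, 300)
    expect_lt(abs(tt$mean - (31 - d$air_temperature)),
              3 * 0.5 / sqrt(tt$n))
    # recovered pixel SD close to the generating noise SD
    expect_equal(tt$sd, 0.5, tolerance = 0.2)
  }
})

test_that("orchard design flags overlap and resolution problems", {
  expect_warning(orchard_design(canopy_radius = 1.2, spacing = c(5, 2)),
                 "overlap")
  expect_error(orchard_design(pixel_size = 0.7, canopy_radius = 0.6),
               "pixel_size")
  # zero trees: everything classifies as soil
  d0 <- orchard_design(n_rows = 0, trees_per_row = 0, seed = 1)
  img0 <- generate_orchard_images(d0)
  expect_false(any(classify_vegetation(img0$stack)))
})

test_that("gas-exchange generation is consistent with its own truth", {
  tr <- ipl_truth(noise_sd = 0)
  ge <- generate_gas_exchange(tr, n_records = c(30, 30), seed = 2)
  # fluorescence back-computation reproduces the P_KO/KC used for An
  p <- orchardphen:::p_ko_kc(ge)
  expect_equal(p, ge$P_ko_kc_true, tolerance = 1e-10)
  expect_true(all(ge$Fs >= 0 & ge$Fs <= ge$Fm_prime))
  expect_error(generate_gas_exchange(tr, n_records = 5, seed = 1),
               "at least 10")
})

test_that("phenotype tables carry the Eq.-form heritability truth", {
  t1 <- attr(generate_phenotypes(genetic_design(30, 4, 1, 1, seed = 1)),
             "truth")
  expect_equal(t1$H2, 0.8)
  t2 <- attr(generate_phenotypes(genetic_design(30, 2, 1, 1, seed = 1)),
             "truth")
  expect_equal(t2$H2, 2 / 3)
  t3 <- attr(generate_phenotypes(genetic_design(30, 4, 0, 1, seed = 1)),
             "truth")
  expect_equal(t3$H2, 0)
  # structure: one value per genotype x replicate, scenarios balanced
  ph <- generate_phenotypes(genetic_design(10, 4, 1, 1, seed = 2))
  expect_identical(nrow(ph), 40L)
  expect_true(all(table(ph$genotype, ph$scenario) == 2))
})
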