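test_that("convex hull volume is exact on reference solids", {
  expect_equal(convex_hull_volume(unit_cube()), 1.0, tolerance = 1e-9)
  expect_equal(convex_hull_volume(regular_tetra()), sqrt(2) / 12,
               tolerance = 1e-9)
  # strictly interior points do not change the hull
  cube_filled <- rbind(unit_cube(), grid_cube(6) * 0.7 + 0.15)
  expect_equal(convex_hull_volume(cube_filled), 1.0, tolerance = 1e-6)
})

test_that("degenerate clouds are rejected with explicit errors", {
  expect_error(convex_hull_volume(matrix(rnorm(9), 3, 3)), "at least 4")
  coplanar <- cbind(matrix(runif(40), 20, 2), 0.5)
  expect_error(convex_hull_volume(coplanar), "coplanar|degenerate")
  collinear <- cbind(seq_len(10), seq_len(10), seq_len(10))
  expect_error(convex_hull_volume(collinear), "coplanar|degenerate")
  expect_error(point_cloud(matrix(1, 2, 2)), "3 columns")
})

test_that("ball-sample hull matches the independent oracle and converges", {
  # frozen oracle: scipy.spatial.ConvexHull on the identical seeded cloud
  # gives 3.997093082357262 for n = 1e4, seed below
  cl <- ball_cloud(10000, seed = 1)
  expect_equal(convex_hull_volume(cl), 3.9970931, tolerance = 1e-6)
  # hull volume converges to the ball volume; at n = 3e4 the sampling
  # deficit is below 3%
  cl2 <- ball_cloud(30000, seed = 101)
  expect_equal(convex_hull_volume(cl2), 4 * pi / 3, tolerance = 0.03)
})

test_that("hull volumes are invariant under rigid motion", {
  cl <- ball_cloud(800, seed = 7)
  tets <- delaunay_tetrahedra(cl)
  v0 <- convex_hull_volume(cl, tets = tets)
  a0 <- alpha_hull_volume(cl, alpha = 0.4, tets = tets)
  for (s in 1:3) {
    r <- rotation_matrix(s)
    moved <- cl %*% r + matrix(c(10, -5, 3), nrow(cl), 3, byrow = TRUE)
    tets2 <- delaunay_tetrahedra(moved)
    expect_equal(convex_hull_volume(moved, tets = tets2), v0,
                 tolerance = 1e-9)
    expect_equal(alpha_hull_volume(moved, alpha = 0.4, tets = tets2), a0,
                 tolerance = 1e-9)
  }
})

test_that("alpha-shape volume behaves as the radius-bound alpha complex", {
  # two dense unit cubes 5 m apart: components summed, each close to 1
  both <- rbind(grid_cube(12, seed = 1), grid_cube(12, shift = c(6, 0, 0),
                                                   seed = 2))
  tets <- delaunay_tetrahedra(both)
  expect_equal(alpha_hull_volume(both, alpha = 0.5, tets = tets), 2.0,
               tolerance = 0.02)
  # very large alpha recovers the convex hull (including the gap)
  expect_equal(alpha_hull_volume(both, alpha = 1e6, tets = tets),
               convex_hull_volume(both, tets = tets), tolerance = 1e-12)
  # alpha below the minimum point spacing retains nothing
  expect_warning(v0 <- alpha_hull_volume(both, alpha = 1e-6, tets = tets),
                 "no tetrahedron")
  expect_identical(v0, 0)
  expect_error(alpha_hull_volume(both, alpha = 0), "alpha")
})

test_that("alpha volume is monotone in alpha and bounded by the convex hull", {
  grid <- c(0.05, 0.1, 0.15, 0.25, 0.5, 1, 5)
  for (s in 1:5) {
    cr <- generate_crown(crown_spec(n_leaves = 150, leaf_radius = 0.04,
                                    clumping = (s - 1) / 5,
                                    points_per_leaf = 3, seed = s))
    tets <- delaunay_tetrahedra(cr$cloud)
    cv <- convex_hull_volume(cr$cloud, tets = tets)
    av <- vapply(grid, function(a)
      suppressWarnings(alpha_hull_volume(cr$cloud, a, tets = tets)),
      numeric(1))
    expect_true(all(diff(av) >= 0))
    expect_true(all(av <= cv + 1e-12))
  }
})

test_that("convexity index is the a/c ratio with its domain checks", {
  expect_equal(convexity_index(0.5, 2.0), 0.25)
  expect_equal(convexity_index(3, 3), 1)
  expect_error(convexity_index(2.1, 2.0), "exceeds")
  expect_error(convexity_index(1, 0), "c_volume")
  # definition holds on a real crown
  cr <- generate_crown(crown_spec(400, 0.04, seed = 3))
  tets <- delaunay_tetrahedra(cr$cloud)
  av <- alpha_hull_volume(cr$cloud, 0.2, tets = tets)
  cv <- convex_hull_volume(cr$cloud, tets = tets)
  expect_identical(convexity_index(av, cv), av / cv)
})

test_that("convexity index of a dense convex solid approaches 1 as alpha grows", {
  cube <- grid_cube(12, seed = 9)
  tets <- delaunay_tetrahedra(cube)
  cv <- convex_hull_volume(cube, tets = tets)
  ci <- alpha_hull_volume(cube, 0.5, tets = tets) / cv
  expect_gt(ci, 0.98)
  expect_lte(ci, 1)
})

test_that("alpha selection maximizes correlation with TLA and has the 0.15 default", {
  expect_identical(select_alpha()$alpha, 0.15)
  expect_identical(select_alpha(clouds = NULL, alpha_grid = c(0.3))$alpha,
                   0.15)
  # heterogeneous crowns; TLA planted to correlate perfectly at alpha = 0.3
  clouds <- lapply(1:8, function(s)
    generate_crown(crown_spec(n_leaves = 100 + 40 * s, leaf_radius = 0.04,
                              semi_axes = c(1, 1, 1.2) * (0.7 + s / 10),
                              clumping = 0.2 + 0.08 * (s %% 3),
                              points_per_leaf = 3, seed = s))$cloud)
  a0 <- 0.3
  tla <- vapply(clouds, function(cl)
    alpha_hull_volume(cl, a0), numeric(1))
  sel <- select_alpha(clouds, tla, alpha_grid = c(0.1, 0.2, 0.3, 0.4, 0.6))
  expect_identical(sel$alpha, a0)
  expect_equal(max(sel$profile$correlation), 1, tolerance = 1e-12)
  # single-candidate grid returns that candidate
  expect_identical(select_alpha(clouds[1:3], tla[1:3],
                                alpha_grid = 0.15)$alpha, 0.15)
  expect_error(select_alpha(clouds[1:3], rep(2, 3), alpha_grid = 0.15),
               "constant TLA")
})

test_that("STAR matches the exact union-of-circles oracle", {
  r <- 0.05
  # one disk, one direction: silhouette = leaf area up to rasterization
  one <- compute_star(point_cloud(matrix(0, 1, 3)), directions = "zenith",
                      leaf_radius = r, grid_resolution = r / 8)
  expect_equal(one$star, 1, tolerance = 0.05)
  # 50 disjoint disks: exact union area = 50 pi r^2, STAR = 1 within 2%
  gx <- expand.grid(x = seq(0.5, 4.5, length.out = 8),
                    y = seq(0.5, 4.5, length.out = 7))[1:50, ]
  pts <- cbind(gx$x, gx$y, withr::with_seed(3, runif(50)))
  s50 <- compute_star(point_cloud(pts), directions = "zenith",
                      leaf_radius = r, grid_resolution = r / 8)
  expect_equal(s50$star, 1, tolerance = 0.02)
  # N coincident disks follow the 1/N law exactly (same rasterization)
  for (n in c(2, 10, 25)) {
    sn <- compute_star(point_cloud(matrix(0, n, 3)), directions = "zenith",
                       leaf_radius = r, grid_resolution = r / 8)
    expect_equal(sn$star * n, one$star, tolerance = 1e-12)
  }
})

test_that("STAR validates its resolution and direction inputs", {
  pc <- point_cloud(matrix(rnorm(30), 10, 3))
  expect_error(compute_star(pc, leaf_radius = 0.05, grid_resolution = 0.05),
               "grid_resolution")
  expect_error(compute_star(pc, directions = matrix(1, 1, 2)), "directions")
  # direction count maps to the hemisphere discretization
  expect_identical(nrow(star_directions(46)), 46L)
  expect_identical(star_directions(1), matrix(c(0, 0, -1), 1, 3))
  expect_true(all(abs(rowSums(star_directions(46)^2) - 1) < 1e-12))
  expect_true(all(star_directions(46)[, 3] < 0))
})

test_that("STAR decreases weakly with clumping at fixed leaf area", {
  stars <- vapply(c(0, 0.45, 0.9), function(cl) {
    cr <- generate_crown(crown_spec(800, 0.04, c(1, 1, 1.2), clumping = cl,
                                    points_per_leaf = 3, seed = 5))
    compute_star(cr$cloud, directions = 6,
                 leaf_radius = 0.04 / sqrt(3),
                 total_leaf_area = cr$truth$TLA)$star
  }, numeric(1))
  expect_true(all(diff(stars) <= 0.01)) # weak decrease, small MC slack
  expect_lt(stars[3], stars[1])
})
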