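# Fixtures built in code: reference solids, seeded clouds and planted tables.

# the 8 corners of the unit cube
unit_cube <- function() as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))

# regular tetrahedron with edge length 1 (volume sqrt(2)/12)
regular_tetra <- function() {
  matrix(c(0, 0, 0,
           1, 0, 0,
           0.5, sqrt(3) / 2, 0,
           0.5, sqrt(3) / 6, sqrt(2 / 3)), ncol = 3, byrow = TRUE)
}

# n points uniform in the unit ball (seeded)
ball_cloud <- function(n, seed) {
  withr::with_seed(seed, {
    d <- matrix(rnorm(3 * n), ncol = 3)
    d / sqrt(rowSums(d^2)) * runif(n)^(1 / 3)
  })
}

# dense jittered grid filling the unit cube, optionally shifted
grid_cube <- function(m = 14, shift = c(0, 0, 0), seed = 1) {
  g <- as.matrix(expand.grid(seq(0, 1, length.out = m),
                             seq(0, 1, length.out = m),
                             seq(0, 1, length.out = m)))
  withr::with_seed(seed, g + matrix(runif(length(g), -1e-4, 1e-4),
                                    ncol = 3)) +
    matrix(shift, nrow(g), 3, byrow = TRUE)
}

# random rotation matrix (seeded, via QR of a Gaussian matrix)
rotation_matrix <- function(seed) {
  withr::with_seed(seed, {
    qr_d <- qr(matrix(rnorm(9), 3, 3))
    q <- qr.Q(qr_d)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# evaluate the wet or dry edge of a trapezoid at arbitrary NDVI
trap_edge <- function(trap, ndvi, edge = c("wet", "dry")) {
  edge <- match.arg(edge)
  f <- (ndvi - trap$ndvi_soil) / (trap$ndvi_veg - trap$ndvi_soil)
  if (edge == "wet") trap$t_sat_soil + f * (trap$t_ww_veg - trap$t_sat_soil)
  else trap$t_dry_soil + f * (trap$t_ws_veg - trap$t_dry_soil)
}

# genotype x trait matrix with k planted, well-separated groups; `spread`
# places group centres on a deterministic ladder (0, sep, 2 sep, ...) so all
# pairwise group contrasts are exactly `separation` apart per trait
planted_blup_table <- function(k = 6, per_group = 10, n_traits = 7,
                               separation = 8, noise_sd = 1, seed = 1,
                               spread = FALSE) {
  withr::with_seed(seed, {
    centers <- if (spread)
      matrix(separation * (seq_len(k) - 1), k, n_traits)
    else matrix(rnorm(k * n_traits, sd = separation), k, n_traits)
    lab <- rep(seq_len(k), each = per_group)
    m <- centers[lab, ] + matrix(rnorm(length(lab) * n_traits,
                                       sd = noise_sd),
                                 length(lab), n_traits)
    dimnames(m) <- list(sprintf("G%03d", seq_along(lab)),
                        paste0("tr", seq_len(n_traits)))
    list(values = m, labels = lab)
  })
}

# the 27-July manual trapezoid reused across imagery tests
reference_trapezoid <- function() {
  fit_trapezoid(vertices = c(0.87, -1.34, 21.86, 5.6),
                ndvi_edges = c(0.05, 0.9))
}
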