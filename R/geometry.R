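#' Construct a crown point cloud
#'
#' Container for a single tree crown scanned (or simulated) as a set of 3D
#' points in meters. All architectural descriptors ([convex_hull_volume()],
#' [alpha_hull_volume()], [compute_star()]) operate on this class.
#'
#' @param points numeric matrix (n x 3) of x, y, z coordinates in meters
#' @param tree_id identifier for the tree (character or integer)
#' @param leaf_area_weight optional one-sided leaf area (m^2) carried by each
#'   point, used as the default total leaf area in [compute_star()]
#' @return object of class `point_cloud`
#' @export
point_cloud <- function(points, tree_id = NA_character_,
                        leaf_area_weight = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stopf("'points' must have 3 columns (x, y, z)")
  if (!is.numeric(points) || anyNA(points))
    stopf("'points' must be numeric with no missing values")
  structure(list(points = points, tree_id = tree_id,
                 leaf_area_weight = leaf_area_weight),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> tree %s: %d points\n",
              as.character(x$tree_id), nrow(x$points)))
  invisible(x)
}

as_cloud_matrix <- function(cloud) {
  if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
}

# Reject clouds on which no 3D volume is defined (< 4 points or rank < 3).
check_nondegenerate <- function(pts) {
  if (nrow(pts) < 4L)
    stopf("volume computation needs at least 4 points (got %d)", nrow(pts))
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] <= 1e-12 * max(sv[1], 1e-300))
    stopf("degenerate point cloud: points are (nearly) coplanar or collinear")
  invisible(TRUE)
}

#' Delaunay tetrahedral decomposition of a crown
#'
#' Tetrahedralizes the convex hull of the cloud. Each row describes one
#' tetrahedron: vertex indices, volume (m^3) and circumsphere radius (m).
#' Computing this once and reusing it across an alpha grid is much cheaper
#' than re-triangulating, so [alpha_hull_volume()] and [select_alpha()] accept
#' the result via their `tets` argument.
#'
#' @param cloud a [point_cloud()] or n x 3 matrix
#' @return matrix with columns `i1..i4`, `volume`, `circumradius`
#' @export
delaunay_tetrahedra <- function(cloud) {
  pts <- as_cloud_matrix(cloud)
  check_nondegenerate(pts)
  .delaunay_tets(pts)
}

#' Convex hull volume of a crown point cloud
#'
#' Volume (m^3) of the 3D convex hull, i.e. the maximal space occupation of
#' the tree. Computed as the total volume of the Delaunay tetrahedralization,
#' whose union is exactly the convex hull.
#'
#' @inheritParams delaunay_tetrahedra
#' @param tets optional precomputed [delaunay_tetrahedra()] result
#' @return convex hull volume in m^3
#' @export
convex_hull_volume <- function(cloud, tets = NULL) {
  if (is.null(tets)) tets <- delaunay_tetrahedra(cloud)
  sum(tets[, "volume"])
}

#' Alpha-hull (alpha-shape) volume of a crown point cloud
#'
#' Volume of the 3D alpha shape: the union of Delaunay tetrahedra whose
#' circumsphere radius is smaller than `alpha` (the radius-bound convention;
#' `alpha` is in meters). Unlike the convex hull this envelope can be concave
#' and fragment into several components, whose volumes are summed. The volume
#' is non-decreasing in `alpha` and reaches the convex hull volume for large
#' `alpha`.
#'
#' @inheritParams convex_hull_volume
#' @param alpha shape parameter > 0, in meters (circumsphere radius bound)
#' @return alpha-shape volume in m^3 (0, with a warning, when no tetrahedron
#'   passes the alpha criterion)
#' @export
alpha_hull_volume <- function(cloud, alpha = 0.15, tets = NULL) {
  chk_num(alpha, "alpha", lower = 0, strict = TRUE)
  if (is.null(tets)) tets <- delaunay_tetrahedra(cloud)
  keep <- tets[, "circumradius"] < alpha
  if (!any(keep)) {
    warnf("no tetrahedron retained at alpha = %g; alpha volume is 0", alpha)
    return(0)
  }
  sum(tets[keep, "volume"])
}

#' Convexity index
#'
#' Ratio of the alpha-hull volume to the convex-hull volume; a proxy for the
#' density of tree space occupation within its convex envelope (1 = the crown
#' fills its convex hull).
#'
#' @param a_volume alpha-hull volume (m^3)
#' @param c_volume convex-hull volume (m^3), > 0
#' @return convexity index in (0, 1]
#' @export
convexity_index <- function(a_volume, c_volume) {
  chk_num(c_volume, "c_volume", lower = 0, strict = TRUE)
  chk_num(a_volume, "a_volume", lower = 0)
  if (a_volume > c_volume * (1 + 1e-9))
    stopf("inconsistent volumes: a_volume (%g) exceeds c_volume (%g)",
          a_volume, c_volume)
  a_volume / c_volume
}

#' Select the alpha parameter against measured leaf areas
#'
#' Chooses, over a grid, the alpha value whose alpha-hull volumes correlate
#' best (Pearson) with the total leaf areas (TLA) of a calibration subset of
#' trees. When no calibration data are supplied the default of 0.15 is
#' returned, the value retained in the study this package models.
#'
#' @param clouds list of [point_cloud()] objects (or `NULL` for the default)
#' @param tla numeric vector of total leaf areas (m^2), one per cloud
#' @param alpha_grid candidate alpha values (meters)
#' @return list with `alpha` (selected value) and `profile` (data frame of
#'   alpha vs Pearson correlation with TLA)
#' @export
select_alpha <- function(clouds = NULL, tla = NULL,
                         alpha_grid = seq(0.05, 0.5, by = 0.05)) {
  if (is.null(clouds)) {
    return(list(alpha = 0.15, profile = NULL,
                note = "default alpha (no calibration subset supplied)"))
  }
  if (length(clouds) < 3L) stopf("need at least 3 calibration clouds")
  if (length(tla) != length(clouds))
    stopf("'tla' must pair one leaf area with each cloud")
  if (length(alpha_grid) < 1L) stopf("empty alpha grid")
  if (sd(tla) == 0) stopf("constant TLA across calibration subset: correlation undefined")
  tet_list <- lapply(clouds, delaunay_tetrahedra)
  vols <- vapply(alpha_grid, function(a) {
    vapply(tet_list, function(tt) {
      suppressWarnings(alpha_hull_volume(NULL, alpha = a, tets = tt))
    }, numeric(1))
  }, numeric(length(clouds)))
  rs <- apply(vols, 2, function(v) if (sd(v) == 0) NA_real_ else cor(v, tla))
  profile <- data.frame(alpha = alpha_grid, correlation = rs)
  if (all(is.na(rs))) stopf("correlation undefined at every alpha on the grid")
  best <- which.max(rs)
  list(alpha = alpha_grid[best], profile = profile)
}

#' Standard hull descriptors for one crown
#'
#' Convenience wrapper computing `c_volume`, `a_volume` (at a given alpha) and
#' the convexity index from a single triangulation.
#'
#' @inheritParams convex_hull_volume
#' @param alpha alpha-shape parameter (meters), default 0.15
#' @return one-row data frame: `tree_id`, `c_volume`, `a_volume`, `alpha`, `c_i`
#' @export
hull_metrics <- function(cloud, alpha = 0.15) {
  tets <- delaunay_tetrahedra(cloud)
  cv <- convex_hull_volume(cloud, tets = tets)
  av <- alpha_hull_volume(cloud, alpha = alpha, tets = tets)
  id <- if (inherits(cloud, "point_cloud")) cloud$tree_id else NA
  data.frame(tree_id = as.character(id), c_volume = cv, a_volume = av,
             alpha = alpha, c_i = convexity_index(av, cv),
             stringsAsFactors = FALSE)
}

#' Upper-hemisphere viewing directions for STAR
#'
#' Equal-area discretization of the upper hemisphere into `n` sky sectors
#' (rings of constant elevation, ring populations proportional to the solid
#' angle of the ring). `n = 1` returns the zenith direction only.
#'
#' @param n number of directions (default 46, a standard sky discretization
#'   size)
#' @return matrix (n x 3) of unit vectors pointing downward through the canopy
#' @export
star_directions <- function(n = 46) {
  if (n < 1) stopf("need at least one direction")
  if (n == 1) return(matrix(c(0, 0, -1), 1, 3))
  # rings: split [0, pi/2] elevation into bands of equal solid angle count
  n_rings <- max(2L, round(sqrt(n)))
  edges <- seq(0, 1, length.out = n_rings + 1) # cos(zenith) in [0,1], equal-area
  counts <- rep(floor(n / n_rings), n_rings)
  counts[seq_len(n - sum(counts))] <- counts[seq_len(n - sum(counts))] + 1
  dirs <- matrix(0, 0, 3)
  for (r in seq_len(n_rings)) {
    cz <- (edges[r] + edges[r + 1]) / 2       # cos(zenith angle), mid-band
    sz <- sqrt(1 - cz^2)
    m <- counts[r]
    az <- 2 * pi * (seq_len(m) - 0.5) / m + (r - 1) * 0.5 # stagger rings
    dirs <- rbind(dirs, cbind(cos(az) * sz, sin(az) * sz, -cz))
  }
  dirs
}

# Median nearest-neighbour distance, estimated on a subsample for large clouds.
median_nn_distance <- function(pts, max_query = 500L) {
  n <- nrow(pts)
  idx <- if (n > max_query) round(seq(1, n, length.out = max_query)) else seq_len(n)
  d <- vapply(idx, function(i) {
    dd <- sqrt(colSums((t(pts) - pts[i, ])^2))
    min(dd[-i])
  }, numeric(1))
  stats::median(d[d > 0])
}

#' Silhouette to total leaf area ratio (STAR)
#'
#' Proxy for light interception efficiency. Every point of the cloud is
#' rendered as an opaque disk of radius `leaf_radius` facing the viewing
#' direction; the silhouette area in a direction is the area of the union of
#' the projected disks, obtained by rasterizing onto a grid orthogonal to the
#' direction and counting covered cells. STAR is the mean over directions of
#' silhouette area / total one-sided leaf area, so a single leaf gives STAR
#' close to 1 and mutual shading drives it below 1.
#'
#' @inheritParams convex_hull_volume
#' @param directions `46` (default hemisphere set), any direction count, the
#'   string `"zenith"`, or an m x 3 matrix of unit view vectors
#' @param leaf_radius disk radius in meters; default half the median
#'   nearest-neighbour distance of the cloud (scale-free)
#' @param grid_resolution rasterization cell size in meters; must be smaller
#'   than `leaf_radius` (default `leaf_radius / 4`)
#' @param total_leaf_area one-sided leaf area (m^2); default `n_points *
#'   leaf_area_weight` when the cloud carries a weight, else `n_points * pi *
#'   leaf_radius^2`
#' @return list of class `star_result`: `star`, `silhouette_areas` (m^2, one
#'   per direction), `total_leaf_area`, `directions`, `leaf_radius`,
#'   `grid_resolution`
#' @export
compute_star <- function(cloud, directions = 46, leaf_radius = NULL,
                         grid_resolution = NULL, total_leaf_area = NULL) {
  pts <- as_cloud_matrix(cloud)
  if (nrow(pts) < 1L) stopf("empty point cloud")
  if (is.character(directions) && identical(directions, "zenith"))
    directions <- 1
  if (is.numeric(directions) && length(directions) == 1L)
    directions <- star_directions(directions)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L || nrow(directions) < 1L)
    stopf("'directions' must be an m x 3 matrix of unit vectors (m >= 1)")
  directions <- directions / sqrt(rowSums(directions^2))
  if (is.null(leaf_radius)) leaf_radius <- median_nn_distance(pts) / 2
  chk_num(leaf_radius, "leaf_radius", lower = 0, strict = TRUE)
  if (is.null(grid_resolution)) grid_resolution <- leaf_radius / 4
  if (grid_resolution >= leaf_radius)
    stopf("grid_resolution (%g) must be smaller than leaf_radius (%g)",
          grid_resolution, leaf_radius)
  if (is.null(total_leaf_area)) {
    w <- if (inherits(cloud, "point_cloud")) cloud$leaf_area_weight else NULL
    total_leaf_area <- if (!is.null(w)) nrow(pts) * w
                       else nrow(pts) * pi * leaf_radius^2
  }
  chk_num(total_leaf_area, "total_leaf_area", lower = 0, strict = TRUE)

  sil <- apply(directions, 1, function(d) {
    silhouette_area(pts, d, leaf_radius, grid_resolution)
  })
  structure(list(star = mean(sil / total_leaf_area),
                 silhouette_areas = sil,
                 total_leaf_area = total_leaf_area,
                 directions = directions,
                 leaf_radius = leaf_radius,
                 grid_resolution = grid_resolution),
            class = "star_result")
}

#' @export
print.star_result <- function(x, ...) {
  cat(sprintf("<star_result> STAR = %.4f over %d directions (TLA %.3f m^2)\n",
              x$star, nrow(x$directions), x$total_leaf_area))
  invisible(x)
}

# Area of the union of circles of radius r centred at the points projected
# along direction d, by counting grid cells whose centre lies in some circle.
silhouette_area <- function(pts, d, r, g) {
  # orthonormal basis of the projection plane
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  u <- pts %*% cbind(e1, e2)
  u0 <- apply(u, 2, min) - r - g
  nu <- ceiling((max(u[, 1]) + r + g - u0[1]) / g)
  nv <- ceiling((max(u[, 2]) + r + g - u0[2]) / g)
  ci <- floor((u[, 1] - u0[1]) / g)   # 0-based cell of each centre
  cj <- floor((u[, 2] - u0[2]) / g)
  k <- ceiling(r / g) + 1L
  covered <- logical(nu * nv)
  for (a in -k:k) {
    for (b in -k:k) {
      ia <- ci + a
      jb <- cj + b
      # cell-centre coordinates of candidate cells
      cx <- u0[1] + (ia + 0.5) * g
      cy <- u0[2] + (jb + 0.5) * g
      hit <- (cx - u[, 1])^2 + (cy - u[, 2])^2 < r^2
      if (any(hit)) {
        ok <- hit & ia >= 0 & ia < nu & jb >= 0 & jb < nv
        covered[ia[ok] * nv + jb[ok] + 1L] <- TRUE
      }
    }
  }
  sum(covered) * g^2
}
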