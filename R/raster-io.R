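#' In-memory single-band raster
#'
#' Minimal georeferenced raster: a numeric matrix plus an affine transform in
#' meters (origin of the lower-left corner and square pixel size). Row 1 of
#' the matrix is the southernmost row; pixel (i, j) has its centre at
#' `(xmin + (j - 0.5) * pixel_size, ymin + (i - 0.5) * pixel_size)`.
#'
#' @param values numeric matrix
#' @param xmin,ymin coordinates of the lower-left raster corner (m)
#' @param pixel_size square pixel edge (m), > 0
#' @return object of class `phen_raster`
#' @export
phen_raster <- function(values, xmin = 0, ymin = 0, pixel_size = 1) {
  values <- as.matrix(values)
  chk_num(pixel_size, "pixel_size", lower = 0, strict = TRUE)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 pixel_size = pixel_size),
            class = "phen_raster")
}

#' @export
print.phen_raster <- function(x, ...) {
  cat(sprintf("<phen_raster> %d x %d pixels, %.3g m/pixel, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$xmin, x$ymin))
  invisible(x)
}

# matrices of pixel-centre x and y coordinates
raster_centers <- function(r) {
  ny <- nrow(r$values); nx <- ncol(r$values)
  list(x = matrix(r$xmin + (seq_len(nx) - 0.5) * r$pixel_size, ny, nx,
                  byrow = TRUE),
       y = matrix(r$ymin + (seq_len(ny) - 0.5) * r$pixel_size, ny, nx))
}

#' Multiband reflectance stack
#'
#' Named list of co-registered reflectance rasters, one per wavelength. All
#' bands must share shape and georeferencing. Band names are wavelengths in
#' nm as strings ("450", "530", "570", "675", "730", "850").
#'
#' @param bands named list of numeric matrices (reflectance in \[0, 1\])
#' @inheritParams phen_raster
#' @return object of class `band_stack`
#' @export
band_stack <- function(bands, xmin = 0, ymin = 0, pixel_size = 1) {
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stopf("'bands' must be a named list (names = wavelengths in nm)")
  dims <- vapply(bands, function(m) dim(as.matrix(m)), integer(2))
  if (ncol(dims) > 1 && any(dims != dims[, 1]))
    stopf("band shape mismatch: all bands must share the same dimensions")
  structure(list(bands = lapply(bands, as.matrix), xmin = xmin, ymin = ymin,
                 pixel_size = pixel_size),
            class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<band_stack> bands %s: %d x %d pixels, %.3g m/pixel\n",
              paste(names(x$bands), collapse = "/"), d[1], d[2],
              x$pixel_size))
  invisible(x)
}

get_band <- function(stack, wavelength) {
  w <- as.character(wavelength)
  if (!w %in% names(stack$bands))
    stopf("band %s nm missing from stack (have: %s)", w,
          paste(names(stack$bands), collapse = ", "))
  stack$bands[[w]]
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format (header of ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value followed by rows north to south).
#'
#' @param r a [phen_raster()]
#' @param path file path (conventionally `.asc`)
#' @param digits significant digits written
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a [phen_raster()]
#' @export
write_ascii_grid <- function(r, path, digits = 7) {
  stopifnot(inherits(r, "phen_raster"))
  v <- r$values
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.10g", r$xmin),
               sprintf("yllcorner %.10g", r$ymin),
               sprintf("cellsize %.10g", r$pixel_size),
               "NODATA_value -9999"), con)
  for (i in rev(seq_len(nrow(v)))) # top row first
    writeLines(paste(signif(v[i, ], digits), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stopf("raster file not found: %s", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stopf("malformed ASCII grid header in %s (needs %s)", path,
          paste(need, collapse = ", "))
  body <- lines[i:length(lines)]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stopf("truncated ASCII grid %s: expected %d values, found %d", path,
          hdr$ncols * hdr$nrows, length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE] # back to south-first rows
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  phen_raster(m, xmin = hdr$xllcorner %||% 0, ymin = hdr$yllcorner %||% 0,
              pixel_size = hdr$cellsize)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an ASCII PLY point cloud
#'
#' Minimal PLY support for crown clouds: ASCII format, x/y/z float vertex
#' properties.
#'
#' @param cloud a [point_cloud()] or n x 3 matrix
#' @param path file path
#' @return `write_ply` returns `path` invisibly; `read_ply` returns a
#'   [point_cloud()]
#' @export
write_ply <- function(cloud, path) {
  pts <- as_cloud_matrix(cloud)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pts)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  writeLines(apply(pts, 1, function(p)
    paste(formatC(p, format = "g", digits = 9), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stopf("PLY file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stopf("%s is not a PLY file", path)
  if (!grepl("ascii", lines[2]))
    stopf("only ASCII PLY is supported (%s)", path)
  endh <- match("end_header", lines)
  if (is.na(endh)) stopf("malformed PLY %s: no end_header", path)
  nv_line <- grep("^element vertex", lines[seq_len(endh)], value = TRUE)
  if (length(nv_line) != 1) stopf("malformed PLY %s: vertex element missing", path)
  nv <- as.integer(strsplit(nv_line, "\\s+")[[1]][3])
  body <- lines[(endh + 1):(endh + nv)]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  if (length(vals) %% nv != 0)
    stopf("truncated PLY %s: expected %d vertices", path, nv)
  m <- matrix(vals, nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  point_cloud(m, tree_id = sub("\\.ply$", "", basename(path)))
}

#' Read a whitespace-delimited XYZ point cloud
#'
#' @param path text file with three numeric columns (x y z), no header
#' @return a [point_cloud()]
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stopf("XYZ file not found: %s", path)
  m <- as.matrix(read.table(path))
  if (ncol(m) < 3) stopf("%s: expected at least 3 columns", path)
  point_cloud(m[, 1:3, drop = FALSE],
              tree_id = sub("\\.[A-Za-z]+$", "", basename(path)))
}
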