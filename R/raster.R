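#' In-memory single-band raster
#'
#' A `grazint_raster` is a regular planar grid of one variable (elevation,
#' reflectance, NDVI, density, intensity, ...). Row 1 is the northernmost
#' row; `origin` is the outer corner of the top-left cell, so cell `[i, j]`
#' covers the half-open square
#' `[x0 + (j-1)s, x0 + js) x (y0 - is, y0 - (i-1)s]`.
#'
#' @param values numeric matrix (rows x cols), row 1 north. `NA` marks nodata.
#' @param origin numeric length-2, planar coordinates (x, y) of the top-left
#'   outer corner, in metres.
#' @param cell_size cell edge length in metres, > 0.
#' @param band what the band means; one of `"dem"`, `"nir"`, `"red"`,
#'   `"ndvi"`, `"slope"`, `"aspect"`, `"density"`, `"intensity"`,
#'   `"generic"`.
#' @return an object of class `grazint_raster`.
#' @export
new_raster <- function(values, origin, cell_size, band = "generic") {
  band <- match.arg(band, c("dem", "nir", "red", "ndvi", "slope", "aspect",
                            "density", "intensity", "grades", "generic"))
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 1, ncol(values) >= 1)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (length(origin) != 2 || !all(is.finite(origin)))
    stop("origin must be two finite planar coordinates")
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size), band = band),
            class = "grazint_raster")
}

#' @export
print.grazint_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<grazint_raster> band=%s  %d x %d cells @ %g m\n",
              x$band, nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  origin (top-left): %g, %g\n", x$origin[1], x$origin[2]))
  if (length(v))
    cat(sprintf("  range: [%g, %g], nodata cells: %d\n", min(v), max(v),
                sum(!is.finite(x$values))))
  invisible(x)
}

#' Raster extent as (xmin, xmax, ymin, ymax)
#' @param r a `grazint_raster`
#' @return numeric length-4 vector
#' @export
raster_extent <- function(r) {
  c(xmin = r$origin[1], xmax = r$origin[1] + ncol(r$values) * r$cell_size,
    ymin = r$origin[2] - nrow(r$values) * r$cell_size, ymax = r$origin[2])
}

#' Row/column of the cells containing points
#'
#' Vectorised; points on a shared edge belong to the cell to the
#' east/south of it (half-open cells).
#'
#' @param r a `grazint_raster`
#' @param x,y planar coordinates (metres)
#' @return integer matrix with columns `row`, `col`; `NA` outside the extent
#' @export
cell_of <- function(r, x, y) {
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row <- floor((r$origin[2] - y) / r$cell_size) + 1L
  # top and left edges are inside the first row/col
  row[y == r$origin[2]] <- 1L
  bad <- row < 1L | row > nrow(r$values) | col < 1L | col > ncol(r$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Planar coordinates of cell centres
#' @param r a `grazint_raster`
#' @param row,col cell indices (vectorised)
#' @return matrix with columns `x`, `y`
#' @export
cell_center <- function(r, row, col) {
  cbind(x = r$origin[1] + (col - 0.5) * r$cell_size,
        y = r$origin[2] - (row - 0.5) * r$cell_size)
}

#' Sample raster values at points
#'
#' Nearest-cell lookup by default; `"bilinear"` interpolates between the
#' four surrounding cell centres (suitable for continuous bands). Nodata
#' propagates: a bilinear query touching a nodata cell returns `NA`.
#'
#' @param r a `grazint_raster`
#' @param xy two-column matrix (or length-2 vector) of planar coordinates
#' @param method `"nearest"` or `"bilinear"`
#' @return numeric vector of sampled values
#' @export
sample_raster <- function(r, xy, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  ext <- raster_extent(r)
  out <- xy[, 1] < ext["xmin"] | xy[, 1] > ext["xmax"] |
         xy[, 2] < ext["ymin"] | xy[, 2] > ext["ymax"]
  if (any(out)) {
    i <- which(out)[1]
    stop(sprintf("point (%g, %g) is outside the raster extent [%g, %g] x [%g, %g]",
                 xy[i, 1], xy[i, 2], ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"]))
  }
  if (method == "nearest") {
    rc <- cell_of(r, xy[, 1], xy[, 2])
    return(r$values[cbind(rc[, "row"], rc[, "col"])])
  }
  # bilinear in cell-centre coordinates, clamped at the border
  s <- r$cell_size
  gx <- (xy[, 1] - r$origin[1]) / s - 0.5   # 0 at centre of col 1
  gy <- (r$origin[2] - xy[, 2]) / s - 0.5
  nr <- nrow(r$values); nc <- ncol(r$values)
  j0 <- pmin(pmax(floor(gx), 0), nc - 1); j1 <- pmin(j0 + 1, nc - 1)
  i0 <- pmin(pmax(floor(gy), 0), nr - 1); i1 <- pmin(i0 + 1, nr - 1)
  tx <- pmin(pmax(gx - j0, 0), 1); ty <- pmin(pmax(gy - i0, 0), 1)
  v00 <- r$values[cbind(i0 + 1, j0 + 1)]; v01 <- r$values[cbind(i0 + 1, j1 + 1)]
  v10 <- r$values[cbind(i1 + 1, j0 + 1)]; v11 <- r$values[cbind(i1 + 1, j1 + 1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' followed by rows north to south. `NA` cells are written as the nodata
#' sentinel (-9999).
#'
#' @param r a `grazint_raster`
#' @param path output file path
#' @param nodata sentinel written for `NA` cells
#' @return `path`, invisibly
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  ext <- raster_extent(r)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", ext["xmin"]),
    sprintf("yllcorner %.10g", ext["ymin"]),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  v <- r$values
  v[!is.finite(v)] <- nodata
  utils::write.table(format(v, digits = 9, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path
#' @param band band meaning for the result (see [new_raster()])
#' @return a `grazint_raster`; sentinel cells become `NA`
#' @export
read_ascii_grid <- function(path, band = "generic") {
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (l in lines) {
    kv <- strsplit(trimws(l), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: header incomplete in ", path)
  v <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(v, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  new_raster(m, origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
             cell_size = hdr$cellsize, band = band)
}
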