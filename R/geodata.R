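#' Normalized difference vegetation index from band rasters
#'
#' Computes per-cell `(NIR - red) / (NIR + red)`. Cells where the
#' denominator is zero become nodata. Negative values (possible over bare
#' soil or water) are clamped to 0 so the result lies in \[0, 1\], the range
#' meaningful for vegetation cover; the number of clamped cells is reported
#' via a message and attached as attribute `"clamped"`, and the pre-clamp
#' minimum as `"preclamp_min"`.
#'
#' @param nir,red reflectance rasters with identical shape, origin and cell
#'   size
#' @return an NDVI raster in \[0, 1\]
#' @export
compute_ndvi <- function(nir, red) {
  stopifnot(inherits(nir, "grazint_raster"), inherits(red, "grazint_raster"))
  if (!identical(dim(nir$values), dim(red$values)) ||
      !isTRUE(all.equal(nir$origin, red$origin)) ||
      !isTRUE(all.equal(nir$cell_size, red$cell_size)))
    stop("nir and red rasters must share shape, origin and cell size")
  den <- nir$values + red$values
  num <- nir$values - red$values
  v <- num / den
  v[den == 0] <- NA_real_
  clamped <- sum(v < 0, na.rm = TRUE)
  preclamp_min <- suppressWarnings(min(v, na.rm = TRUE))
  if (clamped > 0) {
    message(sprintf("compute_ndvi: clamped %d negative cells to 0 (pre-clamp min %.4f)",
                    clamped, preclamp_min))
    v[v < 0] <- 0
  }
  out <- new_raster(v, nir$origin, nir$cell_size, band = "ndvi")
  attr(out, "clamped") <- clamped
  attr(out, "preclamp_min") <- preclamp_min
  out
}

#' Slope and aspect from a DEM (Horn's method)
#'
#' Gradient by Horn's 3x3 finite differences with edge replication at the
#' border. Slope is `atan(|grad z|)` in degrees (0-90). Aspect is the
#' compass direction of the downslope vector, degrees clockwise from north
#' in \[0, 360); flat cells (gradient magnitude < `flat_tol`) get `NA`
#' aspect.
#'
#' @param dem elevation raster, at least 3x3
#' @param flat_tol gradient magnitude below which a cell counts as flat
#' @return list with `slope` and `aspect` rasters
#' @export
compute_slope_aspect <- function(dem, flat_tol = 1e-8) {
  stopifnot(inherits(dem, "grazint_raster"))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("DEM must be at least 3x3 for Horn's method")
  s <- dem$cell_size
  # replicate edges, then index the 8 neighbours of every interior cell
  zp <- z[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  a <- zp[i - 1, j - 1]; b <- zp[i - 1, j]; cc <- zp[i - 1, j + 1]
  d <- zp[i,     j - 1];                    f <- zp[i,     j + 1]
  g <- zp[i + 1, j - 1]; h <- zp[i + 1, j]; k <- zp[i + 1, j + 1]
  dzdx <- ((cc + 2 * f + k) - (a + 2 * d + g)) / (8 * s)   # east +
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + k)) / (8 * s)   # north + (row 1 is north)
  grad <- sqrt(dzdx^2 + dzdy^2)
  slope <- atan(grad) * 180 / pi
  # downslope direction = -grad vector; compass = atan2(east, north)
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[grad < flat_tol] <- NA_real_
  list(slope = new_raster(slope, dem$origin, s, band = "slope"),
       aspect = new_raster(aspect, dem$origin, s, band = "aspect"))
}
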