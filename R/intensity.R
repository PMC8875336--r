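#' Intake model constants
#'
#' The constant-rate intake model: grazing sheep remove dry matter worth
#' 2-4% of body weight per day; at a dry-to-fresh ratio of about 39% this
#' corresponds to fresh-grass intake of 7.6% of body weight. Only a
#' fraction `feeding_time_fraction` (84.92-90.19%, default 86%) of the
#' grazing day is spent actually feeding.
#'
#' @param dry_matter_fraction_of_weight daily dry-matter intake as a
#'   fraction of body weight
#' @param dry_to_fresh_ratio dry matter mass per unit fresh mass
#' @param fresh_intake_fraction daily fresh intake as a fraction of body
#'   weight
#' @param feeding_time_fraction share of grazing time spent feeding (a)
#' @return an object of class `intake_model`
#' @export
intake_model <- function(dry_matter_fraction_of_weight = 0.03,
                         dry_to_fresh_ratio = 0.39,
                         fresh_intake_fraction = 0.076,
                         feeding_time_fraction = 0.86) {
  vals <- c(dry_matter_fraction_of_weight, dry_to_fresh_ratio,
            fresh_intake_fraction, feeding_time_fraction)
  if (any(vals <= 0 | vals >= 1))
    stop("all intake model fractions must lie strictly in (0, 1)")
  structure(list(dry_matter_fraction_of_weight = dry_matter_fraction_of_weight,
                 dry_to_fresh_ratio = dry_to_fresh_ratio,
                 fresh_intake_fraction = fresh_intake_fraction,
                 feeding_time_fraction = feeding_time_fraction),
            class = "intake_model")
}

#' Daily fresh-grass intake of one animal
#'
#' `"fresh"` mode: `weight * fresh_intake_fraction`, in grams. `"derived"`
#' mode derives the fresh intake from the dry-matter fraction and the
#' dry-to-fresh ratio (`weight * dm / ratio`); the two routes must agree
#' within 5% or the model is rejected as inconsistent.
#'
#' @param weight body weight (kg), > 0
#' @param model an [intake_model()]
#' @param mode `"fresh"` or `"derived"`
#' @return daily intake in grams
#' @export
daily_intake <- function(weight, model = intake_model(),
                         mode = c("fresh", "derived")) {
  mode <- match.arg(mode)
  if (!is.numeric(weight) || any(weight <= 0))
    stop("weight must be positive (kg)")
  if (mode == "derived") {
    implied <- model$dry_matter_fraction_of_weight / model$dry_to_fresh_ratio
    if (abs(implied - model$fresh_intake_fraction) / model$fresh_intake_fraction > 0.05)
      stop("derived fresh fraction disagrees with fresh_intake_fraction by more than 5%")
    return(weight * implied * 1000)
  }
  weight * model$fresh_intake_fraction * 1000
}

#' Average grazing (intake) rate over a day
#'
#' The constant-rate model's daily average rate in grams per second.
#' `"literal"` mode is `IZ / TZ`; `"corrected"` mode (default) divides by
#' the feeding time `TZ * a` instead of the total grazing time, since only
#' the feeding fraction of the day removes forage.
#'
#' @param iz total daily intake (g)
#' @param tz effective grazing time of the day (s), > 0
#' @param a feeding-time fraction
#' @param mode `"corrected"` or `"literal"`
#' @return intake rate (g/s)
#' @export
average_grazing_rate <- function(iz, tz, a = 0.86,
                                 mode = c("corrected", "literal")) {
  mode <- match.arg(mode)
  if (tz <= 0) stop("TZ must be positive seconds")
  if (mode == "literal") iz / tz else iz / (tz * a)
}

#' Intake attributed to one trajectory segment
#'
#' `rate * duration * feeding_fraction`. With the literal rate and
#' `feeding_fraction = 1` this is the plain constant-rate allocation; with
#' the corrected rate the `feeding_fraction` multiplier accounts for the
#' share of the segment spent feeding, and a full day's segments telescope
#' back to the daily intake.
#'
#' @param segment a segment row/data.frame (uses its `duration`) or a
#'   numeric duration in seconds
#' @param rate intake rate (g/s), >= 0
#' @param feeding_fraction fraction of the segment spent feeding
#' @return grams (vectorised over segments)
#' @export
segment_intake <- function(segment, rate, feeding_fraction = 1) {
  if (rate < 0) stop("rate must be non-negative")
  dur <- if (is.data.frame(segment) || is.list(segment)) segment$duration else segment
  rate * dur * feeding_fraction
}

#' Square analysis grid with segment buffers
#'
#' @param extent width and height of the gridded area (m)
#' @param cell_size cell edge (m), default 13
#' @param origin planar coordinates of the lower-left corner; snapped down
#'   to a multiple of `cell_size` for reproducible cell indexing
#' @param buffer_half_width half-width of the rectangular segment buffer (m)
#' @return an object of class `grid_spec`
#' @export
grid_spec <- function(extent, cell_size = 13, origin = c(0, 0),
                      buffer_half_width = 3) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (buffer_half_width < 0) stop("buffer_half_width must be non-negative")
  origin <- floor(origin / cell_size) * cell_size
  structure(list(origin = origin, cell_size = cell_size,
                 extent = extent, buffer_half_width = buffer_half_width,
                 nrows = ceiling(extent[2] / cell_size),
                 ncols = ceiling(extent[1] / cell_size)),
            class = "grid_spec")
}

# zero raster on a grid_spec (top-left raster origin from the lower-left
# grid origin)
empty_grid_raster <- function(grid, band = "generic") {
  new_raster(matrix(0, grid$nrows, grid$ncols),
             origin = c(grid$origin[1], grid$origin[2] + grid$nrows * grid$cell_size),
             cell_size = grid$cell_size, band = band)
}

#' Grid cells touched by a segment's rectangular buffer
#'
#' The buffer is the rectangle of half-width `grid$buffer_half_width`
#' along the segment axis with flat (capped) ends; a zero-length segment
#' uses the axis-aligned square of the same half-width about the point.
#' Each intersecting cell gets weight `overlap area / buffer area`, so
#' weights sum to 1 when the buffer lies fully inside the grid extent; the
#' clipped-away fraction (if any) is reported in attribute `"clipped"`.
#'
#' @param segment one segment row (needs `x0`, `y0`, `x1`, `y1`) or a
#'   numeric vector `c(x0, y0, x1, y1)`
#' @param grid a [grid_spec()]
#' @return data.frame with columns `row`, `col`, `weight`
#' @export
buffer_cells <- function(segment, grid) {
  p <- if (is.numeric(segment)) segment else
    c(segment$x0[1], segment$y0[1], segment$x1[1], segment$y1[1])
  h <- grid$buffer_half_width
  dx <- p[3] - p[1]; dy <- p[4] - p[2]
  L <- sqrt(dx^2 + dy^2)
  if (L < 1e-12) {
    rect <- cbind(c(p[1] - h, p[1] + h, p[1] + h, p[1] - h),
                  c(p[2] - h, p[2] - h, p[2] + h, p[2] + h))
    total <- (2 * h)^2
  } else {
    ux <- dx / L; uy <- dy / L
    nx <- -uy; ny <- ux
    rect <- cbind(c(p[1] + h * nx, p[3] + h * nx, p[3] - h * nx, p[1] - h * nx),
                  c(p[2] + h * ny, p[4] + h * ny, p[4] - h * ny, p[2] - h * ny))
    total <- L * 2 * h
  }
  s <- grid$cell_size
  ox <- grid$origin[1]; oy_top <- grid$origin[2] + grid$nrows * s
  jmin <- max(1L, floor((min(rect[, 1]) - ox) / s) + 1L)
  jmax <- min(grid$ncols, floor((max(rect[, 1]) - ox) / s) + 1L)
  imin <- max(1L, floor((oy_top - max(rect[, 2])) / s) + 1L)
  imax <- min(grid$nrows, floor((oy_top - min(rect[, 2])) / s) + 1L)
  rows <- integer(0); cols <- integer(0); areas <- numeric(0)
  if (jmin <= jmax && imin <= imax) {
    for (i in imin:imax) for (j in jmin:jmax) {
      a <- poly_area(clip_poly_box(rect,
                                   ox + (j - 1) * s, ox + j * s,
                                   oy_top - i * s, oy_top - (i - 1) * s))
      if (a > 0) { rows <- c(rows, i); cols <- c(cols, j); areas <- c(areas, a) }
    }
  }
  out <- data.frame(row = rows, col = cols, weight = areas / total)
  attr(out, "clipped") <- 1 - sum(out$weight)
  out
}

#' Allocate a day's intake onto the analysis grid
#'
#' Two allocation modes. `"conservative"` (default) spreads each segment's
#' intake over the cells its buffer covers, weighted by overlap area, so
#' the total allocated mass equals the sum of segment intakes exactly.
#' `"literal_eq5"` evaluates the closed-form cell intensity
#' `F = IZ * Ti * Ci / (sum(Ci) * TZ * S)` where `Ti` is the summed dwell
#' time of segment midpoints in cell i, `Ci` their count and `S` the cell
#' area; it reproduces the published formula verbatim but double-weights
#' occupancy and conserves mass only in degenerate cases.
#'
#' @param segments segment data.frame from [segmentize()]
#' @param iz total daily intake IZ (g)
#' @param tz effective grazing time TZ (s)
#' @param grid a [grid_spec()]
#' @param mode `"conservative"` or `"literal_eq5"`
#' @param model an [intake_model()] (supplies the feeding-time fraction)
#' @param feeding_correction use the feeding-time-corrected rate in
#'   conservative mode (ignored by `literal_eq5`, whose closed form
#'   cancels the correction)
#' @return an `intensity_grid`: list with `values` (g/m^2 raster),
#'   `contributing_points` (count raster), `total_time`, `total_intake`,
#'   `allocated_g`, `grid`, `mode`
#' @export
allocate_intensity <- function(segments, iz, tz, grid,
                               mode = c("conservative", "literal_eq5"),
                               model = intake_model(),
                               feeding_correction = TRUE) {
  mode <- match.arg(mode)
  if (nrow(segments) == 0) stop("cannot allocate an empty segment list")
  S <- grid$cell_size^2
  f <- empty_grid_raster(grid, band = "intensity")
  cnt <- empty_grid_raster(grid, band = "density")
  rc <- cell_of(f, segments$mid_x, segments$mid_y)
  ok <- !is.na(rc[, 1])
  if (mode == "literal_eq5") {
    ti <- tapply(segments$duration[ok], paste(rc[ok, 1], rc[ok, 2]), sum)
    ci <- tapply(rep(1, sum(ok)), paste(rc[ok, 1], rc[ok, 2]), sum)
    keys <- names(ti)
    rcu <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
    sum_ci <- sum(ci)
    if (sum_ci == 0) stop("no segment midpoints fall inside the grid")
    f$values[rcu] <- iz * ti * ci / (sum_ci * tz * S)
    cnt$values[rcu] <- ci
    allocated <- sum(f$values) * S
  } else {
    a <- model$feeding_time_fraction
    rate <- average_grazing_rate(iz, tz, a = a,
                                 mode = if (feeding_correction) "corrected" else "literal")
    ff <- if (feeding_correction) a else 1
    intakes <- segment_intake(segments, rate, feeding_fraction = ff)
    for (k in seq_len(nrow(segments))) {
      bc <- buffer_cells(segments[k, ], grid)
      if (nrow(bc))
        f$values[cbind(bc$row, bc$col)] <- f$values[cbind(bc$row, bc$col)] +
          intakes[k] * bc$weight / S
    }
    if (any(ok)) {
      tb <- table(paste(rc[ok, 1], rc[ok, 2]))
      rcu <- do.call(rbind, lapply(strsplit(names(tb), " "), as.integer))
      cnt$values[rcu] <- as.numeric(tb)
    }
    allocated <- sum(f$values) * S
  }
  structure(list(values = f, contributing_points = cnt,
                 total_time = tz, total_intake = iz,
                 allocated_g = allocated, grid = grid, mode = mode),
            class = "intensity_grid")
}

#' Superpose intensity grids across days and animals
#'
#' Cellwise sum of intensity and contributing-point counts; totals add.
#' All grids must share the same grid specification.
#'
#' @param grids list of `intensity_grid` objects
#' @return a single `intensity_grid`
#' @export
superpose <- function(grids) {
  if (!length(grids)) stop("no grids to superpose")
  g0 <- grids[[1]]
  for (g in grids[-1]) {
    if (!isTRUE(all.equal(g$grid$origin, g0$grid$origin)) ||
        g$grid$cell_size != g0$grid$cell_size ||
        g$grid$nrows != g0$grid$nrows || g$grid$ncols != g0$grid$ncols)
      stop("all intensity grids must share the same grid specification")
  }
  out <- g0
  for (g in grids[-1]) {
    out$values$values <- out$values$values + g$values$values
    out$contributing_points$values <-
      out$contributing_points$values + g$contributing_points$values
    out$total_time <- out$total_time + g$total_time
    out$total_intake <- out$total_intake + g$total_intake
    out$allocated_g <- out$allocated_g + g$allocated_g
  }
  out$mode <- if (length(unique(vapply(grids, `[[`, "", "mode"))) == 1)
    g0$mode else "mixed"
  out
}
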