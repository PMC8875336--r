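#' Simulation configuration for a synthetic grazing system
#'
#' Bundles the parameters of the synthetic study area and flock: a roughly
#' 210-ha paddock, 2-minute collar fixes over a 06:00-18:00 grazing day, a
#' pen and a water point, grazing patches of elevated NDVI, and a
#' 200-animal flock whose weights fall 15/70/15 percent into the
#' below-40 kg, 40-60 kg and above-60 kg classes.
#'
#' Planar coordinates are local metres with (0, 0) at the south-west corner
#' of the area; `anchor_lonlat` places that origin on the globe for lon/lat
#' export (equirectangular about the anchor).
#'
#' @param seed integer master seed; all generator randomness derives from it
#' @param area_extent width and height of the area in metres
#' @param fix_interval collar fix interval in seconds
#' @param day_start,day_end local clock hours of pen departure and return
#' @param pen_location,water_location,rest_location planar coordinates of
#'   the pen, the water point, and the midday rest site
#' @param n_grazing_patches number of elevated-NDVI grazing patches
#' @param flock_size number of animals
#' @param weight_class_proportions fractions in the <40, 40-60, >60 kg
#'   classes; must sum to 1
#' @param anchor_lonlat lon/lat (degrees) of the planar origin
#' @param dem_cell DEM / band raster cell size in metres
#' @param graze_speed,travel_speed mean movement speeds (m/s) while grazing
#'   and while travelling between sites
#' @param crw_kappa von Mises turning-angle concentration of the grazing
#'   correlated random walk
#' @param ndvi_bias Metropolis acceptance strength toward higher NDVI
#' @param pen_dwell,drink_dwell,rest_dwell dwell durations in seconds
#' @return an object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       area_extent = c(1450, 1450),
                       fix_interval = 120,
                       day_start = 6, day_end = 18,
                       pen_location = c(180, 160),
                       water_location = c(1050, 420),
                       rest_location = c(650, 1020),
                       n_grazing_patches = 4,
                       flock_size = 200,
                       weight_class_proportions = c(0.15, 0.70, 0.15),
                       anchor_lonlat = c(107.6, 39.0),
                       dem_cell = 30,
                       graze_speed = 0.30, travel_speed = 0.90,
                       crw_kappa = 4, ndvi_bias = 6,
                       pen_dwell = 600, drink_dwell = 900, rest_dwell = 3600) {
  if (abs(sum(weight_class_proportions) - 1) > 1e-9)
    stop("weight_class_proportions must sum to 1")
  if (fix_interval <= 0) stop("fix_interval must be positive")
  if (day_end <= day_start) stop("day_end must be after day_start")
  inside <- function(p) all(p >= 0) && p[1] <= area_extent[1] && p[2] <= area_extent[2]
  if (!inside(pen_location) || !inside(water_location) || !inside(rest_location))
    stop("pen, water and rest locations must lie inside the area extent")
  structure(list(seed = as.integer(seed), area_extent = area_extent,
                 fix_interval = fix_interval, day_start = day_start,
                 day_end = day_end, pen_location = pen_location,
                 water_location = water_location, rest_location = rest_location,
                 n_grazing_patches = n_grazing_patches, flock_size = flock_size,
                 weight_class_proportions = weight_class_proportions,
                 anchor_lonlat = anchor_lonlat, dem_cell = dem_cell,
                 graze_speed = graze_speed, travel_speed = travel_speed,
                 crw_kappa = crw_kappa, ndvi_bias = ndvi_bias,
                 pen_dwell = pen_dwell, drink_dwell = drink_dwell,
                 rest_dwell = rest_dwell),
            class = "sim_config")
}

#' Draw flock body weights by weight class
#'
#' Class counts come from the largest-remainder apportionment of
#' `weight_class_proportions`, so counts always sum to `flock_size`
#' exactly; within-class weights are uniform on 30-40, 40-60 and 60-75 kg.
#'
#' @param config a [sim_config()]
#' @return numeric vector of `flock_size` weights (kg), with a
#'   `"class_counts"` attribute
#' @export
simulate_flock_weights <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$flock_size <= 0) stop("flock_size must be positive")
  counts <- largest_remainder(config$flock_size, config$weight_class_proportions)
  set.seed(derive_seed(config$seed, "flock"))
  lo <- c(30, 40, 60); hi <- c(40, 60, 75)
  w <- unlist(lapply(1:3, function(k) stats::runif(counts[k], lo[k], hi[k])))
  attr(w, "class_counts") <- counts
  w
}

# largest-remainder apportionment; ties broken by class order
largest_remainder <- function(n, props) {
  if (abs(sum(props) - 1) > 1e-9) stop("proportions must sum to 1")
  raw <- n * props
  base <- floor(raw)
  left <- round(n - sum(base))
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# deterministic grazing patch centres, well separated, away from borders
grazing_patches <- function(config) {
  set.seed(derive_seed(config$seed, "patches"))
  margin <- 180; min_sep <- 320
  ext <- config$area_extent
  centres <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centres) < config$n_grazing_patches && tries < 2000) {
    p <- c(stats::runif(1, margin, ext[1] - margin),
           stats::runif(1, margin, ext[2] - margin))
    ok <- nrow(centres) == 0 ||
      min(sqrt((centres[, 1] - p[1])^2 + (centres[, 2] - p[2])^2)) >= min_sep
    # keep patches off the pen so the pen cluster is a rest, not grazing, zone
    ok <- ok && sqrt(sum((p - config$pen_location)^2)) > 250
    if (ok) centres <- rbind(centres, p)
    tries <- tries + 1
  }
  centres
}

#' Generate a smooth synthetic DEM
#'
#' Sum of three low-frequency sinusoidal ridges plus small white noise on a
#' 30-m grid (synthetic stand-in for a 30-m elevation product).
#'
#' @param config a [sim_config()]
#' @param base_elev mean elevation (m)
#' @param amplitude relief amplitude (m); 0 gives a constant DEM
#' @param noise_sd white-noise standard deviation (m)
#' @return a `grazint_raster` with `band = "dem"`
#' @export
generate_terrain <- function(config, base_elev = 1300, amplitude = 25,
                             noise_sd = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "terrain"))
  s <- config$dem_cell
  ncols <- ceiling(config$area_extent[1] / s)
  nrows <- ceiling(config$area_extent[2] / s)
  cx <- (seq_len(ncols) - 0.5) * s
  cy <- nrows * s - (seq_len(nrows) - 0.5) * s  # row 1 north
  L <- max(config$area_extent)
  z <- matrix(base_elev, nrows, ncols)
  for (k in 1:3) {
    th <- stats::runif(1, 0, 2 * pi); ph <- stats::runif(1, 0, 2 * pi)
    fr <- 2 * pi * k / (1.6 * L)
    z <- z + (amplitude / k) *
      sin(fr * (outer(cy, cx * 0, "+") * sin(th) + outer(cy * 0, cx, "+") * cos(th)) + ph)
  }
  if (noise_sd > 0 && amplitude > 0)
    z <- z + matrix(stats::rnorm(nrows * ncols, 0, noise_sd), nrows, ncols)
  new_raster(z, origin = c(0, nrows * s), cell_size = s, band = "dem")
}

#' Generate NIR and red reflectance bands
#'
#' Builds a smooth background NDVI field (0.15-0.45) with Gaussian grazing
#' patches whose centre NDVI is drawn uniformly in \[0.58, 0.90\], then
#' factors it into NIR and red reflectances of constant total brightness so
#' that `(nir - red)/(nir + red)` reproduces the field exactly. Both
#' reflectances are strictly inside (0, 1].
#'
#' @param config a [sim_config()]
#' @param dem the DEM raster defining the grid
#' @param brightness total reflectance `nir + red`
#' @param patch_sigma Gaussian radius of grazing patches (m)
#' @return list with `nir` and `red` rasters (and the patch centres as the
#'   `"patches"` attribute)
#' @export
generate_bands <- function(config, dem, brightness = 0.5, patch_sigma = 130) {
  stopifnot(inherits(config, "sim_config"), inherits(dem, "grazint_raster"))
  patches <- grazing_patches(config)
  set.seed(derive_seed(config$seed, "bands"))
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  ctr_x <- matrix(rep((seq_len(nc) - 0.5) * dem$cell_size, each = nr), nr, nc)
  ctr_y <- matrix(rep(dem$origin[2] - (seq_len(nr) - 0.5) * dem$cell_size, nc), nr, nc)
  base <- 0.30 +
    0.10 * sin(2 * pi * ctr_x / (1.9 * max(config$area_extent)) + 0.7) *
           cos(2 * pi * ctr_y / (1.7 * max(config$area_extent)) + 1.3)
  targets <- stats::runif(nrow(patches), 0.58, 0.90)
  # take the strongest patch at each cell: centres hit their target exactly
  w <- matrix(0, nr, nc); tau <- matrix(0, nr, nc)
  for (k in seq_len(nrow(patches))) {
    d2 <- (ctr_x - patches[k, 1])^2 + (ctr_y - patches[k, 2])^2
    wk <- exp(-d2 / (2 * patch_sigma^2))
    upd <- wk > w
    w[upd] <- wk[upd]; tau[upd] <- targets[k]
  }
  ndvi <- base + w * (tau - base)
  ndvi <- pmin(pmax(ndvi, 0.02), 0.95)
  nir <- brightness * (1 + ndvi) / 2
  red <- brightness * (1 - ndvi) / 2
  out <- list(nir = new_raster(nir, dem$origin, dem$cell_size, band = "nir"),
              red = new_raster(red, dem$origin, dem$cell_size, band = "red"))
  attr(out, "patches") <- patches
  out
}

#' Generate a diurnal temperature series
#'
#' Sinusoid peaking in early afternoon plus white noise, sampled at the
#' collar fix interval across the grazing day. Summer days are warmer than
#' autumn days by construction.
#'
#' @param day_index integer day number (shifts the noise stream)
#' @param season `"summer"` or `"autumn"`
#' @param seed integer seed
#' @param fix_interval sampling interval (s)
#' @param day_start,day_end local clock hours
#' @param peak_hour clock hour of the temperature maximum
#' @param amplitude half-range of the diurnal cycle (deg C)
#' @param noise_sd noise standard deviation (deg C); 0 gives the exact
#'   sinusoid
#' @return data.frame with columns `hour` and `temp_c`, class
#'   `grazint_temperature`
#' @export
generate_temperature <- function(day_index, season = c("summer", "autumn"),
                                 seed = 1L, fix_interval = 120,
                                 day_start = 6, day_end = 18,
                                 peak_hour = 14, amplitude = 6, noise_sd = 0.8) {
  season <- match.arg(season)
  mean_c <- if (season == "summer") 24 else 10
  hour <- seq(day_start, day_end, by = fix_interval / 3600)
  temp <- mean_c + amplitude * cos(2 * pi * (hour - peak_hour) / 24)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "temp", day_index, if (season == "summer") 1 else 2))
    temp <- temp + stats::rnorm(length(hour), 0, noise_sd)
  }
  structure(data.frame(hour = hour, temp_c = temp),
            class = c("grazint_temperature", "data.frame"))
}

#' Simulate one animal-day of collar fixes with planted ground truth
#'
#' The day follows the structure of a herded grazing day: a short dwell at
#' the pen after the 06:00 departure, a morning grazing loop as a
#' correlated random walk whose steps are accepted with Metropolis
#' probability favouring higher NDVI, a mid-morning visit to the water
#' point (15-min drinking dwell), a midday rest dwell (60 min, low-speed
#' jitter with 1-m standard deviation), an afternoon grazing loop, and a
#' return leg that ends at the pen by 18:00. Fixes are emitted at the exact
#' collar interval, so a 12-h day at 120 s gives 361 fixes.
#'
#' The ground truth records the constant-rate intake of every segment
#' (daily intake spread uniformly over the day) and the planted intensity
#' field on a 13-m grid, plus the rest/drinking zone polygons, enabling
#' recovery tests downstream.
#'
#' @param config a [sim_config()]
#' @param animal_weight body weight in kg, > 0
#' @param day_index integer day number (varies the randomness)
#' @param ndvi optional NDVI raster; generated from `config` when `NULL`
#' @param animal_id identifier stored in the fix stream
#' @return list with `trajectory` (a fix data.frame of class
#'   `grazint_trajectory`: `animal_id`, `time`, `x`, `y`, `lon`, `lat`) and
#'   `ground_truth` (list: `intensity_field`, `zone_polygons`,
#'   `per_segment_intake`, `daily_intake_g`)
#' @export
simulate_trajectory <- function(config, animal_weight, day_index = 1,
                                ndvi = NULL, animal_id = "sheep_001") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(animal_weight) || animal_weight <= 0)
    stop("animal_weight must be a positive number of kilograms")
  if (is.null(ndvi)) {
    dem <- generate_terrain(config)
    ndvi <- compute_ndvi(generate_bands(config, dem)$nir,
                         generate_bands(config, dem)$red)
  }
  set.seed(derive_seed(config$seed, "traj", day_index, round(animal_weight * 1000)))
  dt <- config$fix_interval
  times <- seq(config$day_start * 3600, config$day_end * 3600, by = dt)
  n <- length(times)
  ext <- config$area_extent
  pen <- config$pen_location; water <- config$water_location
  rest <- config$rest_location

  ndvi_at <- function(p) {
    p <- pmin(pmax(p, 1e-6), ext - 1e-6)
    sample_raster(ndvi, matrix(p, ncol = 2))
  }
  clampp <- function(p) pmin(pmax(p, 15), ext - 15)

  pen_dwell_steps <- max(1, round(config$pen_dwell / dt))
  drink_steps <- max(1, round(config$drink_dwell / dt))
  rest_steps <- max(1, round(config$rest_dwell / dt))
  drink_start_step <- round(n * 0.35)
  rest_start_step <- round(n * 0.5)

  pos <- matrix(NA_real_, n, 2)
  pos[1, ] <- pen + stats::rnorm(2, 0, 2)
  heading <- stats::runif(1, 0, 2 * pi)
  state <- "pen_dwell"; dwell_left <- pen_dwell_steps - 1
  travel_step <- config$travel_speed * dt

  for (k in 2:n) {
    cur <- pos[k - 1, ]
    steps_left <- n - k
    dist_pen <- sqrt(sum((cur - pen)^2))
    # hand control to the return leg soon enough to make it home
    if (state %in% c("graze", "to_water", "to_rest") &&
        steps_left * travel_step <= dist_pen * 1.35 + 3 * travel_step)
      state <- "return"
    if (state == "graze" && k >= drink_start_step && k < rest_start_step &&
        !exists("drank", inherits = FALSE)) state <- "to_water"
    if (state == "graze" && k >= rest_start_step &&
        !exists("rested", inherits = FALSE)) state <- "to_rest"

    if (state == "pen_dwell") {
      pos[k, ] <- pen + stats::rnorm(2, 0, 1)
      dwell_left <- dwell_left - 1
      if (dwell_left <= 0) state <- "graze"
    } else if (state %in% c("to_water", "to_rest", "return")) {
      tgt <- switch(state, to_water = water, to_rest = rest, return = pen)
      d <- sqrt(sum((tgt - cur)^2))
      if (d < 10) {
        if (state == "to_water") { state <- "drink"; dwell_left <- drink_steps }
        else if (state == "to_rest") { state <- "rest"; dwell_left <- rest_steps }
        else { state <- "pen_jitter" }
        pos[k, ] <- cur + stats::rnorm(2, 0, 1)
      } else {
        ang <- atan2(tgt[2] - cur[2], tgt[1] - cur[1]) + rvonmises(1, 0, 25)
        step <- min(travel_step * stats::runif(1, 0.85, 1.1), d)
        pos[k, ] <- clampp(cur + step * c(cos(ang), sin(ang)))
        heading <- ang
      }
    } else if (state == "drink" || state == "rest") {
      centre <- if (state == "drink") water else rest
      pos[k, ] <- centre + stats::rnorm(2, 0, 1)
      dwell_left <- dwell_left - 1
      if (dwell_left <= 0) {
        if (state == "drink") assign("drank", TRUE)
        if (state == "rest") assign("rested", TRUE)
        state <- "graze"
      }
    } else if (state == "pen_jitter") {
      pos[k, ] <- pen + stats::rnorm(2, 0, 1)
    } else { # graze: NDVI-biased correlated random walk
      cur_ndvi <- ndvi_at(cur)
      accepted <- FALSE
      for (try in 1:8) {
        ang <- rvonmises(1, heading, config$crw_kappa)
        step <- config$graze_speed * dt * stats::rgamma(1, shape = 4, rate = 4)
        cand <- clampp(cur + step * c(cos(ang), sin(ang)))
        dn <- ndvi_at(cand) - cur_ndvi
        if (dn >= 0 || stats::runif(1) < exp(config$ndvi_bias * dn)) {
          pos[k, ] <- cand; heading <- ang; accepted <- TRUE; break
        }
      }
      if (!accepted) { pos[k, ] <- cur; heading <- stats::runif(1, 0, 2 * pi) }
    }
  }
  # guarantee the evening return lands at the pen
  if (sqrt(sum((pos[n, ] - pen)^2)) > 15) pos[n, ] <- pen + stats::rnorm(2, 0, 2)

  day0 <- as.POSIXct("2020-08-01 00:00:00", tz = "UTC") + (day_index - 1) * 86400
  ll <- planar_to_lonlat(pos[, 1], pos[, 2], config$anchor_lonlat)
  traj <- data.frame(animal_id = animal_id, time = day0 + times,
                     x = pos[, 1], y = pos[, 2], lon = ll[, "lon"], lat = ll[, "lat"])
  class(traj) <- c("grazint_trajectory", "data.frame")

  # planted ground truth: constant-rate intake over the day, midpoint-cell field
  iz <- daily_intake(animal_weight)
  tz <- (n - 1) * dt
  per_seg <- rep(iz * dt / tz, n - 1)
  gs <- 13
  gnc <- ceiling(ext[1] / gs); gnr <- ceiling(ext[2] / gs)
  field <- new_raster(matrix(0, gnr, gnc), origin = c(0, gnr * gs),
                      cell_size = gs, band = "intensity")
  mid <- (pos[-1, , drop = FALSE] + pos[-n, , drop = FALSE]) / 2
  rc <- cell_of(field, mid[, 1], mid[, 2])
  for (i in seq_len(n - 1))
    field$values[rc[i, 1], rc[i, 2]] <- field$values[rc[i, 1], rc[i, 2]] +
      per_seg[i] / gs^2
  sq <- function(c, h) cbind(c(c[1] - h, c[1] + h, c[1] + h, c[1] - h),
                             c(c[2] - h, c[2] - h, c[2] + h, c[2] + h))
  gt <- list(intensity_field = field,
             zone_polygons = list(
               list(class = "rest", name = "pen", coords = sq(pen, 25)),
               list(class = "rest", name = "rest_site", coords = sq(rest, 25)),
               list(class = "drinking", name = "water", coords = sq(water, 20))),
             per_segment_intake = per_seg,
             daily_intake_g = iz)
  list(trajectory = traj, ground_truth = gt)
}
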