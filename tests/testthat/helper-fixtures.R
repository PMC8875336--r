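# shared fixtures, built in code at test time

tiny_config <- function(seed = 3) sim_config(seed = seed)

# a toy planar trajectory: random walk fixes at a fixed interval
random_walk_trajectory <- function(n_fixes, seed, extent = c(400, 400),
                                   step_sd = 12, dt = 120) {
  set.seed(seed)
  xy <- matrix(0, n_fixes, 2)
  xy[1, ] <- extent / 2
  for (k in 2:n_fixes)
    xy[k, ] <- pmin(pmax(xy[k - 1, ] + stats::rnorm(2, 0, step_sd), 10), extent - 10)
  df <- data.frame(animal_id = "toy",
                   time = as.POSIXct("2020-08-01 06:00:00", tz = "UTC") +
                     (seq_len(n_fixes) - 1) * dt,
                   x = xy[, 1], y = xy[, 2])
  ll <- grazint:::planar_to_lonlat(df$x, df$y, c(107.6, 39.0))
  df$lon <- ll[, "lon"]; df$lat <- ll[, "lat"]
  class(df) <- c("grazint_trajectory", "data.frame")
  df
}

# brute-force KDE oracle: plain double loop over fixes x cells, same
# Gaussian kernel and 4-bandwidth cutoff as the contract states
kde_oracle <- function(xy, bandwidth, grid) {
  r <- grazint:::empty_grid_raster(grid, band = "density")
  s <- r$cell_size
  coef <- 1 / (2 * pi * bandwidth^2)
  cut2 <- (4 * bandwidth)^2
  for (i in seq_len(nrow(r$values))) {
    cy <- r$origin[2] - (i - 0.5) * s
    for (j in seq_len(ncol(r$values))) {
      cx <- r$origin[1] + (j - 0.5) * s
      acc <- 0
      for (k in seq_len(nrow(xy))) {
        d2 <- (cx - xy[k, 1])^2 + (cy - xy[k, 2])^2
        if (d2 <= cut2) acc <- acc + coef * exp(-d2 / (2 * bandwidth^2))
      }
      r$values[i, j] <- acc
    }
  }
  r
}

# Monte-Carlo buffer-weight oracle: rejection sampling of the rectangle
buffer_mc_oracle <- function(p, grid, n_pts = 1e5, seed = 1) {
  set.seed(seed)
  h <- grid$buffer_half_width
  dx <- p[3] - p[1]; dy <- p[4] - p[2]
  L <- sqrt(dx^2 + dy^2)
  if (L < 1e-12) {
    px <- stats::runif(n_pts, p[1] - h, p[1] + h)
    py <- stats::runif(n_pts, p[2] - h, p[2] + h)
  } else {
    u <- stats::runif(n_pts); v <- stats::runif(n_pts, -h, h)
    px <- p[1] + u * dx - v * dy / L
    py <- p[2] + u * dy + v * dx / L
  }
  s <- grid$cell_size
  oy_top <- grid$origin[2] + grid$nrows * s
  key <- paste(floor((oy_top - py) / s) + 1, floor((px - grid$origin[1]) / s) + 1)
  table(key) / n_pts
}

# 780-row table of standardized features with a target planted on the
# X7 variable set (NDVI, S, T, Ftemp, C)
planted_x7_table <- function(n = 780, sigma = 0.05, seed = 42) {
  set.seed(seed)
  tab <- data.frame(NDVI = rnorm(n), S = rnorm(n), T = rnorm(n),
                    Ftemp = rnorm(n), C = rnorm(n), P = rnorm(n),
                    D = runif(n, 0, 360), E = rnorm(n))
  tab$target <- 2 * tab$NDVI + 0.5 * tab$S + 0.8 * tab$T +
    0.6 * tab$Ftemp + 0.7 * tab$C + rnorm(n, 0, sigma)
  class(tab) <- c("feature_table", "data.frame")
  tab
}
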