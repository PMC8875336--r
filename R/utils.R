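# internal helpers shared across modules

# deterministic child seeds: fold integer tags into a 31-bit value
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) {
    tv <- if (is.character(t)) sum(utf8ToInt(t) * seq_along(utf8ToInt(t))) else as.double(t)
    h <- (h * 48271 + tv) %% 2147483647
  }
  as.integer(h)
}

# equirectangular projection about an anchor (lon0, lat0), degrees <-> metres
EARTH_RADIUS <- 6371000

planar_to_lonlat <- function(x, y, anchor) {
  lat0 <- anchor[2] * pi / 180
  cbind(lon = anchor[1] + x / (EARTH_RADIUS * cos(lat0)) * 180 / pi,
        lat = anchor[2] + y / EARTH_RADIUS * 180 / pi)
}

lonlat_to_planar <- function(lon, lat, anchor) {
  lat0 <- anchor[2] * pi / 180
  cbind(x = (lon - anchor[1]) * pi / 180 * EARTH_RADIUS * cos(lat0),
        y = (lat - anchor[2]) * pi / 180 * EARTH_RADIUS)
}

# even-odd ray casting; poly is a matrix of vertices (closed or open ring)
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  if (px[1] == px[n] && py[1] == py[n]) { px <- px[-n]; py <- py[-n]; n <- n - 1 }
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- (py[i] > y) != (py[j] > y)
    if (any(cross)) {
      xint <- (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]
      flip <- cross & (x < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

# Sutherland-Hodgman clip of a convex subject polygon to an axis-aligned box
clip_poly_box <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(p, inside_fun, intersect_fun) {
    n <- nrow(p)
    if (n == 0) return(p)
    out <- matrix(numeric(0), ncol = 2)
    prev <- p[n, ]
    prev_in <- inside_fun(prev)
    for (i in seq_len(n)) {
      cur <- p[i, ]; cur_in <- inside_fun(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect_fun(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect_fun(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    out
  }
  ix <- function(p, q, xc) { t <- (xc - p[1]) / (q[1] - p[1]); c(xc, p[2] + t * (q[2] - p[2])) }
  iy <- function(p, q, yc) { t <- (yc - p[2]) / (q[2] - p[2]); c(p[1] + t * (q[1] - p[1]), yc) }
  p <- poly
  p <- clip_edge(p, function(v) v[1] >= xmin, function(a, b) ix(a, b, xmin))
  p <- clip_edge(p, function(v) v[1] <= xmax, function(a, b) ix(a, b, xmax))
  p <- clip_edge(p, function(v) v[2] >= ymin, function(a, b) iy(a, b, ymin))
  p <- clip_edge(p, function(v) v[2] <= ymax, function(a, b) iy(a, b, ymax))
  p
}

# shoelace area of a polygon given as an open ring
poly_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# von Mises sampler (Best & Fisher 1979 rejection scheme)
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cq <- kappa * (r - f)
      if (cq * (2 - cq) - u[2] > 0 || log(cq / u[2]) + 1 - cq >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}
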