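#' Read collar fixes from CSV or GPX
#'
#' CSV needs columns `animal_id`, `timestamp` (ISO 8601), and either
#' `lon`/`lat` or planar `x`/`y`; GPX track points are read via the xml2
#' package (one animal per file, named after the file). Rows with
#' unparseable time or coordinates are dropped and counted; duplicate
#' timestamps within an animal collapse to the first occurrence. Fixes are
#' split into one trajectory per animal per local day and time-sorted.
#'
#' @param path input file
#' @param dialect `"csv"` or `"gpx"`
#' @param anchor lon/lat anchor used to project lon/lat input to local
#'   planar metres (equirectangular)
#' @return list of `grazint_trajectory` data.frames, with attribute
#'   `"dropped"` (count of discarded rows)
#' @export
read_fixes <- function(path, dialect = c("csv", "gpx"),
                       anchor = c(107.6, 39.0)) {
  dialect <- match.arg(dialect)
  if (dialect == "gpx") {
    if (!requireNamespace("xml2", quietly = TRUE))
      stop("GPX ingestion requires the xml2 package")
    doc <- xml2::read_xml(path)
    pts <- xml2::xml_find_all(doc, "//*[local-name()='trkpt']")
    df <- data.frame(
      animal_id = tools::file_path_sans_ext(basename(path)),
      timestamp = xml2::xml_text(xml2::xml_find_first(pts, "./*[local-name()='time']")),
      lon = as.numeric(xml2::xml_attr(pts, "lon")),
      lat = as.numeric(xml2::xml_attr(pts, "lat")))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    tcol <- intersect(c("timestamp", "time"), names(df))[1]
    if (is.na(tcol)) stop("missing required column: timestamp")
    if (!"animal_id" %in% names(df)) stop("missing required column: animal_id")
    planar <- all(c("x", "y") %in% names(df))
    if (!planar && !all(c("lon", "lat") %in% names(df)))
      stop("missing required columns: lon/lat (or x/y)")
    names(df)[names(df) == tcol] <- "timestamp"
  }
  if (nrow(df) == 0) {
    warning("no fixes in ", path)
    out <- list(); attr(out, "dropped") <- 0L
    return(out)
  }
  tm <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  tm[is.na(tm)] <- alt[is.na(tm)]
  if (all(c("x", "y") %in% names(df))) {
    coord_ok <- is.finite(suppressWarnings(as.numeric(df$x))) &
                is.finite(suppressWarnings(as.numeric(df$y)))
  } else {
    coord_ok <- is.finite(suppressWarnings(as.numeric(df$lon))) &
                is.finite(suppressWarnings(as.numeric(df$lat)))
  }
  keep <- !is.na(tm) & coord_ok
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]; tm <- tm[keep]
  if (nrow(df) == 0) {
    warning("no valid fixes in ", path)
    out <- list(); attr(out, "dropped") <- dropped
    return(out)
  }
  df$time <- tm
  if (!all(c("x", "y") %in% names(df))) {
    xy <- lonlat_to_planar(as.numeric(df$lon), as.numeric(df$lat), anchor)
    df$x <- xy[, "x"]; df$y <- xy[, "y"]
  } else {
    df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
    if (!all(c("lon", "lat") %in% names(df))) {
      ll <- planar_to_lonlat(df$x, df$y, anchor)
      df$lon <- ll[, "lon"]; df$lat <- ll[, "lat"]
    }
  }
  df$.day <- format(df$time, "%Y-%m-%d")
  parts <- split(df, list(df$animal_id, df$.day), drop = TRUE)
  out <- lapply(parts, function(p) {
    p <- p[order(p$time), , drop = FALSE]
    p <- p[!duplicated(p$time), , drop = FALSE]
    p <- p[, c("animal_id", "time", "x", "y", "lon", "lat")]
    rownames(p) <- NULL
    class(p) <- c("grazint_trajectory", "data.frame")
    p
  })
  attr(out, "dropped") <- dropped
  out
}

#' Break a trajectory into consecutive segments
#'
#' Each consecutive fix pair becomes a segment carrying duration, length,
#' midpoint and midpoint time. Lengths are Euclidean when planar `x`/`y`
#' columns are present, haversine on lon/lat otherwise (sphere radius
#' 6371 km). Segments faster than `max_speed` are flagged as GPS glitches
#' and removed (count in attribute `"glitches"`). If the trajectory has a
#' `run` column (from [exclude_zones()]), segments never bridge two runs.
#'
#' @param traj a `grazint_trajectory`
#' @param max_speed speed filter threshold (m/s)
#' @return data.frame of segments (`duration`, `length`, `speed`, `mid_x`,
#'   `mid_y`, `midpoint_time`, `run`)
#' @export
segmentize <- function(traj, max_speed = 3) {
  if (nrow(traj) < 2) {
    warning("trajectory has fewer than 2 fixes; no segments")
    out <- data.frame(duration = numeric(0), length = numeric(0),
                      speed = numeric(0), mid_x = numeric(0), mid_y = numeric(0),
                      midpoint_time = as.POSIXct(character(0), tz = "UTC"),
                      run = integer(0))
    attr(out, "glitches") <- 0L
    return(out)
  }
  n <- nrow(traj)
  i0 <- seq_len(n - 1); i1 <- i0 + 1
  dur <- as.numeric(difftime(traj$time[i1], traj$time[i0], units = "secs"))
  if (any(dur <= 0)) stop("fix times must be strictly increasing")
  planar <- all(c("x", "y") %in% names(traj)) && all(is.finite(traj$x))
  if (planar) {
    len <- sqrt((traj$x[i1] - traj$x[i0])^2 + (traj$y[i1] - traj$y[i0])^2)
    mx <- (traj$x[i0] + traj$x[i1]) / 2
    my <- (traj$y[i0] + traj$y[i1]) / 2
  } else {
    len <- geosphere::distHaversine(cbind(traj$lon[i0], traj$lat[i0]),
                                    cbind(traj$lon[i1], traj$lat[i1]),
                                    r = 6371000)
    mx <- (traj$lon[i0] + traj$lon[i1]) / 2
    my <- (traj$lat[i0] + traj$lat[i1]) / 2
  }
  run <- if ("run" %in% names(traj)) traj$run else rep(1L, n)
  if (planar) {
    x0 <- traj$x[i0]; y0 <- traj$y[i0]; x1 <- traj$x[i1]; y1 <- traj$y[i1]
  } else {
    x0 <- traj$lon[i0]; y0 <- traj$lat[i0]; x1 <- traj$lon[i1]; y1 <- traj$lat[i1]
  }
  seg <- data.frame(duration = dur, length = len, speed = len / dur,
                    x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                    mid_x = mx, mid_y = my,
                    midpoint_time = traj$time[i0] + dur / 2,
                    run = run[i0])
  seg <- seg[run[i0] == run[i1], , drop = FALSE]   # no bridging across gaps
  glitch <- seg$speed > max_speed
  out <- seg[!glitch, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "glitches") <- sum(glitch)
  out
}

#' Gaussian kernel density of track points on an analysis grid
#'
#' Density surface normalised so that its integral over the plane equals
#' the number of fixes (so `sum(values) * cell_size^2` is close to n for
#' fixes away from the grid edge). Contributions beyond `4 * bandwidth` of
#' a fix are truncated to zero.
#'
#' @param fixes a trajectory data.frame (columns `x`, `y`) or a two-column
#'   matrix of planar coordinates
#' @param bandwidth Gaussian kernel bandwidth in metres; defaults to a
#'   Silverman-style rule `sigma * n^(-1/6)` on the fix coordinates
#' @param grid a [grid_spec()] defining the analysis raster
#' @return a `grazint_raster` with `band = "density"` (fixes per m^2);
#'   bandwidth used is in attribute `"bandwidth"`
#' @export
kernel_density <- function(fixes, bandwidth = NULL, grid) {
  xy <- if (is.data.frame(fixes)) cbind(fixes$x, fixes$y) else as.matrix(fixes)
  n <- nrow(xy)
  if (n < 1) stop("at least one fix is required")
  if (is.null(bandwidth)) {
    sigma <- mean(c(stats::sd(xy[, 1]), stats::sd(xy[, 2])))
    if (!is.finite(sigma) || sigma == 0) sigma <- grid$cell_size
    bandwidth <- sigma * n^(-1 / 6)
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  r <- empty_grid_raster(grid, band = "density")
  s <- r$cell_size
  nr <- nrow(r$values); nc <- ncol(r$values)
  cut <- 4 * bandwidth
  coef <- 1 / (2 * pi * bandwidth^2)
  for (i in seq_len(n)) {
    rc <- c(floor((r$origin[2] - xy[i, 2]) / s) + 1,
            floor((xy[i, 1] - r$origin[1]) / s) + 1)
    w <- ceiling(cut / s) + 1
    rows <- max(1, rc[1] - w):min(nr, rc[1] + w)
    cols <- max(1, rc[2] - w):min(nc, rc[2] + w)
    if (!length(rows) || !length(cols)) next
    cx <- r$origin[1] + (cols - 0.5) * s
    cy <- r$origin[2] - (rows - 0.5) * s
    d2 <- outer((cy - xy[i, 2])^2, (cx - xy[i, 1])^2, "+")
    k <- coef * exp(-d2 / (2 * bandwidth^2))
    k[d2 > cut^2] <- 0
    r$values[rows, cols] <- r$values[rows, cols] + k
  }
  attr(r, "bandwidth") <- bandwidth
  r
}

#' Classify a density surface into five grades
#'
#' Grade 5 is "extremely high" density, grade 1 "extremely low". Nonzero
#' cells are partitioned by the chosen scheme; zero-density cells always
#' get grade 1.
#'
#' @param density a density raster
#' @param scheme `"quantile"` (default), `"jenks"` (natural-breaks style
#'   1-D k-means), or `"equal_interval"`
#' @param n_grades number of grades
#' @return an integer-valued `grazint_raster` with `band = "grades"`
#' @export
grade_density <- function(density, scheme = c("quantile", "jenks", "equal_interval"),
                          n_grades = 5) {
  scheme <- match.arg(scheme)
  v <- density$values
  nz <- v[is.finite(v) & v > 0]
  g <- matrix(1L, nrow(v), ncol(v))
  g[!is.finite(v)] <- NA_integer_
  if (length(nz) == 0) {
    warning("all-zero density: every cell gets grade 1")
  } else if (length(unique(nz)) == 1) {
    g[is.finite(v) & v > 0] <- as.integer(n_grades)
  } else {
    breaks <- switch(scheme,
      quantile = stats::quantile(nz, probs = seq(0, 1, length.out = n_grades + 1),
                                 names = FALSE),
      equal_interval = seq(min(nz), max(nz), length.out = n_grades + 1),
      jenks = jenks_breaks(nz, n_grades))
    breaks <- unique(breaks)
    idx <- findInterval(nz, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    # if ties collapsed some breaks, spread the surviving classes over 1..n
    idx <- as.integer(round((idx - 1) / max(1, length(breaks) - 2) * (n_grades - 1))) + 1L
    g[is.finite(v) & v > 0] <- idx
  }
  new_raster(g, density$origin, density$cell_size, band = "grades")
}

# natural-breaks style classing: deterministic 1-D k-means seeded at
# quantiles, Lloyd iterations to convergence; returns class boundaries
jenks_breaks <- function(x, k) {
  ux <- sort(unique(x))
  if (length(ux) <= k) return(c(ux[1] - 1e-12, ux))
  centres <- stats::quantile(ux, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  for (it in 1:100) {
    assign <- apply(abs(outer(ux, centres, "-")), 1, which.min)
    new_c <- vapply(seq_len(k), function(j)
      if (any(assign == j)) mean(ux[assign == j]) else centres[j], numeric(1))
    if (max(abs(new_c - centres)) < 1e-12) break
    centres <- sort(new_c)
  }
  bounds <- vapply(seq_len(k - 1), function(j) {
    hi <- max(ux[assign == j]); lo <- min(ux[assign == j + 1]); (hi + lo) / 2
  }, numeric(1))
  c(min(x), bounds, max(x))
}

#' Identify and classify aggregation zones from graded density
#'
#' Connected components (4-neighbour) of cells at grade `min_grade` or
#' above become candidate clusters. A cluster is classed `rest` when the
#' mean speed of the fixes inside it is below `rest_speed` and their total
#' dwell is at least `min_dwell` seconds; `drinking` when it contains the
#' water point; `grazing` otherwise. Explicit override polygons win over
#' the rules for any cluster whose centroid falls inside one.
#'
#' @param grades graded raster from [grade_density()]
#' @param fixes the fix data.frame used to build the density
#' @param water_point planar coordinates of the water point (or `NULL`)
#' @param overrides optional list of `list(class =, coords = matrix)` polygons
#' @param min_grade minimum grade for cluster membership
#' @param rest_speed mean-speed threshold for rest classification (m/s)
#' @param min_dwell minimum total dwell for rest classification (s)
#' @return a `zone_map`: list with `grades` raster and `clusters` (each a
#'   list with `cells`, `class`, `centroid`, `n_fixes`, `mean_speed`,
#'   `dwell`), plus the overrides
#' @export
classify_zones <- function(grades, fixes, water_point = NULL, overrides = NULL,
                           min_grade = 4, rest_speed = 0.05, min_dwell = 1800) {
  g <- grades$values
  cand <- which(is.finite(g) & g >= min_grade, arr.ind = TRUE)
  labels <- label_components(g >= min_grade & is.finite(g))
  xy <- cbind(fixes$x, fixes$y)
  n <- nrow(xy)
  dt <- if (n > 1) as.numeric(difftime(fixes$time[-1], fixes$time[-n], units = "secs")) else numeric(0)
  step <- if (n > 1) sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2) else numeric(0)
  fix_speed <- if (n > 1) c(step / dt, step[n - 1] / dt[n - 1]) else 0
  fix_dt <- if (n > 1) c(dt, dt[n - 1]) else 0
  rc <- cell_of(grades, xy[, 1], xy[, 2])
  fix_label <- rep(NA_integer_, n)
  ok <- !is.na(rc[, 1])
  fix_label[ok] <- labels[cbind(rc[ok, 1], rc[ok, 2])]
  clusters <- list()
  for (lab in setdiff(unique(as.vector(labels)), 0)) {
    cells <- which(labels == lab, arr.ind = TRUE)
    inside <- which(!is.na(fix_label) & fix_label == lab)
    ctr <- colMeans(cell_center(grades, cells[, 1], cells[, 2]))
    ms <- if (length(inside)) mean(fix_speed[inside]) else Inf
    dwell <- sum(fix_dt[inside])
    cls <- "grazing"
    if (!is.null(water_point)) {
      wrc <- cell_of(grades, water_point[1], water_point[2])
      if (!is.na(wrc[1, 1]) && labels[wrc[1, 1], wrc[1, 2]] == lab) cls <- "drinking"
    }
    if (cls == "grazing" && ms < rest_speed && dwell >= min_dwell) cls <- "rest"
    if (!is.null(overrides)) {
      for (ov in overrides) {
        if (point_in_polygon(ctr[1], ctr[2], ov$coords)) { cls <- ov$class; break }
      }
    }
    clusters[[length(clusters) + 1]] <-
      list(cells = cells, class = cls, centroid = ctr,
           n_fixes = length(inside), mean_speed = ms, dwell = dwell)
  }
  structure(list(grades = grades, clusters = clusters, overrides = overrides),
            class = "zone_map")
}

# 4-connected component labelling of a logical matrix
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- ((cur - 1) %% nr) + 1; j <- ((cur - 1) %/% nr) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          lin <- (jj - 1) * nr + ii
          if (mask[lin] && labels[lin] == 0L) {
            labels[lin] <- nxt
            queue <- c(queue, lin)
          }
        }
      }
    }
  }
  labels
}

#' Remove fixes that fall in rest or drinking zones
#'
#' Fixes whose containing cell belongs to a rest or drinking cluster (or
#' that lie inside a rest/drinking override polygon) are removed. Each
#' contiguous run of surviving fixes gets a distinct `run` id, so
#' [segmentize()] never creates a segment bridging an excluded gap. The
#' operation is idempotent.
#'
#' @param traj a `grazint_trajectory`
#' @param zones a `zone_map` from [classify_zones()]
#' @return the filtered trajectory with a `run` column; removed fix count
#'   in attribute `"removed"`
#' @export
exclude_zones <- function(traj, zones) {
  stopifnot(inherits(zones, "zone_map"))
  n <- nrow(traj)
  drop <- rep(FALSE, n)
  rc <- cell_of(zones$grades, traj$x, traj$y)
  for (cl in zones$clusters) {
    if (!cl$class %in% c("rest", "drinking")) next
    cellset <- paste(cl$cells[, 1], cl$cells[, 2])
    drop <- drop | (!is.na(rc[, 1]) & paste(rc[, 1], rc[, 2]) %in% cellset)
  }
  if (!is.null(zones$overrides)) {
    for (ov in zones$overrides) {
      if (ov$class %in% c("rest", "drinking"))
        drop <- drop | point_in_polygon(traj$x, traj$y, ov$coords)
    }
  }
  keep <- which(!drop)
  base_run <- if ("run" %in% names(traj)) traj$run else rep(1L, n)
  out <- traj[keep, , drop = FALSE]
  if (nrow(out)) {
    gap <- c(FALSE, diff(keep) > 1 | diff(base_run[keep]) != 0)
    out$run <- cumsum(gap) + 1L
  } else {
    out$run <- integer(0)
  }
  rownames(out) <- NULL
  class(out) <- c("grazint_trajectory", "data.frame")
  attr(out, "removed") <- sum(drop)
  out
}
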