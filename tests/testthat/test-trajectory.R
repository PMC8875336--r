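test_that("CSV ingestion drops malformed rows and splits animals and days", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,timestamp,lon,lat",
               "a,2020-08-01T06:00:00,107.601,39.001",
               "b,2020-08-01T06:00:00,107.602,39.002",
               "a,2020-08-01T06:02:00,107.6015,39.0012",
               "a,not-a-time,107.6,39.0",
               "b,2020-08-01T06:02:00,107.6025,39.0022",
               "a,2020-08-01T06:04:00,107.6018,39.0014",
               "a,2020-08-02T06:00:00,107.601,39.001"),
             path)
  trs <- read_fixes(path)
  expect_equal(attr(trs, "dropped"), 1L)
  expect_length(trs, 3)  # a x 2 days, b x 1 day
  n_by <- vapply(trs, nrow, 0L)
  expect_setequal(n_by, c(3L, 2L, 1L))
  for (tr in trs) expect_true(all(diff(as.numeric(tr$time)) > 0))
})

test_that("empty files and duplicate timestamps are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("animal_id,timestamp,lon,lat", path)
  expect_warning(trs <- read_fixes(path), "no fixes")
  expect_length(trs, 0)
  writeLines(c("animal_id,timestamp,x,y",
               "a,2020-08-01T06:00:00,10,10",
               "a,2020-08-01T06:00:00,99,99",
               "a,2020-08-01T06:02:00,20,20"), path)
  trs <- read_fixes(path)
  expect_equal(nrow(trs[[1]]), 2)
  expect_equal(trs[[1]]$x[1], 10)  # first occurrence wins
  writeLines(c("animal_id,lon,lat", "a,107.6,39"), path)
  expect_error(read_fixes(path), "timestamp")
})

test_that("GPX track points are ingested as a trajectory", {
  path <- withr::local_tempfile(fileext = ".gpx")
  writeLines(c('<?xml version="1.0"?>',
               '<gpx xmlns="http://www.topografix.com/GPX/1/1"><trk><trkseg>',
               '<trkpt lat="39.001" lon="107.601"><time>2020-08-01T06:00:00</time></trkpt>',
               '<trkpt lat="39.0012" lon="107.6012"><time>2020-08-01T06:02:00</time></trkpt>',
               '</trkseg></trk></gpx>'), path)
  trs <- read_fixes(path, dialect = "gpx")
  expect_length(trs, 1)
  expect_equal(nrow(trs[[1]]), 2)
  expect_true(all(is.finite(trs[[1]]$x)))
})

test_that("segmentation: counts, telescoping duration, zero-length segments", {
  tr <- random_walk_trajectory(361, seed = 1)
  segs <- segmentize(tr)
  expect_equal(nrow(segs), 360)
  expect_equal(sum(segs$duration), 43200)
  tr2 <- tr[1:3, ]; tr2$x <- 50; tr2$y <- 50
  segs2 <- segmentize(tr2)
  expect_equal(segs2$length, c(0, 0))
  expect_warning(out <- segmentize(tr[1, , drop = FALSE]), "fewer than 2")
  expect_equal(nrow(out), 0)
})

test_that("haversine length of a 1-degree latitude hop, then speed-filtered", {
  tr <- data.frame(animal_id = "a",
                   time = as.POSIXct("2020-08-01 06:00:00", tz = "UTC") + c(0, 120),
                   lon = c(107.6, 107.6), lat = c(39, 40))
  class(tr) <- c("grazint_trajectory", "data.frame")
  segs_all <- segmentize(tr, max_speed = Inf)
  expect_equal(segs_all$length, 2 * pi * 6371000 / 360, tolerance = 1e-6)
  segs <- segmentize(tr)          # 926 m/s is a GPS glitch
  expect_equal(nrow(segs), 0)
  expect_equal(attr(segs, "glitches"), 1L)
})

test_that("kernel density matches the brute-force oracle to 1e-9", {
  grid <- grid_spec(extent = c(400, 400), cell_size = 10)  # 40 x 40 cells
  set.seed(21)
  xy <- cbind(runif(200, 60, 340), runif(200, 60, 340))
  for (bw in c(8, 20)) {
    fast <- kernel_density(xy, bandwidth = bw, grid = grid)
    slow <- kde_oracle(xy, bw, grid)
    expect_lt(max(abs(fast$values - slow$values)), 1e-9)
  }
})

test_that("kernel density integrates to the fix count and peaks at the fixes", {
  grid <- grid_spec(extent = c(390, 390), cell_size = 13)
  set.seed(2)
  xy <- cbind(runif(100, 100, 290), runif(100, 100, 290))
  d <- kernel_density(xy, bandwidth = 12, grid = grid)
  expect_equal(sum(d$values) * 169, 100, tolerance = 0.01)
  one <- kernel_density(matrix(c(200, 200), 1), bandwidth = 10, grid = grid)
  peak <- which(one$values == max(one$values), arr.ind = TRUE)
  expect_equal(unname(cell_center(one, peak[1], peak[2])[1, ]), c(201.5, 201.5))
  # two separated clusters give two local maxima
  two <- kernel_density(rbind(cbind(rnorm(40, 100, 5), rnorm(40, 100, 5)),
                              cbind(rnorm(40, 300, 5), rnorm(40, 300, 5))),
                        bandwidth = 10, grid = grid)
  expect_gt(two$values[cell_of(two, 100, 100)], 10 * two$values[cell_of(two, 200, 200)])
  expect_gt(two$values[cell_of(two, 300, 300)], 10 * two$values[cell_of(two, 200, 200)])
  expect_error(kernel_density(xy, bandwidth = -1, grid = grid), "positive")
})

test_that("density grading: five labels, monotone, quantile balance, degenerate cases", {
  set.seed(31)
  vals <- matrix(c(rep(0, 20), runif(80, 0.1, 9)), 10, 10)
  d <- new_raster(vals, c(0, 100), 10, "density")
  g <- grade_density(d)
  expect_setequal(unique(as.vector(g$values)), 1:5)
  expect_true(all(g$values[vals == 0] == 1))
  # monotone: sort cells by density, grades must be non-decreasing
  ord <- order(vals)
  expect_true(all(diff(g$values[ord]) >= 0))
  # quantile classes on distinct values are near-equal (order-statistics oracle)
  nz <- table(g$values[vals > 0])
  expect_lte(max(nz) - min(nz), 1)
  cst <- new_raster(matrix(2, 4, 4), c(0, 4), 1, "density")
  gc <- grade_density(cst)
  expect_equal(length(unique(as.vector(gc$values))), 1)
  expect_warning(gz <- grade_density(new_raster(matrix(0, 3, 3), c(0, 3), 1, "density")),
                 "all-zero")
  expect_true(all(gz$values == 1))
  for (sch in c("jenks", "equal_interval")) {
    gs <- grade_density(d, scheme = sch)
    expect_true(all(diff(gs$values[ord]) >= 0))
    expect_true(all(gs$values[vals > 0] >= 1 & gs$values[vals > 0] <= 5))
  }
})

test_that("zone classification recovers planted rest and drinking clusters", {
  cfg <- tiny_config(seed = 8)
  sim <- simulate_trajectory(cfg, 50, 1)
  tr <- sim$trajectory
  grid <- grid_spec(extent = cfg$area_extent)
  g <- grade_density(kernel_density(tr, bandwidth = 20, grid = grid),
                     scheme = "jenks")
  zones <- classify_zones(g, tr, water_point = cfg$water_location)
  classes <- vapply(zones$clusters, `[[`, "", "class")
  expect_true("drinking" %in% classes)
  expect_true("rest" %in% classes)
  drink <- zones$clusters[[which(classes == "drinking")[1]]]
  expect_lt(sqrt(sum((drink$centroid - cfg$water_location)^2)), 40)
  # the planted rest polygon is recovered with >= 80% area overlap
  rest_poly <- sim$ground_truth$zone_polygons[[2]]$coords
  rests <- zones$clusters[classes == "rest"]
  overlap <- 0
  for (cl in rests) {
    for (k in seq_len(nrow(cl$cells))) {
      ctr <- cell_center(g, cl$cells[k, 1], cl$cells[k, 2])
      s <- g$cell_size
      overlap <- overlap + grazint:::poly_area(grazint:::clip_poly_box(
        rest_poly, ctr[1] - s / 2, ctr[1] + s / 2, ctr[2] - s / 2, ctr[2] + s / 2))
    }
  }
  expect_gte(overlap / grazint:::poly_area(rest_poly), 0.80)
})

test_that("override polygons win over rule-based classing", {
  cfg <- tiny_config(seed = 8)
  tr <- simulate_trajectory(cfg, 50, 1)$trajectory
  grid <- grid_spec(extent = cfg$area_extent)
  g <- grade_density(kernel_density(tr, bandwidth = 20, grid = grid),
                     scheme = "jenks")
  zones <- classify_zones(g, tr, water_point = cfg$water_location)
  classes <- vapply(zones$clusters, `[[`, "", "class")
  rest_idx <- which(classes == "rest")[1]
  ctr <- zones$clusters[[rest_idx]]$centroid
  ov <- list(list(class = "grazing",
                  coords = cbind(ctr[1] + c(-40, 40, 40, -40),
                                 ctr[2] + c(-40, -40, 40, 40))))
  zones2 <- classify_zones(g, tr, water_point = cfg$water_location, overrides = ov)
  expect_identical(zones2$clusters[[rest_idx]]$class, "grazing")
})

test_that("zone exclusion removes dwell fixes, splits runs, and is idempotent", {
  cfg <- tiny_config(seed = 8)
  tr <- simulate_trajectory(cfg, 50, 1)$trajectory
  grid <- grid_spec(extent = cfg$area_extent)
  g <- grade_density(kernel_density(tr, bandwidth = 20, grid = grid),
                     scheme = "jenks")
  zones <- classify_zones(g, tr, water_point = cfg$water_location)
  ex <- exclude_zones(tr, zones)
  expect_gt(attr(ex, "removed"), 0)
  expect_lt(nrow(ex), nrow(tr))
  expect_gt(max(ex$run), 1)
  ex2 <- exclude_zones(ex, zones)
  expect_equal(attr(ex2, "removed"), 0)
  expect_identical(ex2$run, ex$run)
  expect_identical(ex2$x, ex$x)
  # segments never bridge an excluded gap
  segs <- segmentize(ex)
  expect_lt(nrow(segs), nrow(ex) - 1)
  expect_true(all(segs$duration == cfg$fix_interval))
})

test_that("exclusion with no overlapping zones is the identity on positions", {
  tr <- random_walk_trajectory(50, seed = 2)
  g <- new_raster(matrix(1L, 10, 10), c(0, 400), 40, "grades")
  zones <- classify_zones(g, tr, water_point = NULL)
  ex <- exclude_zones(tr, zones)
  expect_equal(attr(ex, "removed"), 0)
  expect_equal(ex$x, tr$x)
  # all fixes inside a rest override polygon -> empty trajectory
  ov <- list(list(class = "rest",
                  coords = cbind(c(-1, 401, 401, -1), c(-1, -1, 401, 401))))
  zones_all <- classify_zones(g, tr, water_point = NULL, overrides = ov)
  # no grade >= 4 clusters exist, so removal comes from the override polygon
  ex_all <- exclude_zones(tr, zones_all)
  expect_equal(attr(ex_all, "removed"), nrow(tr))
  expect_equal(nrow(ex_all), 0)
})
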