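test_that("daily intake: fresh and derived modes match hand values", {
  expect_equal(daily_intake(50), 3800)
  expect_equal(daily_intake(50, mode = "derived"), 0.03 / 0.39 * 50 * 1000,
               tolerance = 1e-9)
  expect_equal(daily_intake(50, mode = "derived"), 3846.15, tolerance = 1e-5)
  expect_error(daily_intake(-1), "positive")
  expect_error(intake_model(fresh_intake_fraction = 0), "strictly in")
  # inconsistent constants are rejected in derived mode
  bad <- intake_model(dry_matter_fraction_of_weight = 0.04,
                      dry_to_fresh_ratio = 0.39)
  expect_error(daily_intake(50, bad, mode = "derived"), "5%")
})

test_that("average grazing rate: literal and feeding-corrected", {
  expect_equal(average_grazing_rate(3600, 3600, mode = "literal"), 1)
  expect_equal(average_grazing_rate(0, 3600, mode = "literal"), 0)
  expect_equal(average_grazing_rate(3800, 43200, a = 0.86), 3800 / (43200 * 0.86))
  expect_equal(average_grazing_rate(3800, 43200, a = 0.86), 0.10229, tolerance = 1e-4)
  expect_error(average_grazing_rate(100, 0), "positive")
})

test_that("segment intake telescopes over the day", {
  expect_equal(segment_intake(43200, rate = 3800 / 43200), 3800)
  expect_equal(segment_intake(0, rate = 1), 0)
  expect_equal(segment_intake(120, rate = 3800 / 43200), 10.5556, tolerance = 1e-4)
  # corrected rate with the feeding fraction telescopes back to IZ
  r <- average_grazing_rate(3800, 43200, a = 0.86, mode = "corrected")
  expect_equal(sum(segment_intake(rep(120, 360), r, feeding_fraction = 0.86)), 3800)
  expect_error(segment_intake(10, rate = -1), "non-negative")
})

test_that("buffer cells: containment, symmetric split, zero-length square", {
  g <- grid_spec(extent = c(130, 130))
  one <- buffer_cells(c(3, 6.5, 9, 6.5), g)
  expect_equal(nrow(one), 1)
  expect_equal(one$weight, 1)
  two <- buffer_cells(c(9, 6.5, 17, 6.5), g)
  expect_equal(sort(two$weight), c(0.5, 0.5))
  expect_equal(sum(two$weight), 1, tolerance = 1e-9)
  pt <- buffer_cells(c(6.5, 6.5, 6.5, 6.5), g)
  expect_equal(pt$weight, 1)
  corner <- buffer_cells(c(13, 13, 13, 13), g)  # point on a 4-cell corner
  expect_equal(sort(corner$weight), rep(0.25, 4))
})

test_that("buffer weights agree with the Monte-Carlo area oracle within 0.01", {
  g <- grid_spec(extent = c(130, 130))
  cases <- list(c(21.3, 34.2, 55.9, 61.7),
                c(40, 40, 41, 95),
                c(80.1, 22.2, 64.3, 30.9))
  for (p in cases) {
    bc <- buffer_cells(p, g)
    expect_equal(sum(bc$weight), 1, tolerance = 1e-9)
    mc <- buffer_mc_oracle(p, g)
    key <- paste(bc$row, bc$col)
    mcw <- rep(0, nrow(bc)); names(mcw) <- key
    mcw[intersect(key, names(mc))] <- mc[intersect(key, names(mc))]
    expect_lt(max(abs(bc$weight - mcw)), 0.01)
  }
})

test_that("literal allocation collapses to the closed form", {
  g <- grid_spec(extent = c(130, 130))
  seg1 <- data.frame(duration = 600, length = 1, speed = 1 / 600,
                     x0 = 5, y0 = 5, x1 = 6, y1 = 5, mid_x = 5.5, mid_y = 5,
                     midpoint_time = as.POSIXct("2020-08-01 10:00:00", tz = "UTC"),
                     run = 1L)
  ig <- allocate_intensity(seg1, iz = 1000, tz = 600, g, mode = "literal_eq5")
  expect_equal(max(ig$values$values), 1000 / 169)  # F = IZ / S exactly
  expect_equal(sum(ig$contributing_points$values), 1)
  two <- rbind(seg1, seg1)
  two$x0[2] <- 20; two$x1[2] <- 21; two$mid_x[2] <- 20.5
  ig2 <- allocate_intensity(two, iz = 1000, tz = 1200, g, mode = "literal_eq5")
  expect_equal(sort(unique(ig2$values$values[ig2$values$values > 0])),
               1000 / (4 * 169))
  expect_error(allocate_intensity(seg1[0, ], 1000, 600, g), "empty")
})

test_that("conservative allocation conserves the allocated mass exactly", {
  g <- grid_spec(extent = c(400, 400))
  tr <- random_walk_trajectory(60, seed = 7)
  segs <- segmentize(tr)
  iz <- daily_intake(50); tz <- sum(segs$duration)
  ig <- allocate_intensity(segs, iz, tz, g)
  rate <- average_grazing_rate(iz, tz, a = 0.86)
  expect_equal(ig$allocated_g, sum(segment_intake(segs, rate, 0.86)),
               tolerance = 1e-9)
  expect_equal(ig$allocated_g, iz, tolerance = 1e-6)  # telescoping
  expect_true(all(ig$values$values >= 0))
  expect_equal(sum(ig$contributing_points$values), nrow(segs))
})

test_that("allocation is monotone in segments and equivariant in intake", {
  g <- grid_spec(extent = c(400, 400))
  segs <- segmentize(random_walk_trajectory(30, seed = 3))
  ig_all <- allocate_intensity(segs, 1000, sum(segs$duration), g)
  ig_head <- allocate_intensity(segs[1:20, ], 1000, sum(segs$duration), g)
  expect_true(all(ig_all$values$values - ig_head$values$values >= -1e-12))
  for (mode in c("conservative", "literal_eq5")) {
    a <- allocate_intensity(segs, 1000, sum(segs$duration), g, mode = mode)
    b <- allocate_intensity(segs, 2000, sum(segs$duration), g, mode = mode)
    expect_equal(b$values$values, 2 * a$values$values)
  }
})

test_that("literal and conservative modes agree in the single-cell limit", {
  g <- grid_spec(extent = c(130, 130))
  # a stationary segment: everything lands in one cell in both modes
  seg <- data.frame(duration = 600, length = 0, speed = 0,
                    x0 = 6.5, y0 = 6.5, x1 = 6.5, y1 = 6.5,
                    mid_x = 6.5, mid_y = 6.5,
                    midpoint_time = as.POSIXct("2020-08-01 10:00:00", tz = "UTC"),
                    run = 1L)
  lit <- allocate_intensity(seg, 500, 600, g, mode = "literal_eq5")
  con <- allocate_intensity(seg, 500, 600, g, mode = "conservative",
                            feeding_correction = FALSE)
  expect_equal(max(lit$values$values), 500 / 169)
  expect_equal(max(con$values$values), 500 / 169)
  expect_equal(lit$values$values, con$values$values)
})

test_that("superposition sums cells and totals and is order-independent", {
  g <- grid_spec(extent = c(400, 400))
  mk <- function(seed) {
    segs <- segmentize(random_walk_trajectory(25, seed = seed))
    allocate_intensity(segs, 1000, sum(segs$duration), g)
  }
  gs <- lapply(1:3, mk)
  zero <- gs[[1]]
  zero$values$values[] <- 0; zero$contributing_points$values[] <- 0
  zero$total_intake <- 0; zero$total_time <- 0; zero$allocated_g <- 0
  expect_equal(superpose(list(gs[[1]], zero))$values$values, gs[[1]]$values$values)
  dbl <- superpose(list(gs[[1]], gs[[1]]))
  expect_equal(dbl$values$values, 2 * gs[[1]]$values$values)
  expect_equal(dbl$total_intake, 2 * gs[[1]]$total_intake)
  ref <- superpose(gs)
  for (perm in list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1), c(3, 1, 2))) {
    alt <- superpose(gs[perm])
    expect_equal(alt$values$values, ref$values$values)
    expect_equal(alt$contributing_points$values, ref$contributing_points$values)
  }
  g2 <- grid_spec(extent = c(390, 390))
  segs <- segmentize(random_walk_trajectory(25, seed = 9))
  expect_error(superpose(list(gs[[1]],
                              allocate_intensity(segs, 1, sum(segs$duration), g2))),
               "same grid")
})
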