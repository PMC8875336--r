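test_that("a 06:00-18:00 day at 120 s yields 361 fixes starting and ending at the pen", {
  cfg <- tiny_config()
  sim <- simulate_trajectory(cfg, 50, 1)
  tr <- sim$trajectory
  expect_equal(nrow(tr), 361)  # 12 h / 120 s + 1
  expect_true(all(diff(as.numeric(tr$time)) == cfg$fix_interval))
  d_first <- sqrt(sum((c(tr$x[1], tr$y[1]) - cfg$pen_location)^2))
  d_last <- sqrt(sum((c(tr$x[361], tr$y[361]) - cfg$pen_location)^2))
  expect_lt(d_first, 20)
  expect_lt(d_last, 20)
})

test_that("trajectory simulation is deterministic for a fixed seed", {
  cfg <- tiny_config(seed = 11)
  a <- simulate_trajectory(cfg, 47.3, 2)
  b <- simulate_trajectory(cfg, 47.3, 2)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$ground_truth$per_segment_intake,
                   b$ground_truth$per_segment_intake)
  expect_error(simulate_trajectory(cfg, -5, 1), "positive")
})

test_that("trajectory dwells at pen, water and rest sites", {
  cfg <- tiny_config()
  tr <- simulate_trajectory(cfg, 55, 1)$trajectory
  near <- function(site, tol = 10)
    sum(sqrt((tr$x - site[1])^2 + (tr$y - site[2])^2) < tol)
  expect_gte(near(cfg$pen_location), 2)
  expect_gte(near(cfg$water_location), cfg$drink_dwell / cfg$fix_interval - 1)
  expect_gte(near(cfg$rest_location), cfg$rest_dwell / cfg$fix_interval - 1)
})

test_that("ground truth conserves the daily intake and the planted field", {
  cfg <- tiny_config(seed = 5)
  sim <- simulate_trajectory(cfg, 62, 3)
  gt <- sim$ground_truth
  expect_equal(sum(gt$per_segment_intake), gt$daily_intake_g, tolerance = 1e-9)
  field_total <- sum(gt$intensity_field$values) * gt$intensity_field$cell_size^2
  expect_lt(abs(field_total - gt$daily_intake_g) / gt$daily_intake_g, 0.01)
  expect_true(all(gt$intensity_field$values >= 0))
})

test_that("fixes inside the planted rest polygon are nearly stationary", {
  cfg <- tiny_config(seed = 8)
  sim <- simulate_trajectory(cfg, 50, 1)
  tr <- sim$trajectory
  rest <- sim$ground_truth$zone_polygons[[2]]
  expect_identical(rest$name, "rest_site")
  inside <- grazint:::point_in_polygon(tr$x, tr$y, rest$coords)
  n <- nrow(tr)
  step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  speed <- c(step, step[n - 1]) / cfg$fix_interval
  expect_gte(mean(speed[inside] < 0.05), 0.95)
})

test_that("flock weights hit the exact class counts and intervals", {
  cfg <- tiny_config()
  w <- simulate_flock_weights(cfg)
  expect_length(w, 200)
  expect_identical(attr(w, "class_counts"), c(30L, 140L, 30L))
  expect_equal(sum(w >= 40 & w <= 60), 140)
  expect_true(all(w >= 30 & w <= 75))
  w1 <- simulate_flock_weights(sim_config(flock_size = 1))
  expect_length(w1, 1)
  expect_error(sim_config(weight_class_proportions = c(0.2, 0.2, 0.2)), "sum to 1")
})

test_that("largest-remainder counts sum to the flock size on a proportion grid", {
  props <- expand.grid(a = seq(0.05, 0.9, by = 0.05), b = seq(0.05, 0.9, by = 0.05))
  props$c <- 1 - props$a - props$b
  props <- props[props$c >= 0.05 - 1e-12, ]
  for (n in c(1, 7, 23, 50)) {
    for (k in seq_len(nrow(props))) {
      cnt <- grazint:::largest_remainder(n, unlist(props[k, ]))
      expect_identical(sum(cnt), as.integer(n))
      expect_true(all(cnt >= 0))
    }
  }
})

test_that("terrain generator: cell size, determinism, constant at zero amplitude", {
  cfg <- tiny_config(seed = 2)
  dem <- generate_terrain(cfg)
  expect_equal(dem$cell_size, 30)
  expect_identical(dem$values, generate_terrain(cfg)$values)
  flat <- generate_terrain(cfg, amplitude = 0)
  expect_equal(max(flat$values) - min(flat$values), 0)
})

test_that("band generator puts patch-centre NDVI in [0.58, 0.90] and stays in (0, 1]", {
  cfg <- tiny_config(seed = 6)
  dem <- generate_terrain(cfg)
  bands <- generate_bands(cfg, dem)
  expect_true(all(bands$nir$values > 0 & bands$nir$values <= 1))
  expect_true(all(bands$red$values > 0 & bands$red$values <= 1))
  ndvi <- compute_ndvi(bands$nir, bands$red)
  expect_true(all(ndvi$values >= 0 & ndvi$values <= 1))
  patches <- attr(bands, "patches")
  at_centres <- sample_raster(ndvi, patches)
  expect_true(all(at_centres >= 0.575 & at_centres <= 0.905))
  expect_identical(generate_bands(cfg, dem)$nir$values, bands$nir$values)
  # identical bands give identically zero NDVI
  same <- compute_ndvi(bands$nir, bands$nir)
  expect_true(all(same$values == 0))
})

test_that("temperature series: exact sinusoid at zero noise, seasonal offset, length", {
  s0 <- generate_temperature(1, "summer", noise_sd = 0)
  expect_equal(nrow(s0), 361)
  expect_equal(s0$hour[which.max(s0$temp_c)], 14)
  a0 <- generate_temperature(1, "autumn", noise_sd = 0)
  expect_equal(mean(s0$temp_c) - mean(a0$temp_c), 14, tolerance = 0.2)
  s1 <- generate_temperature(2, "summer", seed = 3)
  expect_identical(s1, generate_temperature(2, "summer", seed = 3))
})
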