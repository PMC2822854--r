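test_that("raster sampling uses the containing cell with the
          smaller-index boundary convention", {
  m <- matrix(as.numeric(1:12), nrow = 3, ncol = 4)  # south-up storage
  g <- raster_grid(m, xll = 10, yll = 20, dx = 1)
  # cell centres
  expect_equal(sample_raster_at(g, cbind(10.5, 20.5)), m[1, 1])
  expect_equal(sample_raster_at(g, cbind(13.5, 22.5)), m[3, 4])
  # a point on an interior cell boundary belongs to the smaller index
  expect_equal(sample_raster_at(g, cbind(11, 20.5)), m[1, 1])
  expect_equal(sample_raster_at(g, cbind(10.5, 21)), m[1, 1])
  # grid edges are inside
  expect_equal(sample_raster_at(g, cbind(10, 20)), m[1, 1])
  expect_equal(sample_raster_at(g, cbind(14, 23)), m[3, 4])
  # outside the extent: error naming the point, or NA on request
  expect_error(sample_raster_at(g, cbind(9.9, 20.5)), "9.9")
  expect_true(is.na(sample_raster_at(g, cbind(9.9, 20.5), outside = "na")))
})

test_that("track rotation is an isometry about the origin", {
  set.seed(5)
  trk <- simulate_two_state_track(sim_config(duration_s = 1800), seed = 5)
  org <- c(trk$fixes$lon[1], trk$fixes$lat[1])

  # full turn is the identity
  r360 <- rotate_track(trk, 360, origin = org)
  expect_equal(r360$fixes$lon, trk$fixes$lon, tolerance = 1e-6)
  expect_equal(r360$fixes$lat, trk$fixes$lat, tolerance = 1e-6)

  # a point due north of the origin rotates 90 degrees to due east
  north <- make_track(c(0, 10), c(175, 175), c(-36, -35.5))
  east <- rotate_track(north, 90)
  b <- initial_bearing(c(175, -36),
                       c(east$fixes$lon[2], east$fixes$lat[2]))
  expect_equal(b, 90, tolerance = 1e-6)

  # distance to origin and inter-fix distances preserved; times untouched
  r <- rotate_track(trk, 137.5, origin = org)
  om <- matrix(org, n_fixes(trk), 2, byrow = TRUE)
  d0 <- great_circle_distance(om, cbind(trk$fixes$lon, trk$fixes$lat))
  d1 <- great_circle_distance(om, cbind(r$fixes$lon, r$fixes$lat))
  expect_equal(d1, d0, tolerance = 1e-6)
  p <- cbind(trk$fixes$lon, trk$fixes$lat)
  q <- cbind(r$fixes$lon, r$fixes$lat)
  seg0 <- great_circle_distance(p[-nrow(p), ], p[-1, ])
  seg1 <- great_circle_distance(q[-nrow(q), ], q[-1, ])
  expect_equal(seg1, seg0, tolerance = 1e-6)
  expect_identical(r$fixes$time, trk$fixes$time)
})

test_that("the rotation null pools fifteen 22.5-degree replicates,
          excludes land, and carries behaviour labels", {
  ocean <- make_flat_ocean(-800)
  trk <- make_track(seq(0, 40, 10), 175 + (0:4) * 0.02, rep(-36, 5),
                    state = c("SLOW", "SLOW", "FAST", "FAST", "FAST"))
  nullp <- build_rotation_null(trk, ocean)
  expect_equal(sort(unique(nullp$angle)), (1:15) * 22.5)
  # uniform ocean: every null depth equals the observed depth
  expect_true(all(nullp$depth == 800))
  expect_true(all(nullp$source == "ROTATED"))
  # labels carried over from the unrotated fixes, per angle
  expect_equal(sum(nullp$label == "SLOW"), 2 * 15)

  # a land half-plane removes the sectors rotated over it
  m <- matrix(-800, 80, 80)
  m[, 1:40] <- 50   # western half is land
  land_west <- raster_grid(m, xll = 173, yll = -38, dx = 0.05)
  null_land <- build_rotation_null(trk, land_west)
  expect_lt(nrow(null_land), nrow(nullp))
  expect_gt(attr(null_land, "n_land_dropped"), 0)
  expect_true(all(null_land$depth > 0))

  # rotated fixes leaving a tight extent are dropped and counted
  tight <- raster_grid(matrix(-800, 20, 4), xll = 174.99, yll = -36.5,
                       dx = 0.05)
  null_tight <- build_rotation_null(trk, tight)
  expect_gt(attr(null_tight, "n_outside_dropped"), 0)
})

test_that("two-sample KS agrees with brute force and stats::ks.test", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  expect_equal(ks_two_sample(c(1, 3, 5), c(2, 4, 6))$D, 1 / 3,
               tolerance = 1e-12)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")

  # oracle sweep over every pooled breakpoint, including tied samples
  brute_D <- function(a, b) {
    max(vapply(c(a, b), function(x) abs(mean(a <= x) - mean(b <= x)),
               numeric(1)))
  }
  set.seed(71)
  for (i in 1:300) {
    n1 <- sample(1:20, 1); n2 <- sample(1:20, 1)
    a <- sample(1:12, n1, replace = TRUE)      # heavy ties
    b <- rnorm(n2, 6, 4)
    k <- ks_two_sample(a, b)
    expect_identical(k$D, brute_D(a, b))
  }

  # asymptotic p matches stats::ks.test on tie-free samples (ks.test
  # evaluates the Kolmogorov CDF to about 1e-6 internally)
  for (i in 1:25) {
    a <- rnorm(40 + i); b <- rnorm(60, 0.3)
    k <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(k$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(k$p, ref$p.value, tolerance = 1e-4)
  }
})

test_that("repeated subsample testing is seeded, calibrated and powerful", {
  set.seed(91)
  pool <- rnorm(4000, 1000, 150)

  # determinism under a fixed seed
  obs <- sample(pool, 120)
  r1 <- repeated_subsample_test(obs, pool, n_runs = 50, seed = 7)
  r2 <- repeated_subsample_test(obs, pool, n_runs = 50, seed = 7)
  expect_identical(r1$runs, r2$runs)
  expect_equal(r1$n_obs, 120)

  # a sample from the pool itself is rarely declared different
  expect_lt(r1$prop_significant, 0.5)
  expect_false(r1$significant)

  # a 10-sd shift separates every run
  r3 <- repeated_subsample_test(obs + 1500, pool, n_runs = 50, seed = 7)
  expect_equal(r3$prop_significant, 1.0)
  expect_true(r3$significant)
  expect_equal(median(r3$runs$D), 1)

  expect_error(repeated_subsample_test(rnorm(100), rnorm(50)), "pool")
})

test_that("depth-band occupancy counts inclusively and splits by label", {
  expect_equal(depth_band_occupancy(rep(800, 7)), 1)
  expect_equal(depth_band_occupancy(c(100, 800, 3000, 800)), 0.5)
  # both edges inclusive
  expect_equal(depth_band_occupancy(c(600, 1000, 599.999, 1000.001)), 0.5)
  expect_warning(o <- depth_band_occupancy(numeric(0)), "undefined")
  expect_true(is.na(o))

  df <- data.frame(depth = c(700, 800, 100, 2000),
                   label = c("SLOW", "SLOW", "FAST", "FAST"))
  by <- depth_band_occupancy(df, by_label = TRUE)
  expect_equal(by$overall, 0.5)
  expect_equal(by$SLOW, 1)
  expect_equal(by$FAST, 0)
})
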