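test_that("value channel is the channel maximum, rescaled by bit depth", {
  f <- array(0, dim = c(2, 2, 3))
  f[1, 1, ] <- c(255, 255, 255)
  f[1, 2, ] <- c(0, 0, 0)
  f[2, 1, ] <- c(51, 128, 77)
  f[2, 2, ] <- c(10, 20, 30)
  v <- to_value_channel(image_series(list(f), 0, "rgb"))
  expect_equal(v$frames[[1]][1, 1], 1)
  expect_equal(v$frames[[1]][1, 2], 0)
  expect_equal(v$frames[[1]][2, 1], 128 / 255)
  expect_equal(v$frames[[1]][2, 2], 30 / 255)
  # already-normalised input passes through and inversion flips it
  g <- array(0.25, dim = c(2, 2, 3))
  vi <- to_value_channel(image_series(list(g), 0, "rgb"), invert = TRUE)
  expect_equal(vi$frames[[1]][1, 1], 0.75)
  expect_error(to_value_channel(gray_series(list(matrix(0, 2, 2)))), "RGB")
})

test_that("background subtraction zeroes identical frames and isolates
           added signal", {
  base <- matrix(0.3, 20, 20)
  s <- subtract_background(gray_series(list(base, base, base)))
  for (f in s$frames) expect_true(all(f == 0))
  disk <- base
  disk[8:12, 8:12] <- 0.6
  s <- subtract_background(gray_series(list(base, disk)))
  expect_equal(sum(s$frames[[2]] > 0), 25)
  expect_true(all(s$frames[[2]][8:12, 8:12] == 0.3))
  expect_error(subtract_background(gray_series(list(base))), "two frames")
})

test_that("smoothing preserves constants and matches the truncated kernel
           on an impulse", {
  const <- matrix(0.4, 30, 30)
  s <- smooth_frames(gray_series(list(const)),
                     preprocess_params(smoothing_passes = 1))
  expect_equal(s$frames[[1]], const, tolerance = 1e-12)
  imp <- matrix(0, 31, 31)
  imp[16, 16] <- 1
  s <- smooth_frames(gray_series(list(imp)),
                     preprocess_params(smoothing_passes = 1))
  # oracle: truncated renormalised 7x7 Gaussian evaluated directly
  d <- (-3):3
  k <- outer(exp(-d^2 / 2), exp(-d^2 / 2))
  k <- k / sum(k)
  expect_equal(s$frames[[1]][16, 16], k[4, 4], tolerance = 1e-12)
  expect_equal(s$frames[[1]][13:19, 13:19], k, tolerance = 1e-12)
})

test_that("two smoothing passes equal one pass with the kernel's
           self-convolution (interior)", {
  withr::with_seed(4, {
    frame <- matrix(runif(40 * 40), 40, 40)
  })
  twice <- smooth_frames(gray_series(list(frame)),
                         preprocess_params(smoothing_passes = 2))$frames[[1]]
  # oracle: direct 13x13 convolution with the self-convolved kernel
  k <- gaussian_kernel(1, 7)
  k2 <- matrix(0, 13, 13)
  for (i in 1:7) for (j in 1:7) {
    k2[i:(i + 6), j:(j + 6)] <- k2[i:(i + 6), j:(j + 6)] + k[i, j] * k
  }
  expect_equal(sum(k2), 1, tolerance = 1e-12)
  direct <- matrix(NA_real_, 40, 40)
  for (r in 7:34) for (cc in 7:34) {
    direct[r, cc] <- sum(k2 * frame[(r - 6):(r + 6), (cc - 6):(cc + 6)])
  }
  expect_equal(twice[7:34, 7:34], direct[7:34, 7:34], tolerance = 1e-10)
})

test_that("a single global threshold separates biomass from background", {
  flat <- matrix(0.4, 15, 15)
  disk <- flat
  disk[5:9, 5:9] <- 0.8
  th <- threshold_series(gray_series(list(flat, disk)),
                         preprocess_params(threshold_v = 0.5))
  expect_false(any(th$masks[[1]]))
  expect_equal(sum(th$masks[[2]]), 25)
  expect_equal(th$threshold, 0.5)
})

test_that("raising the threshold never increases foreground (monotonicity)", {
  withr::with_seed(11, {
    frames <- replicate(4, matrix(runif(400), 20, 20), simplify = FALSE)
  })
  s <- gray_series(frames)
  counts <- sapply(seq(0.1, 0.9, by = 0.2), function(thr) {
    sum(sapply(threshold_series(s, preprocess_params(threshold_v = thr))$masks,
               sum))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("the automatic threshold is Otsu on the final frame and recovers
           truth areas within rasterisation error", {
  sim <- simulate_plate(one_colony_spec(rate = 0.3, n_frames = 12,
                                        noise_sd = 0.05, max_area = 3000))
  res <- analyze_plate(sim$series)
  expect_gt(res$threshold, 0.05)
  expect_lt(res$threshold, 0.45)
  on <- sim$truth$true_areas > 50
  est <- res$tracks$area_px[match(which(on), res$tracks$frame)]
  rel <- abs(est - sim$truth$true_areas[on]) / sim$truth$true_areas[on]
  expect_true(all(rel <= 0.15))
})

test_that("degenerate (colony-free) histograms fall back with a warning", {
  withr::with_seed(3, {
    frames <- replicate(3, matrix(0.001 * runif(900), 30, 30),
                        simplify = FALSE)
  })
  expect_warning(
    th <- threshold_series(gray_series(frames), preprocess_params()),
    "degenerate")
  expect_equal(th$threshold, preprocess_params()$fallback_threshold)
})

test_that("seed detection finds one seed per colony, inside its disk", {
  sim <- simulate_plate(one_colony_spec(rate = 0.3, n_frames = 15,
                                        noise_sd = 0.04, max_area = 3000))
  res <- analyze_plate(sim$series)
  expect_equal(nrow(res$seeds), 1)
  truth <- sim$truth$colonies
  d <- sqrt((res$seeds$row_px - truth$y)^2 + (res$seeds$col_px - truth$x)^2)
  expect_lt(d, sqrt(truth$max_area_px / pi))
})

test_that("two colonies give two seeds whether or not they merge late", {
  # never merge
  cols <- data.frame(x = c(60, 160), y = c(110, 110), lag_h = c(2, 4),
                     init_area_px = 100, rate_per_h = c(0.3, 0.2),
                     max_area_px = 2000)
  sp <- plate_spec(220, 220, n_frames = 20, colonies = cols,
                   noise_sd = 0.04, rng_seed = 5)
  res <- analyze_plate(simulate_plate(sp)$series)
  expect_equal(nrow(res$seeds), 2)
  # merge late: disks eventually overlap, early frames dominate the
  # z-projection so both peaks persist
  cols2 <- data.frame(x = c(95, 145), y = c(120, 120), lag_h = 2,
                      init_area_px = 100, rate_per_h = 0.3,
                      max_area_px = 4000)
  sp2 <- plate_spec(240, 240, n_frames = 24, colonies = cols2,
                    noise_sd = 0.04, rng_seed = 6)
  sim2 <- simulate_plate(sp2)
  expect_equal(nrow(sim2$truth$merges), 1)
  res2 <- analyze_plate(sim2$series)
  expect_equal(nrow(res2$seeds), 2)
})

test_that("an empty plate yields no seeds and an empty track list", {
  sp <- plate_spec(60, 60, n_frames = 4, noise_sd = 0.03, rng_seed = 7)
  sim <- simulate_plate(sp)
  res <- suppressWarnings(analyze_plate(sim$series))
  expect_equal(nrow(res$seeds), 0)
  expect_equal(nrow(res$tracks), 0)
})

test_that("seeded splitting partitions every component among its seeds", {
  # dumbbell: two squares joined by a bar, one seed in each square
  m <- matrix(FALSE, 40, 60)
  m[10:30, 5:25] <- TRUE
  m[10:30, 35:55] <- TRUE
  m[19:21, 26:34] <- TRUE
  seeds <- data.frame(seed_id = c(1L, 2L), row_px = c(20L, 20L),
                      col_px = c(15L, 45L))
  lab <- split_merged_colonies(m, seeds)
  expect_setequal(unique(lab[m]), c(1L, 2L))
  expect_true(all(lab[!m] == 0L))
  expect_equal(sum(lab == 1) + sum(lab == 2), sum(m))
  # one seed, one component: whole component takes its label
  lab1 <- split_merged_colonies(m, seeds[1, ])
  expect_equal(sum(lab1 == 1), sum(m))
  # off-foreground seeds are dropped with a warning
  seeds_off <- rbind(seeds, data.frame(seed_id = 3L, row_px = 2L,
                                       col_px = 2L))
  expect_warning(split_merged_colonies(m, seeds_off), "dropped")
})

test_that("a merged pair splits along the perpendicular bisector with areas
           near the truth disks", {
  cols <- data.frame(x = c(100, 160), y = c(130, 130), lag_h = 2,
                     init_area_px = 100, rate_per_h = 0.3,
                     max_area_px = 6000)
  sp <- plate_spec(260, 260, n_frames = 24, colonies = cols,
                   noise_sd = 0.04, rng_seed = 5)
  sim <- simulate_plate(sp)
  res <- analyze_plate(sim$series)
  expect_equal(nrow(res$seeds), 2)
  f <- sim$truth$merges$first_overlap_frame[1]
  est <- res$tracks$area_px[res$tracks$frame == f]
  truth <- sim$truth$raster_areas[, f]
  expect_true(all(abs(est - truth) / truth <= 0.10))
  # partition conservation holds at every frame, merged or not
  v <- smooth_frames(subtract_background(to_value_channel(sim$series)))
  th <- threshold_series(v, preprocess_params(threshold_v = res$threshold))
  for (fr in c(1, f, length(th$masks))) {
    lab <- split_merged_colonies(th$masks[[fr]], res$seeds,
                                 warn_dropped = FALSE)
    expect_equal(sum(lab > 0), sum(th$masks[[fr]]))
  }
})

test_that("per-seed areas of a merged pair sum to the joint component", {
  cols <- data.frame(x = c(100, 150), y = c(125, 125), lag_h = 2,
                     init_area_px = 100, rate_per_h = 0.35,
                     max_area_px = 5000)
  sp <- plate_spec(250, 250, n_frames = 20, colonies = cols,
                   noise_sd = 0.03, rng_seed = 8)
  sim <- simulate_plate(sp)
  res <- analyze_plate(sim$series)
  v <- smooth_frames(subtract_background(to_value_channel(sim$series)))
  th <- threshold_series(v, preprocess_params(threshold_v = res$threshold))
  for (fr in seq_along(th$masks)) {
    tot <- sum(res$tracks$area_px[res$tracks$frame == fr])
    expect_equal(tot, sum(th$masks[[fr]]))
  }
})

test_that("seed recovery: detected seed count equals true colony count over
           many random well-spaced plates", {
  n_ok <- 0
  for (i in 1:100) {
    n_col <- 1 + (i %% 3)
    sp <- random_plate_spec(n_col, rate_range = c(0.15, 0.45),
                            init_area_px = 100, max_area_px = 1200,
                            lag_range_h = c(2, 6), rng_seed = 1000 + i,
                            n_frames = 12, noise_sd = 0.04)
    res <- analyze_plate(simulate_plate(sp)$series)
    if (nrow(res$seeds) == n_col) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 100)
})

test_that("exclusion flags: clean, edge, merged-with-edge and ambiguous", {
  # centred colony, never near the border: no flags
  sim <- simulate_plate(one_colony_spec(n_frames = 10, noise_sd = 0.03,
                                        max_area = 1500))
  res <- analyze_plate(sim$series)
  expect_false(any(res$exclusions$excluded))

  # colony rendered touching the border: edge flag; a second colony merged
  # with it: merged_with_edge
  cols <- data.frame(
    x = c(20, 68), y = c(60, 60), lag_h = 2, init_area_px = 100,
    rate_per_h = 0.3, max_area_px = c(2000, 2000),
    edge_ok = c(TRUE, FALSE))
  sp <- plate_spec(180, 120, n_frames = 20, colonies = cols,
                   noise_sd = 0.03, rng_seed = 9)
  sim <- simulate_plate(sp)
  res <- analyze_plate(sim$series)
  expect_equal(nrow(res$seeds), 2)
  ex <- res$exclusions[order(res$seeds$col_px), ]
  expect_true(ex$edge[1])
  expect_false(ex$edge[2])
  expect_true(ex$merged_with_edge[2])
  expect_true(all(ex$excluded))

  # six colonies merging into one blob with cap 5: all ambiguous
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  cols6 <- data.frame(x = 130 + 40 * cos(ang), y = 130 + 40 * sin(ang),
                      lag_h = 2, init_area_px = 100, rate_per_h = 0.35,
                      max_area_px = 6000)
  sp6 <- plate_spec(260, 260, n_frames = 22, colonies = cols6,
                    noise_sd = 0.03, rng_seed = 10)
  res6 <- analyze_plate(simulate_plate(sp6)$series,
                        max_seeds_per_component = 5)
  expect_equal(nrow(res6$seeds), 6)
  expect_true(all(res6$exclusions$ambiguous_merge))
  # and with a cap of 6 the same plate is not ambiguous
  res6b <- analyze_plate(simulate_plate(sp6)$series,
                         max_seeds_per_component = 6)
  expect_false(any(res6b$exclusions$ambiguous_merge))
})
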