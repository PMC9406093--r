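test_that("node factors invert the relative node gains", {
  nf <- node_factors(c(100, 100, 100, 125))
  expect_equal(nf$factors[4], mean(c(100, 100, 100, 125)) / 125)
  # node 25% above the grand mean gets factor 0.80
  nf2 <- node_factors(c(80, 120, 125, 75))  # grand mean 100, node 3 at 125
  expect_equal(nf2$factors[3], 0.80)
  # node at grand_mean / 1.49 gets factor 1.49 (others arranged so the
  # grand mean stays 100)
  low <- 100 / 1.49
  rest <- (400 - low) / 3
  nf3 <- node_factors(c(rest, low, rest, rest))
  expect_equal(nf3$factors[2], 1.49)
  expect_equal(node_factors(c(1, 1, 1, 1))$factors, rep(1, 4))
})

test_that("applying factors equalizes all node means", {
  set.seed(3)
  for (i in 1:10) {
    means <- runif(6, 50, 250)
    nf <- node_factors(means)
    corrected <- apply_factors(nf, means)
    expect_true(max(abs(corrected - nf$reference_mean)) < 1e-9)
  }
  expect_error(node_factors(c(100, 0, 80)), "dead node")
})

test_that("factor construction recovers the simulator's node deviations", {
  # static deviations put node 5 25% high; its factor must come back 0.80
  tr <- simulate_cylinder(65, noise = noise_model(sigma = 0, seed = 1))
  vals <- as.matrix(as.data.frame(unclass(tr))[, -1])
  nf <- node_factors(colMeans(vals))
  expect_equal(unname(nf$factors[5]), 0.80, tolerance = 1e-6)
  expect_equal(unname(nf$factors[2]), 1.49, tolerance = 0.01)
})

test_that("baseline subtraction zeroes constant traces and isolates steps", {
  m0 <- subtract_baseline(flat_trace(150), idle_window = 1)
  expect_true(all(map_values(m0) == 0))

  cfg <- patch_config(node_count = 10)
  vals <- matrix(200, 120, 10)
  vals[61:120, 8] <- 140  # -60 step at node 8 after 2 s idle
  tr <- adc_trace((0:119) / 30, vals, cfg)
  m <- subtract_baseline(tr, idle_window = 2)
  expect_equal(map_values(m)[120, 8], -60, ignore_attr = TRUE)
  expect_true(all(map_values(m)[, -8] == 0))
  short <- flat_trace(100, n_frames = 10L)
  expect_error(subtract_baseline(short, idle_window = 2), "idle window")
})

test_that("a simulated thumb fold is most negative at node 9", {
  m <- simulate_gesture("10000", finger_templates(), noise_model(sigma = 0))
  prof <- node_profile(m)
  expect_identical(which.min(prof), 9L)
})

test_that("the curvature line fit recovers the generating constants", {
  k <- 2 / c(53, 65, 82, 90, 100)
  fit <- fit_curvature_line(k, 6927.6 * k - 82.6)
  expect_equal(fit$slope, 6927.6, tolerance = 1e-9)
  expect_equal(fit$intercept, -82.6, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1.0)
  expect_equal(fit$calibration$c1, 82.6, tolerance = 1e-9)
  # degenerate fits
  expect_error(fit_curvature_line(c(0.02, 0.02, 0.02), c(1, 2, 3)), "distinct")
  flat <- fit_curvature_line(k, rep(100, 5))
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  expect_equal(flat$r_squared, 0, tolerance = 1e-12)
})

test_that("noisy cylinder means still recover the slope within 5%", {
  diams <- c(53, 65, 82, 90, 100)
  mean_adc <- sapply(seq_along(diams), function(i) {
    tr <- simulate_cylinder(diams[i], noise = noise_model(sigma = 5, seed = i))
    mean(as.matrix(as.data.frame(unclass(tr))[, -1]))
  })
  fit <- fit_curvature_line(2 / diams, mean_adc)
  expect_lt(abs(fit$slope - 6927.6) / 6927.6, 0.05)
  expect_gte(fit$r_squared, 0.95)
})

test_that("adc_to_curvature applies the empirical law and its round trip", {
  cal <- curvature_calibration()
  expect_equal(adc_to_curvature(184.7, cal), (184.7 + 82.6) / 6927.6)
  expect_equal(adc_to_curvature(-82.6, cal), 0)
  expect_warning(out <- adc_to_curvature(-90, cal), "clipped")
  expect_equal(out, 0)
  expect_equal(signif(curvature_resolution(cal), 2), 0.00014)
  # round trip: kappa -> forward law -> back
  kappas <- seq(0, 0.05, by = 0.005)
  expect_equal(adc_to_curvature(cal$c2 * kappas - cal$c1, cal), kappas)
  expect_equal(curvature_radius(0.04), 25)
  expect_error(curvature_radius(0), "non-positive")
})

test_that("stage detection partitions ramp / plateau / release traces", {
  cfg <- patch_config(node_count = 6)
  # 2 s idle at 100, ramp to 220 over 1 s, hold 2 s, detach to ~0
  idle <- matrix(100, 60, 6)
  ramp <- matrix(rep(seq(100, 220, length.out = 30), 6), 30, 6)
  hold <- matrix(220, 60, 6)
  det <- matrix(2, 10, 6)
  vals <- rbind(idle, ramp, hold, det)
  tr <- adc_trace((seq_len(nrow(vals)) - 1) / 30, vals, cfg)
  seg <- detect_stages(tr, onset_level = 30)
  expect_identical(as.character(seg$labels[30]), "attach_idle")
  expect_identical(as.character(seg$labels[120]), "curvature_change")
  expect_identical(as.character(seg$labels[155]), "detach")
  expect_false(seg$alleviation)
  expect_identical(seg$detach_frame, 151L)

  # flat trace stays in stage I throughout
  seg0 <- detect_stages(flat_trace(100), onset_level = 30)
  expect_true(all(seg0$labels == "attach_idle"))

  # onset then return below the onset level flags alleviation
  vals2 <- rbind(idle, ramp, hold, matrix(110, 60, 6))
  tr2 <- adc_trace((seq_len(nrow(vals2)) - 1) / 30, vals2, cfg)
  seg2 <- detect_stages(tr2, onset_level = 30)
  expect_true(seg2$alleviation)
})
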