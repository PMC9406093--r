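test_that("finger templates honour the per-finger peak-node anatomy", {
  tpl <- finger_templates()
  expect_identical(which.min(tpl$thumb), 9L)
  expect_identical(which.min(tpl$index), 8L)
  expect_identical(which.min(tpl$middle), 6L)
  expect_identical(which.min(tpl$ring), 5L)
  # little: two comparable negative peaks at nodes 3 and 4
  expect_true(all(tpl$little[c(3, 4)] < -40))
  expect_lt(abs(tpl$little[3] - tpl$little[4]), 0.2 * abs(tpl$little[3]))
  # thumb: positive periphery at 7 and 10, weak dent at 8
  expect_true(all(tpl$thumb[c(7, 10)] > 0))
  expect_true(tpl$thumb[8] < 0 && tpl$thumb[8] > tpl$thumb[9])
  # index: valleys at 7, 8, 9; convex flanks at 6 and 10
  expect_true(all(tpl$index[7:9] < 0))
  expect_true(all(tpl$index[c(6, 10)] > 0))
  expect_error(finger_templates(scale = -5), "scale")
})

test_that("natural multi-folds are the exact linear sum of their fingers", {
  tpl <- finger_templates()
  nm0 <- noise_model(sigma = 0)
  m <- simulate_gesture("00111", tpl, nm0)
  lin <- tpl$middle + tpl$ring + tpl$little
  expect_equal(map_values(m)[60, ], lin, ignore_attr = TRUE)
  # all-unfolded, no noise: identically zero
  m0 <- simulate_gesture("00000", tpl, nm0)
  expect_true(all(map_values(m0) == 0))
})

test_that("unnatural folds deviate from the linear sum by at least 125", {
  tpl <- finger_templates()
  for (code in c("01001", "00101", "01101", "10101", "11101")) {
    bits <- as.integer(strsplit(code, "")[[1]])
    lin <- Reduce(`+`, tpl[finger_names()[bits == 1]])
    prof <- gesture_profile(code, tpl)
    expect_gte(max(abs(prof - lin)), 125)
    expect_false(is_natural_gesture(code))
  }
  expect_true(is_natural_gesture("00111"))
  expect_error(simulate_gesture("0011", finger_templates()), "5-character")
})

test_that("all 32 binaries have distinct noiseless signatures", {
  tpl <- finger_templates()
  profs <- sapply(gesture_codes(), gesture_profile, templates = tpl)
  d <- as.matrix(stats::dist(t(profs), method = "maximum"))
  expect_gt(min(d[upper.tri(d)]), 0)
})

test_that("negative deformation scales ~3.49x from one to four folded fingers, linearly", {
  tpl <- finger_templates()
  neg_sum <- function(p) -sum(p[p < 0])
  ns <- sapply(gesture_codes(), function(c) neg_sum(gesture_profile(c, tpl)))
  nf <- sapply(strsplit(gesture_codes(), ""), function(b) sum(b == "1"))
  by_n <- tapply(ns, nf, mean)
  expect_equal(unname(by_n[["4"]] / by_n[["1"]]), 3.49, tolerance = 0.01)
  r2 <- summary(stats::lm(by_n[2:5] ~ c(1:4)))$r.squared
  expect_gte(r2, 0.96)
  # folding the fifth finger relieves rather than deepens (interference)
  expect_lt(by_n[["5"]], by_n[["4"]])
})

test_that("cylinder simulation follows the forward law and diameter ordering", {
  cal <- curvature_calibration()
  tr <- simulate_cylinder(100, cal, noise_model(sigma = 0, node_deviation = rep(1, 6)))
  vals <- as.matrix(as.data.frame(unclass(tr))[, -1])
  expect_equal(unique(as.numeric(vals)), cal$c2 * (2 / 100) - cal$c1,
               tolerance = 1e-9)
  means <- sapply(c(53, 65, 82, 90, 100), function(d) {
    mean(as.matrix(as.data.frame(unclass(
      simulate_cylinder(d, cal, noise_model(sigma = 0))))[, -1]))
  })
  expect_true(all(diff(means) < 0))  # smaller diameter, stronger signal
})

test_that("trial sets are sized, labeled, and reproducible under the seed", {
  ts1 <- simulate_trial_set(3, seed = 9)
  expect_length(ts1, 15L)
  expect_identical(vapply(ts1[1:3], `[[`, "", "finger"),
                   rep("thumb", 3))
  ts2 <- simulate_trial_set(3, seed = 9)
  expect_identical(lapply(ts1, function(x) map_values(x$map)),
                   lapply(ts2, function(x) map_values(x$map)))
  ts3 <- simulate_trial_set(3, seed = 10)
  expect_false(identical(map_values(ts1[[1]]$map), map_values(ts3[[1]]$map)))
})

test_that("attachment drift traces have 31 samples, 26/5 split, decaying mean", {
  tr <- simulate_attachment_drift(drift_spec(sigma = 0), seed = 1)
  expect_length(tr$t, 31L)
  expect_equal(tr$t, seq(0, 60, by = 2))
  expect_identical(tr$train_idx, 1:26)
  expect_identical(tr$test_idx, 27:31)
  expect_true(all(diff(tr$y) < 0))  # noiseless decay is strictly decreasing
  tr2 <- simulate_attachment_drift(seed = 4)
  expect_identical(tr2$y, simulate_attachment_drift(seed = 4)$y)
})
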