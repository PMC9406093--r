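test_that("build_map subtracts baselines and upsampling preserves node values", {
  cfg <- patch_config(node_count = 10)
  tr <- adc_trace(0, matrix(100, 1, 10), cfg)
  m <- build_map(tr, baseline = rep(100, 10))
  expect_equal(dim(map_values(m)), c(1L, 10L))
  expect_true(all(map_values(m) == 0))

  vals <- matrix(rep(seq(100, 190, by = 10), each = 2), 2, 10)
  tr2 <- adc_trace(c(0, 1 / 30), vals, cfg)
  m4 <- build_map(tr2, baseline = rep(0, 10), upsample = 4)
  expect_length(map_nodes(m4), 37L)
  orig <- map_nodes(m4) %in% 1:10
  expect_equal(map_values(m4)[1, orig], seq(100, 190, by = 10),
               ignore_attr = TRUE)
  expect_true(attr(m4, "interpolated"))
  expect_error(classify_single_finger(m4), "interpolated")
})

test_that("1-D k-means separates well-separated values and is deterministic", {
  m <- new_map_for_test(c(rep(0, 50), rep(-60, 50)))
  q <- quantize_map(m, k = 2)
  expect_equal(q$centroids, c(-60, 0))
  expect_equal(sort(unique(as.integer(q$labels))), c(1L, 2L))
  # perfect separation
  expect_true(all(q$labels[map_values(m) == -60] == 1L))

  q2 <- quantize_map(m, k = 2)
  expect_identical(q$labels, q2$labels)
})

test_that("k equal to the number of distinct values gives zero error; k above errors", {
  m <- new_map_for_test(rep(c(-80, -40, 0, 40), each = 25))
  q <- quantize_map(m, k = 4)
  expect_equal(q$centroids, c(-80, -40, 0, 40))
  recon <- q$centroids[q$labels]
  expect_equal(as.numeric(recon), as.numeric(map_values(m)))
  expect_error(quantize_map(m, k = 5), "distinct")
})

test_that("k-means matches the brute-force optimal 1-D threshold partition", {
  vals <- rep(c(-80, -40, 0, 40), each = 25)
  m <- new_map_for_test(vals)
  q <- quantize_map(m, k = 2)
  # brute force over the 3 threshold partitions of the sorted distinct values
  sse <- function(groups) sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  parts <- lapply(1:3, function(cut) {
    thr <- c(-80, -40, 0)[cut]
    list(vals[vals <= thr], vals[vals > thr])
  })
  best <- which.min(sapply(parts, sse))
  expect_equal(best, 2L)  # {-80,-40} vs {0,40}
  expect_true(all(q$labels[vals <= -40] == 1L))
  expect_true(all(q$labels[vals > -40] == 2L))
})

test_that("quantization is idempotent with fixed centroids and conserves mass", {
  m <- simulate_gesture("01100", noise = noise_model(sigma = 10, seed = 2))
  q <- quantize_map(m, k = 6)
  recon <- new_map_for_test(as.numeric(q$centroids[q$labels]),
                            nrow = nrow(q$labels))
  q2 <- quantize_map(recon, centroids = q$centroids)
  expect_identical(as.integer(q2$labels), as.integer(q$labels))
  # cluster means conserve the grid total
  tot <- sum(sapply(seq_len(q$k), function(i) {
    sum(q$labels == i) * q$centroids[i]
  }))
  expect_equal(tot, sum(map_values(m)), tolerance = 1e-6)
})

test_that("k-means labelings are locally optimal against single reassignments", {
  m <- simulate_gesture("00110", noise = noise_model(sigma = 10, seed = 5))
  q <- quantize_map(m, k = 5)
  v <- as.numeric(map_values(m))
  lab <- as.integer(q$labels)
  # with centroids fixed at cluster means, every cell already sits with its
  # nearest centroid, so any single swap cannot lower the SSE
  cen <- sapply(seq_len(q$k), function(i) mean(v[lab == i]))
  nearest <- apply(outer(v, cen, function(a, b) (a - b)^2), 1, which.min)
  expect_identical(nearest, lab)
})

test_that("core lines are extracted with 4-connectivity, depth order, tie rules", {
  expect_length(extract_core_lines(new_map_for_test(rep(0, 100))), 0L)

  vals <- matrix(0, 5, 10)
  vals[, 9] <- -60
  m <- new_deformation_map_for_test(vals)
  cl <- extract_core_lines(m)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$nodes, 9)
  expect_equal(cl[[1]]$depth, -60)
  expect_equal(cl[[1]]$extent, 5L)

  # two disjoint lines sorted deepest first
  vals2 <- matrix(0, 4, 10)
  vals2[, 3] <- -50
  vals2[, 8] <- -90
  cl2 <- extract_core_lines(new_deformation_map_for_test(vals2))
  expect_equal(sapply(cl2, `[[`, "depth"), c(-90, -50))
  # threshold -Inf merges everything into one whole-grid line
  cl3 <- extract_core_lines(new_deformation_map_for_test(vals2),
                            threshold = -Inf)
  expect_length(cl3, 1L)
  expect_equal(cl3[[1]]$extent, 40L)
  expect_error(extract_core_lines(m, threshold = 10), "<= 0")
})

test_that("a simulated '11110' map forms core lines covering nodes 4, 5 and 8", {
  m <- simulate_gesture("11110", noise = noise_model(sigma = 0))
  cl <- extract_core_lines(m)
  covered <- sort(unique(unlist(lapply(cl, `[[`, "nodes"))))
  expect_true(all(c(4, 5, 8) %in% covered))
})
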