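test_that("a fully occupied volume saturates every valid node at 1", {
  vol <- labeled_volume(array(1L, c(20, 20, 20)), c(200, 200, 200))
  dm <- compute_density_map(vol, kernel_radius_um = 0.5, step_um = 0.5)
  expect_true(all(dm$values[dm$valid] == 1))
})

test_that("an empty volume is 0 everywhere", {
  vol <- labeled_volume(array(0L, c(16, 16, 16)), c(200, 200, 200))
  dm <- compute_density_map(vol, kernel_radius_um = 0.5, step_um = 0.5)
  expect_true(all(dm$values[dm$valid] == 0))
})

test_that("a concentric ball of half the kernel radius gives ~1/8 at the central node", {
  # ball radius 0.5 um at a node; kernel radius 1.0 um -> (0.5/1.0)^3 = 0.125
  sp_um <- c(0.05, 0.05, 0.05)
  n <- 60
  ctr <- n / 2 * 0.05 # 1.5 um, a multiple of step 0.25 -> a node sits there
  v <- (seq_len(n) - 0.5) * 0.05 - ctr
  arr <- array(as.integer(outer(outer(v^2, v^2, `+`), v^2, `+`) <= 0.5^2), c(n, n, n))
  vol <- labeled_volume(arr, sp_um * 1000)
  dm <- compute_density_map(vol, kernel_radius_um = 1.0, step_um = 0.25)
  node <- ctr / 0.25 + 1
  got <- dm$values[node, node, node]
  expect_equal(got, 0.125, tolerance = 0.02)
  oracle <- density_node_oracle(arr, sp_um, rep(ctr, 3), 1.0)
  expect_equal(got, unname(oracle["occupied"] / oracle["in_bounds"]), tolerance = 1e-12)
})

test_that("node values equal direct voxel counting to 1e-9 relative", {
  vol <- random_label_volume(c(24, 24, 24), p_fg = 0.3, seed = 7, spacing_nm = c(100, 100, 100))
  dm <- compute_density_map(vol, kernel_radius_um = 0.4, step_um = 0.5)
  d <- dim(dm$values)
  set.seed(1)
  for (k in 1:12) {
    u <- sample(d[1], 1); v <- sample(d[2], 1); w <- sample(d[3], 1)
    node <- c((u - 1) * 0.5, (v - 1) * 0.5, (w - 1) * 0.5)
    o <- density_node_oracle(unclass(vol), c(0.1, 0.1, 0.1), node, 0.4)
    if (o["in_bounds"] == 0) next
    expect_equal(dm$values[u, v, w], unname(o["occupied"] / o["in_bounds"]),
      tolerance = 1e-9
    )
  }
})

test_that("adding occupied voxels never decreases any node value", {
  vol1 <- random_label_volume(c(16, 16, 16), p_fg = 0.2, seed = 3, spacing_nm = c(150, 150, 150))
  arr2 <- unclass(vol1)
  extra <- which(arr2 == 0L)[c(10, 50, 200, 400)]
  arr2[extra] <- 1L
  vol2 <- labeled_volume(arr2, c(150, 150, 150))
  d1 <- compute_density_map(vol1, kernel_radius_um = 0.5, step_um = 0.5)
  d2 <- compute_density_map(vol2, kernel_radius_um = 0.5, step_um = 0.5)
  expect_true(all(d2$values >= d1$values - 1e-12, na.rm = TRUE))
})

test_that("interior node mean tracks the global occupied fraction of a random mask", {
  p <- 0.3
  vol <- random_label_volume(c(32, 32, 32), p_fg = p, seed = 17, spacing_nm = c(100, 100, 100))
  dm <- compute_density_map(vol, kernel_radius_um = 0.5, step_um = 0.4, edge_policy = "strict")
  vals <- dm$values[dm$valid]
  # 3 standard errors of the per-node binomial mean (nodes overlap; this is conservative per node)
  kern_vox <- 4 / 3 * pi * 0.5^3 / 0.001
  se <- sqrt(p * (1 - p) / kern_vox)
  expect_lt(abs(mean(vals) - mean(unclass(vol) > 0)), 3 * se)
})

test_that("edge policies differ in validity, and a clipped corner is invalid by default", {
  vol <- labeled_volume(array(1L, c(12, 12, 12)), c(200, 200, 200))
  ren <- compute_density_map(vol, kernel_radius_um = 1, step_um = 0.6)
  strict <- compute_density_map(vol, kernel_radius_um = 1, step_um = 0.6, edge_policy = "strict")
  expect_false(ren$valid[1, 1, 1]) # corner node has ~1/8 kernel coverage
  expect_gt(sum(ren$valid), sum(strict$valid))
})

test_that("overlap score is 1 against itself and -1 against the complement", {
  vol <- random_label_volume(c(20, 20, 20), p_fg = 0.3, seed = 5, spacing_nm = c(150, 150, 150))
  dm <- compute_density_map(vol, kernel_radius_um = 0.5, step_um = 0.5)
  expect_equal(overlap_score(dm, dm)$correlation, 1)
  inv <- dm
  inv$values <- 1 - dm$values
  expect_equal(overlap_score(dm, inv)$correlation, -1)
})

test_that("grid mismatch is an incompatibility error", {
  vol <- random_label_volume(c(20, 20, 20), p_fg = 0.3, seed = 5, spacing_nm = c(150, 150, 150))
  a <- compute_density_map(vol, kernel_radius_um = 0.5, step_um = 0.5)
  b <- compute_density_map(vol, kernel_radius_um = 0.5, step_um = 0.6)
  expect_error(overlap_score(a, b), "grid")
})

test_that("a kernel smaller than a voxel is a configuration error", {
  vol <- labeled_volume(array(1L, c(8, 8, 8)), c(300, 300, 300))
  expect_error(compute_density_map(vol, kernel_radius_um = 0.2), "kernel radius")
})
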