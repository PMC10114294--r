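test_that("collinear centroids give the textbook NN distances", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)) + 0.55 # (x, y, z) um, offset into the grid
  vol <- make_instances_from_points(pts)
  inst <- split_instances(vol)
  nn <- nearest_neighbor(inst)
  expect_equal(sort(nn$nn_distance_um), c(1, 1, 2))
})

test_that("NN distances match the brute-force oracle on random point sets", {
  set.seed(21)
  pts <- cbind(runif(400, 0, 20), runif(400, 0, 20), runif(400, 0, 20))
  # work directly on an instance table with known centroids
  vol <- make_instances_from_points(pts, spacing_nm = c(100, 100, 100))
  inst <- split_instances(vol)
  nn <- nearest_neighbor(inst)
  ctr <- cbind(inst$centroid_x_um, inst$centroid_y_um, inst$centroid_z_um)
  expect_equal(nn$nn_distance_um, nn_oracle(ctr), tolerance = 1e-12)
  # minimality: each reported distance is <= distance to every other point
  for (i in sample(nrow(inst), 20)) {
    d <- sqrt(rowSums(sweep(ctr[-i, , drop = FALSE], 2, ctr[i, ], `-`)^2))
    expect_gte(min(d), nn$nn_distance_um[i] - 1e-12)
  }
})

test_that("distances scale with the physical spacing, not the voxel grid", {
  arr <- array(0L, c(4, 4, 4))
  arr[1, 1, 1] <- 1L
  arr[2, 1, 1] <- 2L # adjacent along z
  arr[1, 1, 3] <- 3L # two steps along x
  vol <- labeled_volume(arr, c(40, 30, 30))
  nn <- nearest_neighbor(split_instances(vol))
  expect_equal(nn$nn_distance_um[1], 0.040) # z neighbour at 40 nm spacing
  arr2 <- array(0L, c(4, 4, 4))
  arr2[1, 1, 1] <- 1L
  arr2[1, 1, 2] <- 2L
  vol2 <- labeled_volume(arr2, c(40, 30, 30))
  nn2 <- nearest_neighbor(split_instances(vol2))
  expect_equal(nn2$nn_distance_um, c(0.030, 0.030))
})

test_that("a 40 nm gap excludes both members; a 60 nm gap retains them", {
  mk <- function(gap_vox) {
    arr <- array(0L, c(12, 6, 6))
    arr[1:3, 1:3, 1:3] <- 1L
    arr[(4 + gap_vox):(6 + gap_vox), 1:3, 1:3] <- 2L
    split_instances(labeled_volume(arr, c(20, 20, 20)))
  }
  # boundary voxel centers 2 voxels apart -> 40 nm gap
  close_pair <- proximity_exclusion(mk(1), min_gap_nm = 50)
  expect_equal(nrow(close_pair), 0)
  expect_equal(sort(attr(close_pair, "excluded")$id), c(1, 2))
  expect_equal(attr(close_pair, "excluded")$gap_nm, c(40, 40))
  # 3 voxels apart -> 60 nm gap
  far_pair <- proximity_exclusion(mk(2), min_gap_nm = 50)
  expect_equal(nrow(far_pair), 2)
  expect_equal(nrow(attr(far_pair, "excluded")), 0)
})

test_that("min_gap = 0 disables the exclusion filter", {
  arr <- array(0L, c(6, 3, 3))
  arr[1, 1, 1] <- 1L
  arr[3, 1, 1] <- 2L
  inst <- split_instances(labeled_volume(arr, c(10, 10, 10)))
  out <- proximity_exclusion(inst, min_gap_nm = 0)
  expect_equal(nrow(out), 2)
})

test_that("raising min_gap never increases the retained count", {
  vol <- random_label_volume(c(24, 24, 24), p_fg = 0.08, seed = 13, spacing_nm = c(40, 30, 30))
  inst <- split_instances(vol)
  kept <- vapply(
    c(0, 30, 60, 120, 240),
    function(g) nrow(proximity_exclusion(inst, min_gap_nm = g)),
    numeric(1)
  )
  expect_true(all(diff(kept) <= 0))
})

test_that("exclude_one keeps the larger member of each close pair", {
  arr <- array(0L, c(10, 6, 6))
  arr[1:2, 1:2, 1:2] <- 1L # 8 voxels
  arr[4:8, 1:4, 1:4] <- 2L # 80 voxels, gap 1 voxel = 20 nm
  inst <- split_instances(labeled_volume(arr, c(20, 20, 20)))
  out <- proximity_exclusion(inst, min_gap_nm = 50, mode = "exclude_one")
  expect_equal(out$id, 2)
})

test_that("nn_summary reports threshold fractions and interpolated percentiles", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)) + 0.55
  nn <- nearest_neighbor(split_instances(make_instances_from_points(pts)))
  s <- nn_summary(nn, thresholds_um = 1)
  expect_equal(unname(s$fraction_within_um["1"]), 2 / 3)
  expect_equal(s$median_um, 1)
  # degenerate distribution: all percentiles collapse onto the common value
  pts2 <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0), c(6, 0, 0)) + 0.55
  nn2 <- nearest_neighbor(split_instances(make_instances_from_points(pts2)))
  s2 <- nn_summary(nn2)
  expect_equal(unname(s2$percentiles_um), rep(2, 4), tolerance = 1e-12)
  expect_equal(s2$iqr_um, c(2, 2), tolerance = 1e-12)
})

test_that("object ordering does not change distances or summaries", {
  set.seed(31)
  pts <- cbind(runif(60, 0, 10), runif(60, 0, 10), runif(60, 0, 10))
  n1 <- nearest_neighbor(split_instances(make_instances_from_points(pts)))
  n2 <- nearest_neighbor(split_instances(make_instances_from_points(pts[rev(seq_len(60)), ])))
  expect_equal(sort(n1$nn_distance_um), sort(n2$nn_distance_um), tolerance = 1e-12)
  expect_equal(
    nn_summary(n1)$percentiles_um, nn_summary(n2)$percentiles_um,
    tolerance = 1e-12
  )
})

test_that("fewer than two retained objects is an error", {
  arr <- array(0L, c(3, 3, 3))
  arr[1, 1, 1] <- 1L
  inst <- split_instances(labeled_volume(arr, c(10, 10, 10)))
  expect_error(nearest_neighbor(inst), "at least 2")
})
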