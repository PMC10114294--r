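test_that("disjoint objects split into separate instances with exact counts", {
  arr <- array(0L, c(8, 8, 8))
  arr[2, 2, 2] <- 1L
  arr[2, 2, 3] <- 1L # plus-shaped 5-voxel object around (2,2,2)? keep simple: two bars
  arr[2:6, 2, 2] <- 1L
  arr[2:6, 6, 6] <- 1L
  vol <- labeled_volume(arr, c(10, 10, 10))
  inst <- split_instances(vol)
  expect_equal(nrow(inst), 2)
  expect_setequal(inst$voxel_count, c(6, 5))
})

test_that("corner-touching voxels merge at 26-connectivity and split at 6", {
  arr <- array(0L, c(4, 4, 4))
  arr[1, 1, 1] <- 1L
  arr[2, 2, 2] <- 1L
  vol <- labeled_volume(arr, c(10, 10, 10))
  expect_equal(nrow(split_instances(vol, connectivity = 26)), 1)
  expect_equal(nrow(split_instances(vol, connectivity = 6)), 2)
})

test_that("connected components agree with the independent graph oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    vol <- random_label_volume(c(24, 24, 24), p_fg = 0.3, n_classes = 2, seed = seed)
    for (conn in c(6, 26)) {
      inst <- split_instances(vol, connectivity = conn)
      mine <- cc_signature(attr(inst, "instance_volume"))
      ref <- cc_signature(cc_oracle(unclass(vol), conn))
      expect_identical(mine, ref, info = sprintf("seed %d conn %d", seed, conn))
    }
  }
})

test_that("instances partition the foreground exactly", {
  for (seed in c(3, 9)) {
    vol <- random_label_volume(c(20, 20, 20), p_fg = 0.4, seed = seed)
    inst <- split_instances(vol)
    expect_equal(sum(inst$voxel_count), sum(vol > 0L))
    iv <- attr(inst, "instance_volume")
    expect_true(all((iv > 0L) == (unclass(vol) > 0L)))
  }
})

test_that("single-voxel morphometrics follow the voxel geometry", {
  arr <- array(0L, c(3, 3, 3))
  arr[1, 1, 1] <- 1L
  vol <- labeled_volume(arr, c(20, 15, 15))
  inst <- measure_basic(split_instances(vol))
  expect_equal(inst$volume_um3, 4500 / 1e9)
  expect_equal(inst$centroid_x_um, 0.0075)
  expect_equal(inst$centroid_y_um, 0.0075)
  expect_equal(inst$centroid_z_um, 0.010)
})

test_that("a 2x2x2 cube at 10 nm has 8000 nm^3 volume and a central centroid", {
  arr <- array(0L, c(6, 6, 6))
  arr[3:4, 3:4, 3:4] <- 1L
  vol <- labeled_volume(arr, c(10, 10, 10))
  inst <- split_instances(vol)
  expect_equal(inst$volume_um3, 8000 / 1e9)
  # cube spans voxels 3-4, i.e. physical [0.02, 0.04] um: center at 0.03
  expect_equal(inst$centroid_x_um, 0.030)
  expect_equal(inst$centroid_z_um, 0.030)
})

test_that("digitized ellipsoid volume matches the analytic value within 3%", {
  vol <- ellipsoid_volume(c(1, 1, 2), spacing_nm = c(20, 20, 20))
  inst <- split_instances(vol)
  expect_equal(inst$volume_um3, 4 / 3 * pi * 2, tolerance = 0.03)
})

test_that("volume outlier flagging applies the median-ratio threshold", {
  mk <- function(vols) {
    # synthetic instance table via single cubes of varying size
    arr <- array(0L, c(40, 10, 10 * length(vols)))
    for (i in seq_along(vols)) {
      k <- round(vols[i]^(1 / 3))
      arr[1:k, 1:k, (10 * (i - 1) + 1):(10 * (i - 1) + k)] <- 1L
    }
    split_instances(labeled_volume(arr, c(100, 100, 100)))
  }
  inst <- mk(c(1, 1, 1, 1))
  tab <- tibble::as_tibble(inst)
  # direct numeric check of the rule itself
  fake <- inst
  fake$volume_um3 <- c(1, 1, 1, 150)
  expect_equal(flag_volume_outliers(fake, factor = 100), fake$id[4])
  fake$volume_um3 <- c(1, 1, 1, 50)
  expect_length(flag_volume_outliers(fake, factor = 100), 0)
  expect_error(flag_volume_outliers(fake[1:2, ]), "3 objects")
})

test_that("volume fractions count child voxels inside each parent", {
  cells <- array(0L, c(10, 10, 20))
  cells[, , 1:10] <- 1L
  cells[, , 11:20] <- 2L
  nuc <- array(0L, c(10, 10, 20))
  nuc[1:5, 1:5, 1:4] <- 1L # 100 voxels in cell 1 (1000 voxels)
  parent <- labeled_volume(cells, c(100, 100, 100), "cells")
  child <- split_instances(labeled_volume(nuc, c(100, 100, 100), "nuclei"))
  vf <- volume_fraction(child, parent)
  expect_equal(vf$fraction[vf$parent_id == 1], 0.1)
  expect_equal(vf$fraction[vf$parent_id == 2], 0)
})

test_that("stray child voxels are reported, not dropped", {
  cells <- array(0L, c(4, 4, 4))
  cells[1:2, , ] <- 1L
  nuc <- array(0L, c(4, 4, 4))
  nuc[3, 1, 1] <- 1L # outside the only parent
  parent <- labeled_volume(cells, c(50, 50, 50), "cells")
  child <- split_instances(labeled_volume(nuc, c(50, 50, 50), "nuclei"))
  expect_warning(vf <- volume_fraction(child, parent), "outside")
  expect_equal(attr(vf, "outside"), 1)
})

test_that("tidy and glance give broom-style views of an instance set", {
  vol <- random_label_volume(c(12, 12, 12), p_fg = 0.2, seed = 2)
  inst <- split_instances(vol)
  td <- tidy(inst)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "instance_set"))
  g <- glance(inst)
  expect_equal(g$n_objects, nrow(inst))
  expect_equal(g$total_volume_um3, sum(inst$volume_um3))
})
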