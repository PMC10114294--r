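# Recovery and contract tests of the synthetic organoid generator. Scenes are
# kept small (tens of micrometres at 250-300 nm voxels) so the whole suite
# stays fast; the statistical recoveries use the sizes the contracts state.

small_spec <- function(...) {
  synthetic_spec(
    shape = c(48, 56, 56), spacing_nm = c(300, 250, 250),
    n_cells = 6, n_junctions = 50, ...
  )
}

test_that("the same spec and seed give bit-identical scenes; different seeds differ", {
  s1 <- generate_organoid(small_spec(seed = 4))
  s2 <- generate_organoid(small_spec(seed = 4))
  s3 <- generate_organoid(small_spec(seed = 5))
  expect_identical(unclass(s1$cells)[, , ], unclass(s2$cells)[, , ])
  expect_identical(unclass(s1$junctions)[, , ], unclass(s2$junctions)[, , ])
  expect_false(identical(unclass(s1$cells)[, , ], unclass(s3$cells)[, , ]))
})

test_that("monolayer scenes hit the lumen fraction target within 0.05", {
  sc <- generate_organoid(small_spec(morphology = "monolayer", seed = 7))
  expect_true(abs(sc$ground_truth$lumen_fraction - 0.6) <= 0.05)
  expect_equal(length(unique(sc$cells[sc$cells > 0])), 6)
  # single connected lumen
  lum <- split_instances(sc$lumen)
  expect_equal(nrow(lum), 1)
})

test_that("compact scenes have zero lumen voxels; mixed scenes have several lumina", {
  comp <- generate_organoid(small_spec(morphology = "compact", seed = 2))
  expect_equal(sum(comp$lumen), 0)
  mix <- generate_organoid(small_spec(morphology = "mixed", seed = 2))
  expect_gte(nrow(mix$ground_truth$lumen), 2)
  expect_true(abs(mix$ground_truth$lumen_fraction - 0.15) <= 0.05)
})

test_that("scene containment invariants hold across a sweep of seeds", {
  for (seed in 1:20) {
    sc <- generate_organoid(synthetic_spec(
      shape = c(40, 44, 44), spacing_nm = c(300, 300, 300),
      n_cells = 5, n_junctions = 30, seed = seed
    ))
    cells <- unclass(sc$cells)
    expect_true(all(cells[unclass(sc$nuclei) > 0] > 0), info = seed)
    # each nucleus lies in its own cell
    nuc <- unclass(sc$nuclei)
    sel <- nuc > 0
    expect_true(all(nuc[sel] == cells[sel]), info = seed)
    expect_true(all(cells[unclass(sc$mitochondria) > 0] > 0), info = seed)
    expect_equal(sum(unclass(sc$lumen) > 0 & cells > 0), 0, info = seed)
    # junction centers were drawn on interface voxels
    truth <- sc$ground_truth$junctions
    if (nrow(truth) > 0) {
      iface <- unclass(sc$interface)
      sp_um <- c(0.3, 0.3, 0.3)
      for (k in seq_len(min(5, nrow(truth)))) {
        v <- as.integer(ceiling(c(
          truth$center_z_um[k] / sp_um[1],
          truth$center_y_um[k] / sp_um[2], truth$center_x_um[k] / sp_um[3]
        )))
        expect_true(iface[v[1], v[2], v[3]] > 0, info = seed)
      }
    }
  }
})

test_that("infeasible packings raise a feasibility error", {
  expect_error(
    generate_organoid(synthetic_spec(
      shape = c(24, 24, 24), spacing_nm = c(300, 300, 300), n_cells = 400
    )),
    "infeasible"
  )
})

test_that("explicit junction centroids give the programmed NN distances", {
  iface <- labeled_volume(array(1L, c(30, 8, 8)), c(200, 200, 200), "interface")
  spec <- synthetic_spec(n_junctions = 3, junction_radius_um = 0.08, seed = 1)
  ctr <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 1.5), c(0.5, 0.5, 3.5)) # (x,y,z)
  jp <- generate_junction_process(spec, iface, centroids_um = ctr)
  inst <- split_instances(jp$volume)
  expect_equal(nrow(inst), 3)
  nn <- nearest_neighbor(inst)
  expect_equal(sort(nn$nn_distance_um), c(1, 1, 2), tolerance = 0.11)
})

test_that("the junction process recovers a programmed 90th-percentile NN distance at n = 5000", {
  # large flat interface: 100 x 100 um plane, 0.2 um voxels
  iface_arr <- array(0L, c(3, 500, 500))
  iface_arr[2, , ] <- 1L
  iface <- labeled_volume(iface_arr, c(200, 200, 200), "interface")
  spec <- synthetic_spec(
    n_junctions = 5000, junction_nn_scale_um = 1.0,
    junction_radius_um = 0.15, seed = 11
  )
  jp <- generate_junction_process(spec, iface)
  expect_equal(nrow(jp$truth), 5000)
  # verify with the brute-force scan on the generated centroids
  pts <- cbind(jp$truth$center_z_um, jp$truth$center_y_um, jp$truth$center_x_um)
  mind <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2 + (pts[, 3] - pts[i, 3])^2
    d2[i] <- Inf
    mind[i] <- sqrt(min(d2))
  }
  q90 <- unname(quantile(mind, 0.9, type = 7))
  expect_equal(q90, 1.0, tolerance = 0.05)
  # hard core: no two centers closer than twice the junction radius
  expect_gte(min(mind), 2 * 0.15)
})

test_that("junction counts beyond the interface capacity raise a feasibility error", {
  iface_arr <- array(0L, c(3, 12, 12))
  iface_arr[2, , ] <- 1L
  iface <- labeled_volume(iface_arr, c(200, 200, 200), "interface")
  spec <- synthetic_spec(n_junctions = 500, junction_radius_um = 0.3, seed = 1)
  expect_error(generate_junction_process(spec, iface), "interface")
})

test_that("ground-truth nucleus ellipsoid volumes match the analytic value", {
  # direct check of the digitisation machinery the generator relies on
  semi <- c(1.2, 1.5, 1.8) # um, smallest semi-axis 12 voxels at 100 nm
  vol <- ellipsoid_volume(semi, c(100, 100, 100))
  inst <- split_instances(vol)
  expect_equal(inst$volume_um3, 4 / 3 * pi * prod(semi), tolerance = 0.03)
})

test_that("tile tables honour programmed damage rates within binomial bounds", {
  tab <- generate_tile_table(
    n_organoids = 8, n_tiles = 50,
    preservation_means = c(g = 0.8), target_r = 0, seed = 3
  )
  pf <- preservation_fraction(tab)
  expect_equal(nrow(pf), 8)
  # per-organoid rates vary around 0.8 (sd 0.08); binomial 99% bounds on top
  lims <- qbinom(c(0.005, 0.995), 50, c(0.5, 0.97)) / 50
  expect_true(all(pf$preserved_fraction >= lims[1] & pf$preserved_fraction <= lims[2]))
  expect_equal(mean(pf$preserved_fraction), 0.8, tolerance = 0.1)
})

test_that("zero damage gives 100% preservation everywhere", {
  tab <- generate_tile_table(n_organoids = 4, preservation_means = c(g = 1), target_r = 0, seed = 2)
  pf <- preservation_fraction(tab)
  expect_true(all(pf$preserved_fraction == 1))
})

test_that("decoupled generators give |R| < 0.3 in 95% of seeds at n = 50", {
  rs <- vapply(1:20, function(seed) {
    tab <- generate_tile_table(
      n_organoids = 50, n_tiles = 30,
      preservation_means = c(g = 0.6), target_r = 0, seed = seed
    )
    pf <- preservation_fraction(tab)
    pearson_r(pf$packing_density_um2, pf$preserved_fraction)
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.3), 0.95)
})
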