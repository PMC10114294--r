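toy_table <- function() {
  tibble::tibble(
    sample_group = "g",
    organoid_id = rep(c("o1", "o2"), c(10, 4)),
    tile_id = c(sprintf("t%02d", 1:10), sprintf("t%02d", 1:4)),
    damaged = c(rep(FALSE, 8), TRUE, TRUE, rep(TRUE, 4))
  )
}

test_that("preservation fractions are intact tiles over total tiles", {
  pf <- preservation_fraction(toy_table())
  expect_equal(pf$preserved_fraction[pf$organoid_id == "o1"], 0.8)
  expect_equal(pf$preserved_fraction[pf$organoid_id == "o2"], 0.0)
  expect_true(all(pf$preserved_fraction * pf$n_tiles == round(pf$preserved_fraction * pf$n_tiles)))
})

test_that("preservation is invariant to tile ordering and to table splitting", {
  tab <- generate_tile_table(n_organoids = 4, n_tiles = 20, seed = 9)
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(
    dplyr::arrange(preservation_fraction(tab), organoid_id),
    dplyr::arrange(preservation_fraction(shuffled), organoid_id)
  )
  halves <- dplyr::bind_rows(tab[seq(1, nrow(tab), 2), ], tab[seq(2, nrow(tab), 2), ])
  expect_equal(
    dplyr::arrange(preservation_fraction(halves), organoid_id),
    dplyr::arrange(preservation_fraction(tab), organoid_id)
  )
})

test_that("packing density is area per cell with its domain checks", {
  expect_equal(packing_density(5000, 50), 100)
  expect_equal(packing_density(123.4, 1), 123.4)
  expect_equal(packing_density(2 * 5000, 2 * 50), packing_density(5000, 50))
  expect_error(packing_density(0, 5), "area")
  expect_error(packing_density(10, 0), "n_cells")
})

test_that("box statistics follow the linear-interpolation quartile rule", {
  s <- group_box_stats(c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_equal(s$median, 0.6)
  expect_equal(s$min, 0.2)
  expect_equal(s$max, 1.0)
  expect_equal(s$q25, 0.4)
  expect_equal(s$q75, 0.8)
  single <- group_box_stats(0.7)
  expect_true(all(unlist(single[c("median", "q25", "q75", "min", "max")]) == 0.7))
  expect_error(group_box_stats(numeric(0)), "at least one")
})

test_that("uniform draws put q25/q75 near 0.25/0.75", {
  set.seed(8)
  s <- group_box_stats(runif(1000))
  expect_lt(abs(s$q25 - 0.25), 0.03)
  expect_lt(abs(s$q75 - 0.75), 0.03)
})

test_that("pearson_r matches its closed-form cases and affine invariance", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  set.seed(4)
  x <- rnorm(40)
  y <- rnorm(40)
  expect_equal(pearson_r(2 * x + 3, y), pearson_r(x, y))
  expect_equal(pearson_r(-2 * x + 3, y), -pearson_r(x, y))
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "variance")
})

test_that("programmed packing-preservation coupling is recovered within 0.15 at n = 50", {
  rs <- vapply(1:20, function(seed) {
    tab <- generate_tile_table(
      n_organoids = 50, n_tiles = 40,
      preservation_means = c(g = 0.6), target_r = 0.39, seed = seed
    )
    preservation_summary(tab)$pearson_r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.39), 0.15)
})

test_that("the preservation summary bundles per-group boxes and R", {
  tab <- generate_tile_table(n_organoids = 6, seed = 12)
  ps <- preservation_summary(tab)
  expect_equal(nrow(ps$per_group), 4)
  expect_true(all(c("median", "q25", "q75", "min", "max") %in% names(ps$per_group)))
  expect_true(ps$pearson_r >= -1 && ps$pearson_r <= 1)
  g <- glance(ps)
  expect_equal(g$n_organoids, 24)
})
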