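#' Specification for a synthetic organoid volume
#'
#' Describes a seeded synthetic multicellular label volume with known ground
#' truth, emulating the three cell-packing morphologies seen in patient-derived
#' organoid FIB-SEM acquisitions: a `monolayer` of cells around a large lumen
#' (lumina up to 60% of mature organoid volume), a `compact` packing with no
#' lumen, and a `mixed` body with several embedded lumina (up to ~15%).
#'
#' @param morphology `"monolayer"`, `"compact"` or `"mixed"`.
#' @param shape Voxel grid `(n_z, n_y, n_x)`.
#' @param spacing_nm Voxel spacing `(s_z, s_y, s_x)` in nm.
#' @param n_cells Number of cells.
#' @param lumen_fraction_target Lumen volume as a fraction of organoid volume,
#'   in `[0, 0.7]`. Defaults per morphology: monolayer 0.6, mixed 0.15,
#'   compact 0.
#' @param nucleus_fraction Nucleus volume as a fraction of its cell's volume
#'   (default 0.25).
#' @param nucleus_axes_ratio Relative ellipsoid semi-axes of nuclei (z, y, x);
#'   `c(1, 1, 1)` gives spherical nuclei, elongated ratios lower sphericity.
#' @param n_junctions Number of cell-junction objects to scatter on cell-cell
#'   interfaces.
#' @param junction_nn_scale_um Target 90th percentile of the junction
#'   nearest-neighbour distance (um), achieved by tuning the occupied
#'   interface patch; `NA` (default) places junctions uniformly on the whole
#'   interface.
#' @param junction_radius_um Radius of each junction object (um).
#' @param fiber_density_um2 Actin-bundle fibers per um^2 of lumen surface.
#' @param fiber_length_um Fiber length (um); microvillar actin bundles appear
#'   as roughly 1-um fibers.
#' @param mito_volume_median_um3,mito_volume_sigma Log-normal mitochondrial
#'   volume distribution (median in um^3, log-sd).
#' @param mito_per_um3 Mitochondria per um^3 of cell volume.
#' @param outlier_mito Optional `c(count, factor)`: plant `count` mitochondria
#'   with `factor` times the median volume.
#' @param seed Integer seed; the whole scene is a deterministic function of
#'   the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(morphology = c("monolayer", "compact", "mixed"),
                           shape = c(96, 112, 112),
                           spacing_nm = c(200, 150, 150),
                           n_cells = 12,
                           lumen_fraction_target = NULL,
                           nucleus_fraction = 0.25,
                           nucleus_axes_ratio = c(1, 1, 1),
                           n_junctions = 400,
                           junction_nn_scale_um = NA,
                           junction_radius_um = 0.15,
                           fiber_density_um2 = 0.5,
                           fiber_length_um = 1.0,
                           mito_volume_median_um3 = 0.25,
                           mito_volume_sigma = 0.6,
                           mito_per_um3 = 0.03,
                           outlier_mito = NULL,
                           seed = 1) {
  morphology <- match.arg(morphology)
  if (is.null(lumen_fraction_target)) {
    lumen_fraction_target <- switch(morphology, monolayer = 0.6, mixed = 0.15, compact = 0)
  }
  if (lumen_fraction_target < 0 || lumen_fraction_target > 0.7) {
    stop("lumen_fraction_target must be in [0, 0.7]", call. = FALSE)
  }
  if (morphology == "compact" && lumen_fraction_target > 0) {
    stop("compact morphology has no lumen; set lumen_fraction_target = 0", call. = FALSE)
  }
  if (n_cells < 1 || n_junctions < 0) stop("counts must be non-negative (n_cells >= 1)", call. = FALSE)
  spec <- list(
    morphology = morphology, shape = as.integer(shape), spacing_nm = as.numeric(spacing_nm),
    n_cells = as.integer(n_cells), lumen_fraction_target = lumen_fraction_target,
    nucleus_fraction = nucleus_fraction, nucleus_axes_ratio = as.numeric(nucleus_axes_ratio),
    n_junctions = as.integer(n_junctions), junction_nn_scale_um = junction_nn_scale_um,
    junction_radius_um = junction_radius_um, fiber_density_um2 = fiber_density_um2,
    fiber_length_um = fiber_length_um, mito_volume_median_um3 = mito_volume_median_um3,
    mito_volume_sigma = mito_volume_sigma, mito_per_um3 = mito_per_um3,
    outlier_mito = outlier_mito, seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  spec
}

with_spec_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# physical voxel-center coordinate axes (um), zyx
axis_coords_um <- function(shape, spacing_nm) {
  sp <- spacing_nm / 1000
  lapply(1:3, function(ax) (seq_len(shape[ax]) - 0.5) * sp[ax])
}

# mask of an ellipsoid given center (zyx um) and semi-axes (zyx um)
ellipsoid_mask <- function(shape, spacing_nm, center_um, semi_um) {
  ax <- axis_coords_um(shape, spacing_nm)
  dz2 <- ((ax[[1]] - center_um[1]) / semi_um[1])^2
  dy2 <- ((ax[[2]] - center_um[2]) / semi_um[2])^2
  dx2 <- ((ax[[3]] - center_um[3]) / semi_um[3])^2
  outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
}

#' Generate a synthetic organoid scene
#'
#' Builds, deterministically from a [synthetic_spec()], a set of co-registered
#' label volumes: `cells` (Voronoi-partitioned), `lumen`, `nuclei` (one
#' ellipsoid per cell at the requested volume fraction), `mitochondria`
#' (log-normal volumes, optional planted giants), `junctions` (hard-core point
#' objects on cell-cell interfaces) and `actin_bundles` (fibers on the lumen
#' surface, oriented along the local surface normal). Ground-truth parameters
#' of every generated object are returned alongside.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_scene`: list of [labeled_volume()]s plus
#'   `ground_truth` (a list of tibbles) and the spec.
#' @export
generate_organoid <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_spec_seed(spec$seed, {
    shape <- spec$shape
    sp <- spec$spacing_nm
    sp_um <- sp / 1000
    vox_um3 <- prod(sp_um)
    extent <- shape * sp_um
    center <- extent / 2
    organoid_semi <- 0.44 * extent

    organoid <- ellipsoid_mask(shape, sp, center, organoid_semi)
    n_org <- sum(organoid)
    # feasibility: each cell needs room for at least ~a 1.5 um sphere
    min_cell_vox <- ceiling((4 / 3) * pi * 1.5^3 / vox_um3)
    if (spec$n_cells * min_cell_vox > n_org * (1 - spec$lumen_fraction_target)) {
      stop(sprintf(
        "infeasible packing: %d cells need >= %d voxels but only %.0f are available",
        spec$n_cells, spec$n_cells * min_cell_vox,
        n_org * (1 - spec$lumen_fraction_target)
      ), call. = FALSE)
    }

    # ---- lumen ----------------------------------------------------------
    lumen <- array(FALSE, shape)
    lumen_truth <- tibble::tibble()
    if (spec$lumen_fraction_target > 0) {
      if (spec$morphology == "monolayer") {
        lumen_centers <- matrix(center, nrow = 1)
        base_semi <- matrix(organoid_semi, nrow = 1)
      } else {
        k <- sample(2:4, 1)
        u <- matrix(stats::runif(3 * k, -0.45, 0.45), ncol = 3)
        lumen_centers <- sweep(u * 2, 2, organoid_semi * 0.5, `*`)
        lumen_centers <- sweep(lumen_centers, 2, center, `+`)
        base_semi <- matrix(rep(organoid_semi * 0.35, k), ncol = 3, byrow = TRUE) *
          stats::runif(k, 0.7, 1.3)
      }
      # scale all lumina jointly so the achieved fraction hits the target
      lum_at <- function(s) {
        m <- array(FALSE, shape)
        for (i in seq_len(nrow(lumen_centers))) {
          m <- m | ellipsoid_mask(shape, sp, lumen_centers[i, ], pmin(base_semi[i, ] * s, organoid_semi * 0.92))
        }
        m & organoid
      }
      lo <- 0.05
      hi <- 1.0
      for (iter in 1:24) {
        mid <- (lo + hi) / 2
        frac <- sum(lum_at(mid)) / n_org
        if (frac < spec$lumen_fraction_target) lo <- mid else hi <- mid
        if (abs(frac - spec$lumen_fraction_target) < 0.004) break
      }
      lumen <- lum_at((lo + hi) / 2)
      lumen_truth <- tibble::tibble(
        id = seq_len(nrow(lumen_centers)),
        center_x_um = lumen_centers[, 3], center_y_um = lumen_centers[, 2],
        center_z_um = lumen_centers[, 1]
      )
    }

    cell_space <- organoid & !lumen

    # ---- cells: Voronoi partition of the cell space ---------------------
    seeds <- cell_seed_points(spec, center, organoid_semi, lumen, sp_um)
    cells <- voronoi_assign(cell_space, seeds, shape, sp)
    cell_truth <- tibble::tibble(
      id = seq_len(spec$n_cells),
      seed_x_um = seeds[, 3], seed_y_um = seeds[, 2], seed_z_um = seeds[, 1],
      voxel_count = as.integer(tabulate(cells[cells > 0L], nbins = spec$n_cells))
    )
    if (any(cell_truth$voxel_count == 0)) {
      stop("infeasible packing: a cell received no voxels; reduce n_cells", call. = FALSE)
    }

    # ---- nuclei ---------------------------------------------------------
    nuc <- generate_nuclei(cells, spec, shape, sp)

    # ---- mitochondria ---------------------------------------------------
    mito <- generate_mitochondria(cells, nuc$labels, spec, shape, sp)

    # ---- interfaces and junctions --------------------------------------
    interface <- interface_mask(cells)
    junctions_vol <- NULL
    junction_truth <- tibble::tibble()
    if (spec$n_junctions > 0) {
      jp <- place_junctions(spec, interface, shape, sp)
      junctions_vol <- jp$volume
      junction_truth <- jp$truth
    } else {
      junctions_vol <- array(0L, shape)
    }

    # ---- actin bundles on the lumen surface -----------------------------
    actin <- generate_actin(lumen, cells, spec, shape, sp)

    lv <- function(arr, nm) labeled_volume(to_int_array(arr, shape), sp, nm)
    scene <- list(
      cells = lv(cells, "cells"),
      lumen = lv(lumen, "lumen"),
      nuclei = lv(nuc$labels, "nuclei"),
      mitochondria = lv(mito$labels, "mitochondria"),
      junctions = lv(junctions_vol, "cell junctions"),
      actin_bundles = lv(actin$labels, "actin bundles"),
      interface = lv(interface, "cell-cell interface"),
      ground_truth = list(
        cells = cell_truth, lumen = lumen_truth, nuclei = nuc$truth,
        mitochondria = mito$truth, junctions = junction_truth, actin = actin$truth,
        organoid_voxels = n_org,
        lumen_fraction = sum(lumen) / n_org
      ),
      spec = spec
    )
    class(scene) <- "synthetic_scene"
    scene
  })
}

to_int_array <- function(x, shape) {
  a <- array(as.integer(x), shape)
  a
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %s morphology, %d cells, seed %d\n",
    x$spec$morphology, x$spec$n_cells, x$spec$seed
  ))
  cat(sprintf(
    "  grid %s voxels at %s nm; lumen fraction %.3f\n",
    paste(x$spec$shape, collapse = "x"), paste(x$spec$spacing_nm, collapse = "x"),
    x$ground_truth$lumen_fraction
  ))
  invisible(x)
}

cell_seed_points <- function(spec, center, organoid_semi, lumen, sp_um) {
  n <- spec$n_cells
  if (spec$morphology == "monolayer") {
    # seeds on a mid-shell between lumen surface and organoid surface
    dirs <- fibonacci_sphere(n)
    dirs <- dirs[sample.int(n), , drop = FALSE]
    jitter <- matrix(stats::rnorm(3 * n, 0, 0.06), ncol = 3)
    radial <- stats::runif(n, 0.78, 0.88)
    pts <- sweep((dirs + jitter) * radial, 2, organoid_semi, `*`)
    sweep(pts, 2, center, `+`)
  } else {
    # uniform seeds in the cell space with a soft minimum separation
    target_sep <- 0.7 * (prod(2 * organoid_semi) / n)^(1 / 3)
    cand <- matrix(stats::runif(3 * n * 60, -1, 1), ncol = 3)
    cand <- cand[rowSums(cand^2) <= 1, , drop = FALSE]
    cand <- sweep(cand, 2, organoid_semi * 0.93, `*`)
    cand <- sweep(cand, 2, center, `+`)
    keep <- .hardcore_sample(cand, target_sep, n)
    if (length(keep) < n) keep <- c(keep, setdiff(seq_len(nrow(cand)), keep))[seq_len(n)]
    cand[keep, , drop = FALSE]
  }
}

voronoi_assign <- function(cell_space, seeds, shape, spacing_nm) {
  ax <- axis_coords_um(shape, spacing_nm)
  out <- array(0L, shape)
  idx <- which(cell_space)
  if (length(idx) == 0) return(out)
  coord <- arrayInd(idx, shape)
  pz <- ax[[1]][coord[, 1]]
  py <- ax[[2]][coord[, 2]]
  px <- ax[[3]][coord[, 3]]
  best <- rep.int(1L, length(idx))
  bestd <- (pz - seeds[1, 1])^2 + (py - seeds[1, 2])^2 + (px - seeds[1, 3])^2
  for (k in seq_len(nrow(seeds))[-1]) {
    d <- (pz - seeds[k, 1])^2 + (py - seeds[k, 2])^2 + (px - seeds[k, 3])^2
    upd <- d < bestd
    best[upd] <- k
    bestd[upd] <- d[upd]
  }
  out[idx] <- best
  out
}

# voxels of a cell adjacent (6-connectivity) to a different cell
interface_mask <- function(cells) {
  m <- array(FALSE, dim(cells))
  for (ax in 1:3) {
    for (by in c(-1L, 1L)) {
      nb <- shift_array(cells, ax, by)
      m <- m | (cells > 0L & nb > 0L & nb != cells)
    }
  }
  m
}

generate_nuclei <- function(cells, spec, shape, spacing_nm) {
  sp_um <- spacing_nm / 1000
  vox_um3 <- prod(sp_um)
  ax <- axis_coords_um(shape, spacing_nm)
  labels <- array(0L, shape)
  rows <- vector("list", spec$n_cells)
  ratio <- spec$nucleus_axes_ratio / prod(spec$nucleus_axes_ratio)^(1 / 3)
  for (cid in seq_len(spec$n_cells)) {
    idx <- which(cells == cid)
    coord <- arrayInd(idx, shape)
    ctr <- c(
      mean(ax[[1]][coord[, 1]]), mean(ax[[2]][coord[, 2]]), mean(ax[[3]][coord[, 3]])
    )
    # pull the center to the nearest cell voxel in case the centroid is outside
    d2 <- (ax[[1]][coord[, 1]] - ctr[1])^2 + (ax[[2]][coord[, 2]] - ctr[2])^2 +
      (ax[[3]][coord[, 3]] - ctr[3])^2
    nearest <- coord[which.min(d2), ]
    ctr <- c(ax[[1]][nearest[1]], ax[[2]][nearest[2]], ax[[3]][nearest[3]])
    target_vox <- spec$nucleus_fraction * length(idx)
    base_r <- (target_vox * vox_um3 / ((4 / 3) * pi))^(1 / 3)
    # bisect the scale so the clipped nucleus hits the target fraction
    nuc_at <- function(s) {
      semi <- pmax(base_r * s * ratio, sp_um)
      bb <- bbox_around(ctr, semi, shape, sp_um)
      sub <- ellipsoid_mask_bbox(bb, spacing_nm, ctr, semi)
      list(bb = bb, mask = sub & (cells[bb$z, bb$y, bb$x, drop = FALSE] == cid))
    }
    lo <- 0.5
    hi <- 3.0
    for (it in 1:18) {
      mid <- (lo + hi) / 2
      got <- sum(nuc_at(mid)$mask)
      if (got < target_vox) lo <- mid else hi <- mid
      if (abs(got - target_vox) <= max(2, 0.01 * target_vox)) break
    }
    res <- nuc_at((lo + hi) / 2)
    sel <- array(FALSE, shape)
    sel[res$bb$z, res$bb$y, res$bb$x] <- res$mask
    labels[sel] <- cid
    semi <- base_r * ((lo + hi) / 2) * ratio
    rows[[cid]] <- tibble::tibble(
      id = cid, parent_cell = cid,
      center_x_um = ctr[3], center_y_um = ctr[2], center_z_um = ctr[1],
      semi_z_um = semi[1], semi_y_um = semi[2], semi_x_um = semi[3],
      target_fraction = spec$nucleus_fraction,
      achieved_voxels = sum(res$mask)
    )
  }
  list(labels = labels, truth = dplyr::bind_rows(rows))
}

bbox_around <- function(center_um, semi_um, shape, sp_um) {
  lo <- pmax(1L, floor((center_um - semi_um) / sp_um - 1))
  hi <- pmin(shape, ceiling((center_um + semi_um) / sp_um + 1))
  list(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
}

ellipsoid_mask_bbox <- function(bb, spacing_nm, center_um, semi_um) {
  sp <- spacing_nm / 1000
  dz2 <- (((bb$z - 0.5) * sp[1] - center_um[1]) / semi_um[1])^2
  dy2 <- (((bb$y - 0.5) * sp[2] - center_um[2]) / semi_um[2])^2
  dx2 <- (((bb$x - 0.5) * sp[3] - center_um[3]) / semi_um[3])^2
  outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
}

generate_mitochondria <- function(cells, nuclei, spec, shape, spacing_nm) {
  sp_um <- spacing_nm / 1000
  vox_um3 <- prod(sp_um)
  labels <- array(0L, shape)
  rows <- list()
  mid <- 0L
  n_out <- if (is.null(spec$outlier_mito)) 0L else as.integer(spec$outlier_mito[1])
  out_factor <- if (is.null(spec$outlier_mito)) 1 else spec$outlier_mito[2]
  mito_ratio <- c(1, 1, 2.2) # elongated along x
  mito_ratio <- mito_ratio / prod(mito_ratio)^(1 / 3)
  paint <- function(sub, bb, id) {
    block <- labels[bb$z, bb$y, bb$x, drop = FALSE]
    block[sub] <- id
    labels[bb$z, bb$y, bb$x] <<- block
  }
  for (cid in seq_len(spec$n_cells)) {
    free_idx <- which(cells == cid & nuclei == 0L)
    if (length(free_idx) == 0) next
    cell_vol_um3 <- sum(cells == cid) * vox_um3
    # planted giants first: their ellipsoid scale is bisected so the clipped,
    # voxelised object actually reaches the requested multiple of the median
    if (n_out > 0) {
      n_out <- n_out - 1L
      mid <- mid + 1L
      coord <- arrayInd(free_idx, shape)
      ctr_free <- colMeans(coord)
      ctr <- (coord[which.min(rowSums(sweep(coord, 2, ctr_free, `-`)^2)), ] - 0.5) * sp_um
      target_vox <- out_factor * spec$mito_volume_median_um3 / vox_um3
      base_r <- (target_vox * vox_um3 / ((4 / 3) * pi))^(1 / 3)
      giant_at <- function(s) {
        semi <- pmax(base_r * s, sp_um * 0.75)
        bb <- bbox_around(ctr, semi, shape, sp_um)
        sub <- ellipsoid_mask_bbox(bb, spacing_nm, ctr, semi) &
          (cells[bb$z, bb$y, bb$x, drop = FALSE] == cid) &
          (nuclei[bb$z, bb$y, bb$x, drop = FALSE] == 0L) &
          (labels[bb$z, bb$y, bb$x, drop = FALSE] == 0L)
        list(bb = bb, sub = sub)
      }
      lo <- 0.8
      hi <- 4
      for (it in 1:16) {
        s <- (lo + hi) / 2
        got <- sum(giant_at(s)$sub)
        if (got < target_vox) lo <- s else hi <- s
        if (abs(got - target_vox) <= max(2, 0.01 * target_vox)) break
      }
      res <- giant_at((lo + hi) / 2)
      paint(res$sub, res$bb, mid)
      rows[[mid]] <- tibble::tibble(
        id = mid, parent_cell = cid,
        target_volume_um3 = out_factor * spec$mito_volume_median_um3,
        planted_outlier = TRUE,
        center_x_um = ctr[3], center_y_um = ctr[2], center_z_um = ctr[1],
        achieved_voxels = sum(res$sub)
      )
      free_idx <- which(cells == cid & nuclei == 0L & labels == 0L)
    }
    n_mito <- max(1L, stats::rpois(1, spec$mito_per_um3 * cell_vol_um3))
    vols <- stats::rlnorm(n_mito,
      meanlog = log(spec$mito_volume_median_um3),
      sdlog = spec$mito_volume_sigma
    )
    centers <- arrayInd(sample(free_idx, min(n_mito, length(free_idx))), shape)
    for (i in seq_len(nrow(centers))) {
      mid <- mid + 1L
      ctr <- (centers[i, ] - 0.5) * sp_um
      r <- (vols[i] / ((4 / 3) * pi))^(1 / 3)
      semi <- pmax(r * mito_ratio, sp_um * 0.75)
      bb <- bbox_around(ctr, semi, shape, sp_um)
      sub <- ellipsoid_mask_bbox(bb, spacing_nm, ctr, semi)
      sub <- sub & (cells[bb$z, bb$y, bb$x, drop = FALSE] == cid) &
        (nuclei[bb$z, bb$y, bb$x, drop = FALSE] == 0L) &
        (labels[bb$z, bb$y, bb$x, drop = FALSE] == 0L)
      paint(sub, bb, mid)
      rows[[mid]] <- tibble::tibble(
        id = mid, parent_cell = cid, target_volume_um3 = vols[i],
        planted_outlier = FALSE,
        center_x_um = ctr[3], center_y_um = ctr[2], center_z_um = ctr[1],
        achieved_voxels = sum(sub)
      )
    }
  }
  list(labels = labels, truth = dplyr::bind_rows(rows))
}

generate_actin <- function(lumen, cells, spec, shape, spacing_nm) {
  sp_um <- spacing_nm / 1000
  labels <- array(0L, shape)
  if (!any(lumen) || spec$fiber_density_um2 <= 0) {
    return(list(labels = labels, truth = tibble::tibble()))
  }
  # lumen-facing cell voxels
  surf <- array(FALSE, shape)
  for (ax in 1:3) {
    for (by in c(-1L, 1L)) {
      surf <- surf | (cells > 0L & shift_array(lumen, ax, by))
    }
  }
  idx <- which(surf)
  if (length(idx) == 0) {
    return(list(labels = labels, truth = tibble::tibble()))
  }
  # surface area proxy: count of exposed faces times mean face area
  area_um2 <- length(idx) * mean(c(
    sp_um[1] * sp_um[2], sp_um[1] * sp_um[3], sp_um[2] * sp_um[3]
  ))
  n_fib <- max(0L, stats::rpois(1, spec$fiber_density_um2 * area_um2))
  n_fib <- min(n_fib, length(idx))
  if (n_fib == 0) {
    return(list(labels = labels, truth = tibble::tibble()))
  }
  coord <- arrayInd(idx, shape)
  pick <- sample(length(idx), n_fib)
  lum_idx <- which(lumen)
  lum_coord <- arrayInd(lum_idx, shape)
  lum_ctr_um <- colMeans(sweep(lum_coord - 0.5, 2, sp_um, `*`))
  rows <- vector("list", n_fib)
  n_steps <- max(2L, ceiling(spec$fiber_length_um / min(sp_um)))
  for (i in seq_len(n_fib)) {
    start_idx <- coord[pick[i], ]
    start_um <- (start_idx - 0.5) * sp_um
    nrm <- start_um - lum_ctr_um # outward normal proxy: away from lumen center
    nrm <- nrm / sqrt(sum(nrm^2))
    step_um <- spec$fiber_length_um / n_steps
    pos <- start_um
    for (s in seq_len(n_steps)) {
      vi <- pmax(1L, pmin(shape, as.integer(ceiling(pos / sp_um))))
      if (cells[vi[1], vi[2], vi[3]] > 0L) labels[vi[1], vi[2], vi[3]] <- i
      pos <- pos + nrm * step_um
    }
    rows[[i]] <- tibble::tibble(
      id = i,
      start_x_um = start_um[3], start_y_um = start_um[2], start_z_um = start_um[1],
      dir_x = nrm[3], dir_y = nrm[2], dir_z = nrm[1],
      length_um = spec$fiber_length_um
    )
  }
  list(labels = labels, truth = dplyr::bind_rows(rows))
}

#' Generate a cell-junction point process on an interface
#'
#' Places `n_junctions` spherical objects (radius `junction_radius_um`) with
#' centers on interface voxels, under a hard-core constraint: no two centers
#' closer than twice the junction radius. If `junction_nn_scale_um` is set,
#' the process is confined to a contiguous interface patch whose size is
#' tuned by bisection until the empirical 90th percentile of
#' nearest-neighbour distances matches the requested scale (a Matern-type
#' construction: clustering comes from patch confinement, the hard core from
#' thinning). An explicit `centroids_um` override (x, y, z in um) bypasses
#' placement entirely.
#'
#' @param spec A [synthetic_spec()] (fields `n_junctions`,
#'   `junction_nn_scale_um`, `junction_radius_um`, `seed` are used).
#' @param interface_mask A [labeled_volume()] (nonzero = interface voxels).
#' @param centroids_um Optional explicit n x 3 matrix of (x, y, z) centers.
#' @return A list: `volume` (labelled junction objects), `truth` (tibble of
#'   programmed centers), `patch_fraction` (tuned interface fraction).
#' @export
generate_junction_process <- function(spec, interface_mask, centroids_um = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  arr <- if (inherits(interface_mask, "labeled_volume")) interface_mask else NULL
  if (is.null(arr)) stop("interface_mask must be a labeled_volume", call. = FALSE)
  shape <- dim(arr)
  sp <- spacing_nm(arr)
  with_spec_seed(spec$seed + 1L, {
    res <- place_junctions(spec, unclass(arr) > 0L, shape, sp, centroids_um)
    res$volume <- labeled_volume(res$volume, sp, "cell junctions")
    res
  })
}

place_junctions <- function(spec, interface, shape, spacing_nm, centroids_um = NULL) {
  sp_um <- spacing_nm / 1000
  n <- spec$n_junctions
  if (!is.null(centroids_um)) {
    ctr_zyx <- cbind(centroids_um[, 3], centroids_um[, 2], centroids_um[, 1])
    return(paint_junctions(ctr_zyx, spec$junction_radius_um, shape, spacing_nm))
  }
  idx <- which(interface)
  if (length(idx) == 0) stop("interface mask is empty", call. = FALSE)
  coord_um <- sweep(arrayInd(idx, shape) - 0.5, 2, sp_um, `*`)
  rmin <- 2 * spec$junction_radius_um
  ord_all <- sample.int(nrow(coord_um))

  sample_patch <- function(fraction) {
    if (fraction >= 1) {
      ids <- ord_all
    } else {
      anchor <- coord_um[ord_all[1], ]
      d2 <- (coord_um[, 1] - anchor[1])^2 + (coord_um[, 2] - anchor[2])^2 +
        (coord_um[, 3] - anchor[3])^2
      cut <- stats::quantile(d2, fraction, type = 7)
      inpatch <- which(d2 <= cut)
      # preference order: the global shuffled order restricted to the patch
      ids <- intersect(ord_all, inpatch)
    }
    sub <- coord_um[ids, , drop = FALSE]
    keep <- .hardcore_sample(sub, rmin, n)
    sub[keep, , drop = FALSE]
  }

  if (is.na(spec$junction_nn_scale_um)) {
    pts <- sample_patch(1)
    if (nrow(pts) < n) {
      stop(sprintf(
        "interface cannot hold %d junctions at hard-core %.3f um (placed %d)",
        n, rmin, nrow(pts)
      ), call. = FALSE)
    }
    out <- paint_junctions(pts, spec$junction_radius_um, shape, spacing_nm)
    out$patch_fraction <- 1
    return(out)
  }

  q90 <- function(pts) {
    nn <- .nn_scan(pts)
    stats::quantile(nn$nn_distance, 0.9, type = 7, names = FALSE)
  }
  full <- sample_patch(1)
  if (nrow(full) < n) {
    stop(sprintf(
      "interface cannot hold %d junctions at hard-core %.3f um (placed %d)",
      n, rmin, nrow(full)
    ), call. = FALSE)
  }
  q_full <- q90(full)
  if (q_full < spec$junction_nn_scale_um * 0.98) {
    stop(sprintf(
      paste0(
        "requested 90th-percentile NN distance %.3f um exceeds what the whole ",
        "interface allows (%.3f um at n = %d); enlarge the interface or reduce n_junctions"
      ),
      spec$junction_nn_scale_um, q_full, n
    ), call. = FALSE)
  }
  lo <- 0.02
  hi <- 1
  pts <- full
  for (it in 1:22) {
    mid <- (lo + hi) / 2
    cand <- sample_patch(mid)
    if (nrow(cand) < n) {
      lo <- mid
      next
    }
    q <- q90(cand)
    if (abs(q / spec$junction_nn_scale_um - 1) < 0.015) {
      pts <- cand
      lo <- hi <- mid
      break
    }
    if (q > spec$junction_nn_scale_um) hi <- mid else lo <- mid
    pts <- cand
  }
  out <- paint_junctions(pts, spec$junction_radius_um, shape, spacing_nm)
  out$patch_fraction <- (lo + hi) / 2
  out
}

paint_junctions <- function(ctr_zyx_um, radius_um, shape, spacing_nm) {
  sp_um <- spacing_nm / 1000
  vol <- array(0L, shape)
  n <- nrow(ctr_zyx_um)
  for (i in seq_len(n)) {
    ctr <- ctr_zyx_um[i, ]
    semi <- rep(max(radius_um, max(sp_um) * 0.51), 3)
    bb <- bbox_around(ctr, semi, shape, sp_um)
    sub <- ellipsoid_mask_bbox(bb, spacing_nm, ctr, semi)
    # guarantee at least the center voxel
    block <- vol[bb$z, bb$y, bb$x, drop = FALSE]
    block[sub & block == 0L] <- i
    vol[bb$z, bb$y, bb$x] <- block
    vi <- pmax(1L, pmin(shape, as.integer(ceiling(ctr / sp_um))))
    if (vol[vi[1], vi[2], vi[3]] == 0L) vol[vi[1], vi[2], vi[3]] <- i
  }
  truth <- tibble::tibble(
    id = seq_len(n),
    center_x_um = ctr_zyx_um[, 3], center_y_um = ctr_zyx_um[, 2], center_z_um = ctr_zyx_um[, 1]
  )
  list(volume = vol, truth = truth)
}

#' Generate a synthetic tile-score table
#'
#' Emulates the manual TEM tile scoring: per organoid, `n_tiles` tiles are
#' drawn as independent Bernoulli trials at the organoid's damage rate; the
#' organoid's damage rate is its group mean plus noise coupled to its packing
#' density (area per cell) so that preservation and packing correlate with a
#' programmable asymptotic Pearson R. Defaults reproduce the study's
#' conditions: group preservation medians around 0.83 (compact colorectal
#' organoids), 0.75 (breast-cancer spheroids), 0.20 (mammary-gland organoids
#' with large lumina) and 0.77 (with cryo-protectants), and an asymptotic
#' packing-preservation correlation of 0.39.
#'
#' @param n_organoids Organoids per group.
#' @param n_tiles Tiles scored per organoid.
#' @param preservation_means Named per-group mean preserved fractions.
#' @param target_r Asymptotic Pearson correlation between packing density
#'   (um^2/cell) and preserved fraction across organoids (applies within
#'   groups; 0 decouples them).
#' @param seed Integer seed.
#' @return A tibble in the [read_tile_scores()] schema (tile rows with
#'   `organoid_area` and `n_cells` on every row of an organoid).
#' @export
generate_tile_table <- function(n_organoids = 8, n_tiles = 50,
                                preservation_means = c(
                                  colon = 0.83, bt474 = 0.75,
                                  mouse = 0.20, cryoprotectant = 0.77
                                ),
                                target_r = 0.39,
                                seed = 1) {
  if (any(preservation_means < 0 | preservation_means > 1)) {
    stop("preservation means must be fractions in [0, 1]", call. = FALSE)
  }
  if (abs(target_r) > 0.99) stop("|target_r| must be <= 0.99", call. = FALSE)
  with_spec_seed(seed, {
    groups <- names(preservation_means)
    if (is.null(groups)) groups <- paste0("group_", seq_along(preservation_means))
    rows <- list()
    sd_pres <- 0.08
    for (g in seq_along(preservation_means)) {
      mu <- preservation_means[g]
      # target_r is the coupling to the OBSERVED preserved fraction, which the
      # binomial tile sampling attenuates; inflate the latent coupling by the
      # classical attenuation factor so the observed correlation matches
      sd_binom <- sqrt(max(mu * (1 - mu), 1e-8) / n_tiles)
      r_latent <- max(-0.99, min(0.99, target_r * sqrt(1 + sd_binom^2 / sd_pres^2)))
      for (o in seq_len(n_organoids)) {
        # latent preservation propensity and correlated packing density
        zp <- stats::rnorm(1)
        zq <- r_latent * zp + sqrt(1 - r_latent^2) * stats::rnorm(1)
        # degenerate rates stay degenerate: a damage rate of exactly 0 (or 1)
        # must not acquire noise
        pres <- if (mu >= 1) 1 else if (mu <= 0) 0 else min(1, max(0, mu + sd_pres * zp))
        packing <- 120 + 35 * zq # um^2 per cell, ~densest at low packing
        area <- stats::runif(1, 3000, 9000)
        n_cells <- max(1L, round(area / packing))
        organoid_id <- sprintf("%s_%02d", groups[g], o)
        damaged <- stats::runif(n_tiles) > pres
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_group = groups[g],
          organoid_id = organoid_id,
          tile_id = sprintf("t%03d", seq_len(n_tiles)),
          damaged = damaged,
          organoid_area = area,
          n_cells = n_cells
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
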