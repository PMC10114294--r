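# Independent oracles and fixture builders shared across the test files.
# These deliberately avoid the package's own code paths: connected components
# go through igraph on the voxel adjacency graph, nearest neighbours through a
# plain double loop, density nodes through vectorised distance tests.

# digitized ball mask centered at the array center plus a sub-voxel offset
ball_array <- function(r_vox, offset = c(0.3, 0.17, 0.41), margin = 4) {
  n <- 2 * ceiling(r_vox) + 2 * margin + 1
  c0 <- (n + 1) / 2
  vz <- seq_len(n) - c0 - offset[1]
  vy <- seq_len(n) - c0 - offset[2]
  vx <- seq_len(n) - c0 - offset[3]
  array(as.integer(outer(outer(vz^2, vy^2, `+`), vx^2, `+`) <= r_vox^2), c(n, n, n))
}

box_array <- function(a, b, c3, margin = 2) {
  arr <- array(0L, c(a + 2 * margin, b + 2 * margin, c3 + 2 * margin))
  arr[margin + seq_len(a), margin + seq_len(b), margin + seq_len(c3)] <- 1L
  arr
}

# digitized ellipsoid with semi-axes (um, zyx) at given spacing (nm, zyx)
ellipsoid_volume <- function(semi_um, spacing_nm, class_name = "ellipsoid") {
  sp_um <- spacing_nm / 1000
  half <- ceiling(semi_um / sp_um) + 3
  n <- 2 * half + 1
  ctr <- (n / 2) * sp_um
  vz <- ((seq_len(n[1]) - 0.5) * sp_um[1] - ctr[1]) / semi_um[1]
  vy <- ((seq_len(n[2]) - 0.5) * sp_um[2] - ctr[2]) / semi_um[2]
  vx <- ((seq_len(n[3]) - 0.5) * sp_um[3] - ctr[3]) / semi_um[3]
  arr <- array(as.integer(outer(outer(vz^2, vy^2, `+`), vx^2, `+`) <= 1), n)
  labeled_volume(arr, spacing_nm, class_name)
}

# closed-form surface area of a prolate spheroid with semi-axes (a, b, b), a > b
prolate_area <- function(a, b) {
  e <- sqrt(1 - b^2 / a^2)
  2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
}

# independent connected-components oracle via igraph on the adjacency graph
cc_oracle <- function(arr, connectivity) {
  d <- dim(arr)
  idx <- which(arr > 0L)
  if (length(idx) == 0) return(array(0L, d))
  pos <- arrayInd(idx, d)
  key <- function(p) (p[, 1] - 1) + d[1] * ((p[, 2] - 1) + d[2] * (p[, 3] - 1))
  id_of <- integer(prod(d))
  id_of[idx] <- seq_along(idx)
  shifts <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    manh <- abs(dz) + abs(dy) + abs(dx)
    if (connectivity == 6 && manh != 1) next
    shifts[[length(shifts) + 1]] <- c(dz, dy, dx)
  }
  edges <- list()
  for (s in shifts) {
    nb <- sweep(pos, 2, s, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- key(nb[ok, , drop = FALSE]) + 1
    nb_id <- id_of[lin]
    src <- which(ok)
    same <- nb_id > 0 & arr[lin] == arr[idx[src]]
    if (any(same)) edges[[length(edges) + 1]] <- cbind(src[same], nb_id[same])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- array(0L, d)
  out[idx] <- comp
  out
}

# partition signature invariant to label permutation: sorted voxel groups
cc_signature <- function(lab_arr) {
  idx <- which(lab_arr > 0L)
  grp <- split(idx, lab_arr[idx])
  unname(grp[order(vapply(grp, min, numeric(1)))])
}

# plain-R nearest-neighbour oracle (double loop)
nn_oracle <- function(pts) {
  n <- nrow(pts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      dd <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (dd < best) best <- dd
    }
    out[i] <- best
  }
  out
}

# density-node oracle: fully vectorised voxel-center distance test
density_node_oracle <- function(mask_arr, spacing_um, node_zyx, radius) {
  d <- dim(mask_arr)
  pos <- arrayInd(seq_len(prod(d)), d)
  ctr <- sweep(pos - 0.5, 2, spacing_um, `*`)
  d2 <- (ctr[, 1] - node_zyx[1])^2 + (ctr[, 2] - node_zyx[2])^2 + (ctr[, 3] - node_zyx[3])^2
  inside <- d2 <= radius^2
  c(occupied = sum(inside & as.logical(mask_arr)), in_bounds = sum(inside))
}

random_label_volume <- function(shape, p_fg = 0.25, n_classes = 1, seed = 1,
                                spacing_nm = c(40, 30, 30)) {
  set.seed(seed)
  arr <- array(0L, shape)
  fg <- stats::runif(prod(shape)) < p_fg
  arr[fg] <- sample.int(n_classes, sum(fg), replace = TRUE)
  labeled_volume(arr, spacing_nm, "random")
}

make_instances_from_points <- function(centroids_um, spacing_nm = c(100, 100, 100),
                                       pad_um = 1) {
  # build a volume with single-voxel objects at the requested centers
  sp_um <- spacing_nm / 1000
  mx <- apply(centroids_um, 2, max)
  shape <- ceiling((mx + pad_um) / sp_um[c(3, 2, 1)])[c(3, 2, 1)] + 1L
  arr <- array(0L, shape)
  for (i in seq_len(nrow(centroids_um))) {
    v <- pmax(1L, pmin(shape, as.integer(ceiling(centroids_um[i, c(3, 2, 1)] / sp_um))))
    arr[v[1], v[2], v[3]] <- i
  }
  labeled_volume(arr, spacing_nm, "points")
}
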