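#' Proximity exclusion of unreliably separated objects
#'
#' Objects of the same structure class whose minimum boundary-to-boundary gap
#' to another object falls below `min_gap_nm` are excluded from
#' nearest-neighbour statistics: at the axial resolution of FIB-SEM
#' acquisitions (40 nm sections after binning) such pairs cannot be reliably
#' distinguished from one object split by a segmentation artifact. The gap is
#' measured as the minimum physical distance between voxel centers of the two
#' objects. By default both members of a close pair are removed
#' (`mode = "exclude_both"`); `mode = "exclude_one"` keeps the larger member
#' of each pair.
#'
#' @param instances An `instance_set` from [split_instances()].
#' @param min_gap_nm Exclusion threshold in nm; default 50. `0` disables the
#'   filter.
#' @param mode `"exclude_both"` (default) or `"exclude_one"`.
#' @return The retained `instance_set`, with an `excluded` attribute: a tibble
#'   of `id`, `partner_id`, `gap_nm` for every excluded object.
#' @export
proximity_exclusion <- function(instances, min_gap_nm = 50, mode = c("exclude_both", "exclude_one")) {
  stopifnot(inherits(instances, "instance_set"))
  mode <- match.arg(mode)
  empty <- tibble::tibble(id = integer(), partner_id = integer(), gap_nm = numeric())
  if (min_gap_nm <= 0 || nrow(instances) < 2) {
    attr(instances, "excluded") <- empty
    return(instances)
  }
  inst_vol <- instance_volume(instances)
  pairs <- .close_pairs(inst_vol, dim(inst_vol), attr(instances, "spacing_nm"), min_gap_nm)
  if (nrow(pairs) == 0) {
    attr(instances, "excluded") <- empty
    return(instances)
  }
  pair_tab <- tibble::tibble(
    a = as.integer(pairs[, 1]), b = as.integer(pairs[, 2]), gap_nm = pairs[, 3]
  )
  if (mode == "exclude_both") {
    excluded <- dplyr::bind_rows(
      dplyr::transmute(pair_tab, id = .data$a, partner_id = .data$b, gap_nm = .data$gap_nm),
      dplyr::transmute(pair_tab, id = .data$b, partner_id = .data$a, gap_nm = .data$gap_nm)
    )
  } else {
    vols <- stats::setNames(instances$volume_um3, instances$id)
    smaller <- ifelse(vols[as.character(pair_tab$a)] < vols[as.character(pair_tab$b)],
      pair_tab$a, pair_tab$b
    )
    excluded <- tibble::tibble(
      id = as.integer(smaller),
      partner_id = ifelse(smaller == pair_tab$a, pair_tab$b, pair_tab$a),
      gap_nm = pair_tab$gap_nm
    )
  }
  excluded <- dplyr::slice_min(
    dplyr::group_by(excluded, .data$id),
    .data$gap_nm,
    n = 1, with_ties = FALSE
  )
  excluded <- dplyr::ungroup(excluded)
  keep <- !instances$id %in% excluded$id
  out <- new_instance_set(
    tibble::as_tibble(instances)[keep, ], instance_volume(instances),
    attr(instances, "spacing_nm"), attr(instances, "connectivity")
  )
  attr(out, "excluded") <- excluded
  out
}

#' Nearest-neighbour distances between object centroids
#'
#' Exact Euclidean 3D nearest-neighbour distances between the centroids of
#' the retained objects, in physical micrometres. Centroids — not volume
#' boundaries — are used, which is robust to imperfect segmentation of the
#' object outline. Distances come from a full pairwise scan; no approximation
#' alters any reported distance.
#'
#' @param instances An `instance_set` with at least 2 objects (typically after
#'   [proximity_exclusion()]).
#' @return An `nn_result`: tibble of `id`, `nn_id`, `nn_distance_um` with the
#'   exclusion log of the input (if any) in the `excluded` attribute.
#' @export
nearest_neighbor <- function(instances) {
  stopifnot(inherits(instances, "instance_set"))
  if (nrow(instances) < 2) {
    stop("nearest-neighbour analysis needs at least 2 retained objects", call. = FALSE)
  }
  pts <- cbind(instances$centroid_z_um, instances$centroid_y_um, instances$centroid_x_um)
  nn <- .nn_scan(pts)
  out <- tibble::tibble(
    id = instances$id,
    nn_id = instances$id[nn$nn_id],
    nn_distance_um = nn$nn_distance
  )
  structure(out,
    excluded = attr(instances, "excluded"),
    class = c("nn_result", class(tibble::tibble()))
  )
}

#' Summaries of a nearest-neighbour distribution
#'
#' For each threshold, the fraction of objects whose nearest-neighbour
#' distance does not exceed it ("90% of junctions within 1 um" is
#' `thresholds_um = 1` and a fraction of 0.9). Percentiles use linear
#' interpolation between order statistics (the same quartile rule as
#' [group_box_stats()]).
#'
#' @param result An `nn_result` from [nearest_neighbor()].
#' @param thresholds_um Distances (um) at which to report the CDF; default 1.
#' @param percentiles Probabilities to report; defaults include the quartiles
#'   and the 90th percentile.
#' @return A list with `n`, `n_excluded`, `fraction_within_um` (named vector),
#'   `percentiles_um` (named vector), `median_um`, and `iqr_um` (25-75%).
#' @export
nn_summary <- function(result, thresholds_um = 1, percentiles = c(0.25, 0.5, 0.75, 0.9)) {
  stopifnot(inherits(result, "nn_result"))
  d <- result$nn_distance_um
  if (length(d) == 0) stop("empty nearest-neighbour result", call. = FALSE)
  frac <- vapply(thresholds_um, function(t) mean(d <= t), numeric(1))
  names(frac) <- as.character(thresholds_um)
  pct <- stats::quantile(d, probs = percentiles, type = 7, names = FALSE)
  names(pct) <- paste0("p", percentiles * 100)
  excl <- attr(result, "excluded")
  list(
    n = length(d),
    n_excluded = if (is.null(excl)) 0L else nrow(excl),
    fraction_within_um = frac,
    percentiles_um = pct,
    median_um = unname(stats::quantile(d, 0.5, type = 7)),
    iqr_um = unname(stats::quantile(d, c(0.25, 0.75), type = 7))
  )
}

#' @rdname nn_summary
#' @param x An `nn_result`.
#' @param ... Unused.
#' @method tidy nn_result
#' @export
tidy.nn_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname nn_summary
#' @method glance nn_result
#' @export
glance.nn_result <- function(x, ...) {
  s <- nn_summary(x)
  tibble::tibble(
    n = s$n,
    n_excluded = s$n_excluded,
    median_um = s$median_um,
    q25_um = s$iqr_um[1],
    q75_um = s$iqr_um[2],
    p90_um = s$percentiles_um[["p90"]],
    fraction_within_1um = mean(x$nn_distance_um <= 1)
  )
}

#' @export
print.nn_result <- function(x, ...) {
  cat(sprintf("<nn_result> %d object(s)\n", nrow(x)))
  NextMethod()
}

#' Violin-style plot of nearest-neighbour distances
#'
#' @param ... One or more named `nn_result` objects, e.g.
#'   `plot_nn_violin(mixed = r1, monolayer = r2)`.
#' @return A ggplot: violins with the 25-75% box and the median marked.
#' @export
plot_nn_violin <- function(...) {
  results <- list(...)
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- paste0("volume_", seq_along(results))
  }
  df <- purrr::map_dfr(results, tidy, .id = "volume")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$volume, y = .data$nn_distance_um)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey30") +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA, fill = "white") +
    ggplot2::stat_summary(fun = stats::median, geom = "point", shape = 18, size = 3) +
    ggplot2::labs(
      x = NULL, y = "nearest-neighbour distance (µm)",
      title = "Inter-object nearest-neighbour distances"
    ) +
    ggplot2::theme_minimal()
}
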