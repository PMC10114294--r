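#' Per-organoid ultrastructural preservation fractions
#'
#' Preservation is the fraction of scored TEM tiles devoid of freeze-damage
#' artifacts: intact tiles over total tiles, per organoid.
#'
#' @param table A tile-score tibble from [read_tile_scores()] or
#'   [generate_tile_table()].
#' @return A tibble with `sample_group`, `organoid_id`, `n_tiles`,
#'   `n_damaged`, `preserved_fraction`, plus `packing_density_um2` (area per
#'   cell) where area and cell counts are present.
#' @export
preservation_fraction <- function(table) {
  required <- c("sample_group", "organoid_id", "tile_id", "damaged")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$sample_group, .data$organoid_id),
    n_tiles = dplyr::n(),
    n_damaged = sum(.data$damaged),
    preserved_fraction = 1 - .data$n_damaged / .data$n_tiles,
    organoid_area = if ("organoid_area" %in% names(table)) .data$organoid_area[1] else NA_real_,
    n_cells = if ("n_cells" %in% names(table)) .data$n_cells[1] else NA_integer_,
    .groups = "drop"
  )
  if (any(out$n_tiles == 0)) stop("organoid with zero tiles", call. = FALSE)
  dplyr::mutate(
    out,
    packing_density_um2 = ifelse(
      !is.na(.data$organoid_area) & !is.na(.data$n_cells),
      packing_density(.data$organoid_area, .data$n_cells), NA_real_
    )
  )
}

#' Cell packing density
#'
#' The organoid's cross-sectional area divided by its cell count (cells
#' approximated by counting nuclei): um^2 per cell. Lower values mean denser
#' packing.
#'
#' @param area_um2 Organoid area(s) in um^2, > 0.
#' @param n_cells Cell count(s), >= 1.
#' @return Area per cell in um^2, vectorised.
#' @export
packing_density <- function(area_um2, n_cells) {
  if (any(area_um2 <= 0)) stop("area must be > 0", call. = FALSE)
  if (any(n_cells < 1)) stop("n_cells must be >= 1", call. = FALSE)
  area_um2 / n_cells
}

#' Box-plot statistics of a group of values
#'
#' Median, quartiles (linear interpolation between order statistics — the
#' single quantile rule used throughout the package), minimum and maximum:
#' the five numbers drawn as the box plots of preservation per sample group.
#'
#' @param values Numeric vector, length >= 1.
#' @return A tibble with `median`, `q25`, `q75`, `min`, `max`, `n`.
#' @export
group_box_stats <- function(values) {
  if (length(values) < 1) stop("need at least one value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    median = q[2], q25 = q[1], q75 = q[3],
    min = min(values), max = max(values), n = length(values)
  )
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation with the domain checks the tile
#' statistics need (equal lengths >= 3, nonzero variance in both variables).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient R in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Preservation summary across organoids
#'
#' Combines [preservation_fraction()], per-group box statistics and — where
#' packing densities are available — the Pearson correlation between packing
#' density and preservation across all organoids.
#'
#' @param table A tile-score tibble.
#' @return A `preservation_summary`: list with `per_organoid` (tibble),
#'   `per_group` (tibble of box statistics on the preserved fractions) and
#'   `pearson_r` (packing vs preservation; `NA` if packing is unavailable).
#' @export
preservation_summary <- function(table) {
  per_org <- preservation_fraction(table)
  per_group <- dplyr::reframe(
    dplyr::group_by(per_org, .data$sample_group),
    group_box_stats(.data$preserved_fraction)
  )
  r <- NA_real_
  ok <- !is.na(per_org$packing_density_um2)
  if (sum(ok) >= 3 &&
    stats::sd(per_org$packing_density_um2[ok]) > 0 &&
    stats::sd(per_org$preserved_fraction[ok]) > 0) {
    r <- pearson_r(per_org$packing_density_um2[ok], per_org$preserved_fraction[ok])
  }
  structure(
    list(per_organoid = per_org, per_group = per_group, pearson_r = r),
    class = "preservation_summary"
  )
}

#' @export
print.preservation_summary <- function(x, ...) {
  cat(sprintf(
    "<preservation_summary> %d organoid(s) in %d group(s); packing-preservation R = %s\n",
    nrow(x$per_organoid), nrow(x$per_group),
    ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r))
  ))
  print(x$per_group)
  invisible(x)
}

#' @rdname preservation_summary
#' @param x A `preservation_summary`.
#' @param ... Unused.
#' @method tidy preservation_summary
#' @export
tidy.preservation_summary <- function(x, ...) x$per_organoid

#' @rdname preservation_summary
#' @method glance preservation_summary
#' @export
glance.preservation_summary <- function(x, ...) {
  tibble::tibble(
    n_organoids = nrow(x$per_organoid),
    n_groups = nrow(x$per_group),
    median_preserved = stats::median(x$per_organoid$preserved_fraction),
    pearson_r = x$pearson_r
  )
}

#' Box plot of preservation per sample group
#'
#' @param summary A `preservation_summary`.
#' @return A ggplot with per-group boxes (median, 25-75% box, min-max
#'   whiskers) and organoid points.
#' @export
plot_preservation_box <- function(summary) {
  stopifnot(inherits(summary, "preservation_summary"))
  df <- summary$per_organoid
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_group, y = .data$preserved_fraction)) +
    ggplot2::geom_boxplot(coef = Inf, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v), limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "ultrastructural preservation",
      title = "Tile-scored preservation per sample group"
    ) +
    ggplot2::theme_minimal()
}
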