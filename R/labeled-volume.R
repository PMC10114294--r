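#' Labelled voxel volume with physical spacing
#'
#' The substrate of every measurement in the package: a 3D integer grid in
#' `(z, y, x)` axis order together with the physical voxel spacing in
#' nanometres (same order). Label 0 is background; positive labels are
#' foreground. Physical coordinates are always reported as `(x, y, z)` in
#' micrometres, and the centre of voxel `(k, j, i)` (0-based) sits at
#' `((i + 0.5) s_x, (j + 0.5) s_y, (k + 0.5) s_z)`.
#'
#' @param labels 3D array (or something coercible) of non-negative integers.
#' @param spacing_nm Numeric length-3 voxel spacing `(s_z, s_y, s_x)` in nm,
#'   all strictly positive.
#' @param class_name Free-text name of the structure class the labels encode
#'   (e.g. `"cell junctions"`, `"nuclei"`).
#' @return A `labeled_volume`: the integer array with `spacing_nm` and
#'   `class_name` attributes.
#' @examples
#' v <- labeled_volume(array(0:1, c(2, 2, 2)), spacing_nm = c(40, 30, 30))
#' voxel_volume_um3(v)
#' @export
labeled_volume <- function(labels, spacing_nm, class_name = "structure") {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  spacing_nm <- as.numeric(spacing_nm)
  if (length(spacing_nm) != 3L || any(!is.finite(spacing_nm)) || any(spacing_nm <= 0)) {
    stop("`spacing_nm` must be three strictly positive numbers (z, y, x)", call. = FALSE)
  }
  if (is.double(labels)) {
    if (any(labels != floor(labels), na.rm = TRUE)) {
      stop("voxel values must be integers", call. = FALSE)
    }
    storage.mode(labels) <- "integer"
  }
  if (anyNA(labels) || any(labels < 0L)) {
    stop("labels must be non-negative integers with no missing values", call. = FALSE)
  }
  structure(labels,
    spacing_nm = spacing_nm,
    class_name = as.character(class_name)[1],
    class = c("labeled_volume", "array")
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x)
  sp <- spacing_nm(x)
  cat(sprintf(
    "<labeled_volume> %s: %d x %d x %d voxels (z,y,x), spacing %g x %g x %g nm\n",
    attr(x, "class_name"), d[1], d[2], d[3], sp[1], sp[2], sp[3]
  ))
  lab <- unique(as.integer(x))
  cat(sprintf(
    "  foreground voxels: %d; distinct labels: %d\n",
    sum(x > 0L), sum(lab > 0L)
  ))
  invisible(x)
}

#' @rdname labeled_volume
#' @param vol A `labeled_volume`.
#' @export
spacing_nm <- function(vol) {
  sp <- attr(vol, "spacing_nm")
  if (is.null(sp)) stop("not a labeled_volume: no spacing metadata", call. = FALSE)
  sp
}

#' @rdname labeled_volume
#' @export
spacing_um <- function(vol) spacing_nm(vol) / 1000

#' @rdname labeled_volume
#' @export
voxel_volume_nm3 <- function(vol) prod(spacing_nm(vol))

#' @rdname labeled_volume
#' @export
voxel_volume_um3 <- function(vol) prod(spacing_um(vol))

# index (0-based, zyx columns) -> physical um coordinates, same column order
voxel_centers_um <- function(idx_zyx, spacing_nm) {
  sp <- spacing_nm / 1000
  sweep(idx_zyx + 0.5, 2, sp, `*`)
}

assert_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)) || !isTRUE(all.equal(spacing_nm(a), spacing_nm(b)))) {
    stop("volumes are not on the same grid (shape and spacing must match)", call. = FALSE)
  }
  invisible(TRUE)
}
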