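#' Read a label volume from TIFF or MRC
#'
#' Reads a multipage TIFF stack (one page per z-slice) or an MRC file into a
#' [labeled_volume()]. Voxel spacing is taken from, in order of precedence:
#' the `spacing_nm` argument, a sidecar JSON file `<path>.spacing.json`
#' containing `{"spacing_nm_zyx": [sz, sy, sx]}`, or (MRC only) the `cella`
#' header. TIFF resolution tags are deliberately not consulted: their dialects
#' are inconsistent across writers.
#'
#' @param path Path to a `.tif`/`.tiff` or `.mrc` file.
#' @param spacing_nm Optional explicit `(s_z, s_y, s_x)` spacing override in nm.
#' @param class_name Structure class name to attach; defaults to the file stem.
#' @return A [labeled_volume()] in `(z, y, x)` axis order.
#' @seealso [write_label_volume()]
#' @export
read_label_volume <- function(path, spacing_nm = NULL, class_name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(class_name)) class_name <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(tools::file_ext(path))
  res <- switch(ext,
    tif = ,
    tiff = read_tiff_volume(path),
    mrc = read_mrc_volume(path),
    stop(sprintf("unsupported volume format '.%s' (use TIFF or MRC)", ext), call. = FALSE)
  )
  sp <- spacing_nm %||% read_spacing_sidecar(path) %||% res$spacing_nm
  if (is.null(sp)) {
    stop(sprintf(
      "no voxel spacing for %s: pass `spacing_nm` or provide a %s sidecar",
      path, paste0(basename(path), ".spacing.json")
    ), call. = FALSE)
  }
  labeled_volume(res$labels, spacing_nm = sp, class_name = class_name)
}

#' Write a label volume to TIFF or MRC
#'
#' The format follows the file extension. Labels must fit the target sample
#' type (16-bit for TIFF, signed 16-bit for MRC). Spacing is stored in a
#' sidecar JSON `<path>.spacing.json` (and, for MRC, in the `cella` header),
#' so that [read_label_volume()] round-trips bit-exactly with its spacing.
#'
#' @param vol A [labeled_volume()].
#' @param path Destination path ending in `.tif`, `.tiff` or `.mrc`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir), call. = FALSE)
  if (file.access(dir, 2L) != 0L) stop(sprintf("directory not writable: %s", dir), call. = FALSE)
  mx <- max(0L, max(vol))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = {
      if (mx > 65535L) stop("TIFF label output supports at most 16-bit labels", call. = FALSE)
      write_tiff_volume(vol, path)
    },
    mrc = {
      if (mx > 32767L) stop("MRC label output supports at most signed 16-bit labels", call. = FALSE)
      write_mrc_volume(vol, path)
    },
    stop(sprintf("unsupported volume format '.%s' (use TIFF or MRC)", ext), call. = FALSE)
  )
  write_spacing_sidecar(path, spacing_nm(vol))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".spacing.json")

read_spacing_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  as.numeric(meta$spacing_nm_zyx)
}

write_spacing_sidecar <- function(path, spacing_nm) {
  jsonlite::write_json(list(spacing_nm_zyx = as.numeric(spacing_nm)),
    sidecar_path(path),
    auto_unbox = FALSE, digits = NA
  )
}

# ---- TIFF ----------------------------------------------------------------

read_tiff_volume <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop(sprintf("unreadable TIFF %s: %s", path, conditionMessage(e)), call. = FALSE)
  )
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d <- dim(pages[[1]])
  arr <- array(0L, c(nz, d[1], d[2]))
  for (k in seq_len(nz)) {
    pg <- pages[[k]]
    if (!identical(dim(pg), d)) stop("TIFF pages differ in size", call. = FALSE)
    if (any(pg != floor(pg))) stop("non-integer voxel values in TIFF", call. = FALSE)
    arr[k, , ] <- as.integer(pg)
  }
  list(labels = arr, spacing_nm = NULL)
}

write_tiff_volume <- function(vol, path) {
  bits <- if (max(0L, max(vol)) > 255L) 16L else 8L
  denom <- 2^bits - 1
  pages <- lapply(seq_len(dim(vol)[1]), function(k) {
    matrix(as.numeric(vol[k, , ]) / denom, nrow = dim(vol)[2], ncol = dim(vol)[3])
  })
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
    error = function(e) stop(sprintf("cannot write TIFF %s: %s", path, conditionMessage(e)), call. = FALSE)
  )
  invisible(ok)
}

# ---- MRC -----------------------------------------------------------------
# MRC2014: 1024-byte header, little-endian. Data axis order: x fastest, then
# y, then z -- the transpose of the in-memory (z, y, x) convention.

read_mrc_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  seek(con, 40)
  cella <- readBin(con, "double", n = 3, size = 4, endian = "little") # angstrom
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (any(c(nx, ny, nz) < 1) || is.na(mode)) stop(sprintf("unreadable MRC %s", path), call. = FALSE)
  seek(con, 1024 + nsymbt)
  n <- as.double(nx) * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE, endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
    "2" = {
      v <- readBin(con, "double", n = n, size = 4, endian = "little")
      if (any(v != floor(v))) stop("non-integer voxel values in MRC mode-2 file", call. = FALSE)
      as.integer(v)
    },
    stop(sprintf("MRC mode %d is not an integer label mode", mode), call. = FALSE)
  )
  if (length(vals) < n) stop(sprintf("truncated MRC %s", path), call. = FALSE)
  arr_xyz <- array(as.integer(vals), c(nx, ny, nz))
  spacing <- NULL
  if (all(is.finite(cella)) && all(cella > 0)) {
    # cella is the cell size in angstrom over (x, y, z)
    spacing <- rev(cella / c(nx, ny, nz)) / 10 * 1000 # -> nm, (z, y, x)
  }
  list(labels = aperm(arr_xyz, c(3, 2, 1)), spacing_nm = spacing)
}

write_mrc_volume <- function(vol, path) {
  d <- dim(vol) # (nz, ny, nx)
  sp <- spacing_nm(vol)
  con <- tryCatch(file(path, "wb"),
    error = function(e) stop(sprintf("cannot write MRC %s", path), call. = FALSE)
  )
  on.exit(close(con))
  hdr <- raw(1024)
  writeBin(as.integer(c(d[3], d[2], d[1], 1L, 0L, 0L, 0L, d[3], d[2], d[1])), con,
    size = 4, endian = "little"
  )
  cella_ang <- rev(sp) * d[c(3, 2, 1)] / 1000 * 10 # nm -> angstrom cell, (x,y,z)
  writeBin(as.numeric(cella_ang), con, size = 4, endian = "little")
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(vol), max(vol), mean(vol))), con, size = 4, endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little") # ispg, nsymbt
  seek(con, 208)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian machine stamp
  seek(con, 1024)
  writeBin(as.integer(aperm(unclass(vol), c(3, 2, 1))), con, size = 2, endian = "little")
  invisible(path)
}

# ---- tile score tables ---------------------------------------------------

#' Read a tile-score table
#'
#' Parses the CSV of manually scored TEM tiles used for ultrastructural
#' preservation statistics. Required columns: `sample_group`, `organoid_id`,
#' `tile_id`, `damaged`. The `damaged` column accepts `0/1`, `true/false` and
#' `yes/no` (case-insensitive). Optional per-organoid columns `organoid_area`
#' (um^2) and `n_cells` may be present on any row of that organoid.
#'
#' @param path CSV file with a header row.
#' @return A tibble with one row per tile, `damaged` as logical, plus the
#'   optional numeric columns when present.
#' @export
read_tile_scores <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_group", "organoid_id", "tile_id", "damaged")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop(sprintf("tile-score CSV lacks required column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  tab <- dplyr::mutate(
    tab,
    sample_group = as.character(.data$sample_group),
    organoid_id = as.character(.data$organoid_id),
    tile_id = as.character(.data$tile_id),
    damaged = parse_flexible_logical(.data$damaged)
  )
  dup <- dplyr::count(tab, .data$organoid_id, .data$tile_id)
  if (any(dup$n > 1)) {
    bad <- dup[dup$n > 1, ]
    stop(sprintf(
      "duplicate (organoid_id, tile_id) pair(s): %s",
      paste(paste(bad$organoid_id, bad$tile_id, sep = "/"), collapse = ", ")
    ), call. = FALSE)
  }
  if ("n_cells" %in% names(tab) &&
    any(!is.na(tab$n_cells) & tab$n_cells < 1)) {
    stop("n_cells must be >= 1 where present", call. = FALSE)
  }
  if ("organoid_area" %in% names(tab) &&
    any(!is.na(tab$organoid_area) & tab$organoid_area <= 0)) {
    stop("organoid_area must be > 0 where present", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

parse_flexible_logical <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- dplyr::case_match(
    key,
    c("1", "true", "yes") ~ TRUE,
    c("0", "false", "no") ~ FALSE,
    .default = NA
  )
  if (anyNA(out)) {
    stop(sprintf(
      "cannot parse damaged value(s): %s",
      paste(unique(key[is.na(out)]), collapse = ", ")
    ), call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
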