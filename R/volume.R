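#' Construct an atlas volume
#'
#' A `vx_volume` is a 3D scalar field on a shared atlas voxel grid. The axis
#' convention is x = left to right, y = anterior to posterior, z = dorsal to
#' ventral, with physical spacing in micrometres per voxel along each axis.
#' Two volumes are grid-compatible iff their dimensions and spacings are equal;
#' all co-registered inputs are assumed to live on one such grid (registration
#' itself is out of scope for this package).
#'
#' @param data 3D numeric array of per-voxel values.
#' @param spacing_um positive numeric triple, micrometres per voxel per axis.
#' @param value_kind one of `"raw"` (scanner intensity), `"normalized8"`
#'   (8-bit, values in 0..255), `"binary"` (0/1 occupancy) or `"label"`
#'   (integer region labels, 0 = background).
#' @param channel free-text channel label.
#' @return An object of class `vx_volume`.
#' @export
vx_volume <- function(data, spacing_um = c(1, 1, 1),
                      value_kind = c("raw", "normalized8", "binary", "label"),
                      channel = "") {
  value_kind <- match.arg(value_kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("`spacing_um` must be three positive finite numbers", call. = FALSE)
  rng <- suppressWarnings(range(data, na.rm = TRUE))
  if (value_kind == "normalized8" && (rng[1] < 0 || rng[2] > 255))
    stop("normalized8 volumes must have values in [0, 255]", call. = FALSE)
  if (value_kind == "binary" && !all(data %in% c(0, 1)))
    stop("binary volumes must contain only 0 and 1", call. = FALSE)
  structure(list(data = data, spacing_um = spacing_um,
                 value_kind = value_kind, channel = channel),
            class = "vx_volume")
}

#' @export
print.vx_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vx_volume> %d x %d x %d voxels @ %g x %g x %g um [%s]%s\n",
              d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2], x$spacing_um[3],
              x$value_kind,
              if (nzchar(x$channel)) paste0(" ", x$channel) else ""))
  invisible(x)
}

#' Voxel grid of a volume
#'
#' @param volume a [vx_volume].
#' @return List with `dims` (integer triple) and `spacing_um`.
#' @export
vx_grid <- function(volume) {
  list(dims = dim(volume$data), spacing_um = volume$spacing_um)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing_um, b$spacing_um, tolerance = 1e-8))
}

stop_grid_mismatch <- function(a, b, what = "volumes") {
  da <- paste(dim(a$data), collapse = "x"); db <- paste(dim(b$data), collapse = "x")
  stop(sprintf("grid mismatch between %s: %s @ (%s) vs %s @ (%s)", what,
               da, paste(signif(a$spacing_um, 6), collapse = ","),
               db, paste(signif(b$spacing_um, 6), collapse = ",")), call. = FALSE)
}

check_binary <- function(mask, what = "mask") {
  if (!all(mask$data %in% c(0, 1)))
    stop(sprintf("%s must be binary (0/1)", what), call. = FALSE)
  invisible(TRUE)
}

#' Read a 3D volume from a NIfTI file
#'
#' Reads a single-channel 3D NIfTI-1 file (`.nii` or `.nii.gz`). Only the
#' voxel spacing is taken from the header; orientation matrices are not
#' interpreted because inputs are assumed co-registered on a common grid.
#'
#' @param path path to the NIfTI file.
#' @param expect_grid optional grid (as returned by [vx_grid]) the file must
#'   match; a mismatch is an error reporting both dimension triples.
#' @param value_kind value kind to stamp on the result (default `"raw"`).
#' @return A [vx_volume].
#' @export
read_volume <- function(path, expect_grid = NULL, value_kind = "raw") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("%s: expected 3D single-channel data, got %d dimensions (%s)",
                 path, length(d), paste(d, collapse = "x")), call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  data <- array(as.numeric(img), dim = d)
  vol <- vx_volume(data, spacing_um = spacing, value_kind = value_kind)
  if (!is.null(expect_grid)) {
    if (!identical(as.integer(d), as.integer(expect_grid$dims)) ||
        !isTRUE(all.equal(spacing, as.numeric(expect_grid$spacing_um), tolerance = 1e-6)))
      stop(sprintf("%s: grid mismatch, file is %s @ (%s) but expected %s @ (%s)",
                   path, paste(d, collapse = "x"),
                   paste(signif(spacing, 6), collapse = ","),
                   paste(expect_grid$dims, collapse = "x"),
                   paste(signif(expect_grid$spacing_um, 6), collapse = ",")),
           call. = FALSE)
  }
  vol
}

#' Write a volume to a NIfTI file
#'
#' Storage type follows `value_kind`: binary and normalized8 volumes are
#' written as uint8, label volumes as int32, and raw volumes as uint16 when
#' all values are integers in 0..65535 (else float32). uint8/uint16 round
#' trips are bit-exact.
#'
#' @param volume a [vx_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "vx_volume"))
  v <- volume$data
  datatype <- switch(volume$value_kind,
    binary = "uint8", normalized8 = "uint8", label = "int32",
    raw = {
      if (all(v == round(v)) && min(v) >= 0 && max(v) <= 65535) "uint16" else "float"
    })
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- volume$spacing_um
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Average registered scans of one line
#'
#' Voxel-wise arithmetic mean of co-registered volumes, computed in floating
#' point, used to form the representative image of a transgenic line from
#' individual larvae. Fewer than three inputs triggers a warning (the library
#' policy is to average at least three registered brains per line), not an
#' error.
#'
#' @param volumes list of grid-compatible [vx_volume] objects.
#' @return A [vx_volume] with `value_kind = "raw"`.
#' @export
average_scans <- function(volumes) {
  if (!is.list(volumes) || length(volumes) == 0)
    stop("`volumes` must be a non-empty list of vx_volume objects", call. = FALSE)
  for (v in volumes) stopifnot(inherits(v, "vx_volume"))
  for (v in volumes[-1]) if (!same_grid(volumes[[1]], v))
    stop_grid_mismatch(volumes[[1]], v, "scans")
  if (length(volumes) < 3)
    warning(sprintf("averaging only %d scan(s); at least 3 larvae per line are recommended",
                    length(volumes)), call. = FALSE)
  acc <- Reduce(`+`, lapply(volumes, function(v) v$data * 1.0))
  vx_volume(acc / length(volumes), spacing_um = volumes[[1]]$spacing_um,
            value_kind = "raw", channel = volumes[[1]]$channel)
}

#' Normalize a volume to 8 bits with top-fraction saturation
#'
#' Intensities are rescaled so that the top `saturation_fraction` of voxels
#' saturate at 255 (default 1e-4, i.e. the brightest 0.01% of pixels), then
#' rounded (half-to-even) to 0..255. The saturation quantile uses linear
#' interpolation (type 7) over either all voxels or, with `domain = "mask"`,
#' only voxels inside a supplied brain mask.
#'
#' @param volume a [vx_volume] with non-negative values.
#' @param saturation_fraction fraction of voxels to saturate, in \[0, 0.5).
#' @param domain `"all_voxels"` (default) or `"mask"`.
#' @param mask binary [vx_volume], required when `domain = "mask"`.
#' @return A [vx_volume] with `value_kind = "normalized8"`. An all-zero input
#'   (quantile 0) maps to an all-zero output.
#' @export
normalize_to_8bit <- function(volume, saturation_fraction = 1e-4,
                              domain = c("all_voxels", "mask"), mask = NULL) {
  domain <- match.arg(domain)
  stopifnot(inherits(volume, "vx_volume"))
  if (!is.numeric(saturation_fraction) || saturation_fraction < 0 || saturation_fraction >= 0.5)
    stop("`saturation_fraction` must be in [0, 0.5)", call. = FALSE)
  v <- volume$data
  if (min(v) < 0) stop("negative intensities cannot be normalized", call. = FALSE)
  vals <- if (domain == "mask") {
    if (is.null(mask)) stop("`mask` is required when domain = \"mask\"", call. = FALSE)
    if (!same_grid(volume, mask)) stop_grid_mismatch(volume, mask)
    check_binary(mask)
    inside <- v[mask$data == 1]
    if (length(inside) == 0) stop("mask domain is empty", call. = FALSE)
    inside
  } else as.vector(v)
  q <- stats::quantile(vals, probs = 1 - saturation_fraction, names = FALSE, type = 7)
  out <- if (q > 0) round(255 * pmin(v, q) / q) else array(0, dim(v))
  vx_volume(array(out, dim(v)), spacing_um = volume$spacing_um,
            value_kind = "normalized8", channel = volume$channel)
}

#' Mask a volume
#'
#' Sets values outside a binary mask to zero (used to remove expression
#' outside the brain); values inside are unchanged.
#'
#' @param volume a [vx_volume].
#' @param mask grid-compatible binary [vx_volume].
#' @return A [vx_volume] of the same value kind.
#' @export
apply_mask <- function(volume, mask) {
  stopifnot(inherits(volume, "vx_volume"), inherits(mask, "vx_volume"))
  if (!same_grid(volume, mask)) stop_grid_mismatch(volume, mask)
  check_binary(mask)
  vx_volume(volume$data * mask$data, spacing_um = volume$spacing_um,
            value_kind = volume$value_kind, channel = volume$channel)
}

rescale_plane_nn <- function(plane, scale) {
  # nearest-neighbour index subsample: bit-exact and invertible to source voxels
  d <- dim(plane)
  sx <- max(1L, as.integer(round(d[1] * scale)))
  sy <- max(1L, as.integer(round(d[2] * scale)))
  ix <- pmin(d[1], floor((seq_len(sx) - 0.5) / scale) + 1)
  iy <- pmin(d[2], floor((seq_len(sy) - 0.5) / scale) + 1)
  plane[ix, iy, drop = FALSE]
}

#' Export a volume as a texture-atlas montage
#'
#' Takes every `z_step`-th plane (z = 1, 1 + z_step, ...), rescales each
#' in-plane by `scale` (nearest-neighbour), and tiles the planes row-major
#' (top-left first) into a `grid_cols` x `grid_rows` montage; unused tiles are
#' zero-filled. This is the 2D texture-atlas format consumed by web volume
#' renderers: e.g. a 400-plane stack at `z_step = 4` on a 10 x 10 grid yields
#' the standard 100-slice atlas.
#'
#' @param volume a [vx_volume].
#' @param z_step positive integer plane step.
#' @param grid_cols,grid_rows montage tiling; `grid_cols * grid_rows` must be
#'   at least the number of exported slices.
#' @param scale in-plane scale factor in (0, 1].
#' @return An object of class `vx_montage`: list with `montage` (2D matrix,
#'   first index = x, second = y running down the tile grid), `n_slices`,
#'   `tile_dims`, `z_step`, `grid` and `scale`.
#' @export
export_texture_atlas <- function(volume, z_step = 4, grid_cols = 10,
                                 grid_rows = 10, scale = 1) {
  stopifnot(inherits(volume, "vx_volume"))
  if (z_step < 1) stop("`z_step` must be >= 1", call. = FALSE)
  if (!is.numeric(scale) || scale <= 0 || scale > 1)
    stop("`scale` must be in (0, 1]", call. = FALSE)
  d <- dim(volume$data)
  zs <- seq(1L, d[3], by = as.integer(z_step))
  n_slices <- length(zs)
  if (grid_cols * grid_rows < n_slices)
    stop(sprintf("montage grid %dx%d holds %d tiles but %d slices were requested",
                 grid_cols, grid_rows, grid_cols * grid_rows, n_slices), call. = FALSE)
  tile0 <- rescale_plane_nn(volume$data[, , 1], scale)
  sx <- nrow(tile0); sy <- ncol(tile0)
  montage <- matrix(0, nrow = grid_cols * sx, ncol = grid_rows * sy)
  for (k in seq_along(zs)) {
    tile <- rescale_plane_nn(volume$data[, , zs[k]], scale)
    col <- (k - 1L) %% grid_cols
    row <- (k - 1L) %/% grid_cols
    montage[col * sx + seq_len(sx), row * sy + seq_len(sy)] <- tile
  }
  structure(list(montage = montage, n_slices = n_slices, tile_dims = c(sx, sy),
                 z_step = as.integer(z_step), grid = c(grid_cols, grid_rows),
                 scale = scale),
            class = "vx_montage")
}

#' Write a montage to an 8-bit grayscale PNG
#'
#' @param montage a `vx_montage` from [export_texture_atlas]; pixel values are
#'   interpreted on the 0..255 scale.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_montage_png <- function(montage, path) {
  stopifnot(inherits(montage, "vx_montage"))
  m <- pmin(pmax(montage$montage / 255, 0), 1)
  png::writePNG(t(m), path)
  invisible(path)
}
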