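#' Predict the Gal4 x Cre intersection of two expression volumes
#'
#' In intersectional transgenics a reporter is expressed only in cells that
#' carry both drivers; on co-registered atlas volumes the intersection is
#' predicted voxel-wise. `mode = "min_intensity"` (default) takes the
#' voxel-wise minimum of the two normalized intensities, a continuous
#' prediction that degrades gracefully when the two lines use different
#' thresholds. `mode = "binary_and"` ANDs the two thresholded masks, the
#' discrete overlap used when comparing against realized triple-transgenic
#' expression.
#'
#' @param a,b grid-compatible [vx_volume] objects.
#' @param mode `"min_intensity"` or `"binary_and"`.
#' @param thresholds numeric pair of cellular thresholds for `a` and `b`;
#'   required for `binary_and`.
#' @return A [vx_volume] on the same grid (binary for `binary_and`).
#' @export
predict_intersection <- function(a, b, mode = c("min_intensity", "binary_and"),
                                 thresholds = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "vx_volume"), inherits(b, "vx_volume"))
  if (!same_grid(a, b)) stop_grid_mismatch(a, b)
  if (mode == "min_intensity") {
    vx_volume(pmin(a$data, b$data), spacing_um = a$spacing_um,
              value_kind = a$value_kind,
              channel = paste(a$channel, b$channel, sep = " x "))
  } else {
    if (is.null(thresholds) || length(thresholds) != 2L)
      stop("`thresholds` (a pair) is required for mode = \"binary_and\"",
           call. = FALSE)
    ba <- binarize(a, thresholds[1]); bb <- binarize(b, thresholds[2])
    vx_volume(ba$data * bb$data, spacing_um = a$spacing_um,
              value_kind = "binary",
              channel = paste(a$channel, b$channel, sep = " x "))
  }
}

axis_index <- function(axis) {
  axis <- match.arg(axis, c("x", "y", "z"))
  c(x = 1L, y = 2L, z = 3L)[[axis]]
}

#' Maximum-intensity projection
#'
#' Per-pixel maximum along one axis (a z projection is the standard
#' horizontal view of a dorsally mounted larva).
#'
#' @param volume a [vx_volume].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Object of class `vx_projection`: list with `pixels` (2D matrix
#'   over the two non-projected axes, in axis order), `axis` and `source`.
#' @export
max_projection <- function(volume, axis = "z") {
  stopifnot(inherits(volume, "vx_volume"))
  ax <- axis_index(axis)
  keep <- setdiff(1:3, ax)
  px <- apply(volume$data, keep, max)
  structure(list(pixels = px, axis = axis, source = volume$channel),
            class = "vx_projection")
}

#' Depth-coded maximum projection
#'
#' For each ray along the projection axis, the pixel hue encodes the depth of
#' the (first) maximum and the brightness encodes the maximum value: pixel
#' colour = colormap(d / (n - 1)) scaled by max / 255, where d is the 0-based
#' arg-max depth. Ties break toward the viewer (first index); all-zero rays
#' are black. Colormaps are the named `grDevices::hcl.colors` palettes (e.g.
#' `"Viridis"`, `"Spectral"`).
#'
#' @param volume a [vx_volume] on the 0..255 intensity scale.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param colormap palette name accepted by `grDevices::hcl.colors`.
#' @return Object of class `vx_projection` with `pixels` an (nx, ny, 3) RGB
#'   array in \[0, 1\].
#' @export
depth_coded_projection <- function(volume, axis = "z", colormap = "Viridis") {
  stopifnot(inherits(volume, "vx_volume"))
  if (!colormap %in% grDevices::hcl.pals())
    stop(sprintf("unknown colormap: %s", colormap), call. = FALSE)
  ax <- axis_index(axis)
  keep <- setdiff(1:3, ax)
  n <- dim(volume$data)[ax]
  m <- apply(volume$data, keep, max)
  d <- apply(volume$data, keep, which.max)  # first maximum on ties
  lut <- grDevices::col2rgb(grDevices::hcl.colors(256L, palette = colormap)) / 255
  t_idx <- if (n > 1) round((d - 1) / (n - 1) * 255) + 1L else array(1L, dim(d))
  bright <- m / 255
  bright[m == 0] <- 0
  px <- array(0, c(dim(m), 3L))
  for (ch in 1:3)
    px[, , ch] <- matrix(lut[ch, t_idx], nrow(m), ncol(m)) * bright
  structure(list(pixels = px, axis = axis, source = volume$channel,
                 colormap = colormap),
            class = "vx_projection")
}

#' Write a projection image to PNG
#'
#' @param projection a `vx_projection`; grayscale pixels are interpreted on
#'   the 0..255 scale, RGB pixels on \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection_png <- function(projection, path) {
  stopifnot(inherits(projection, "vx_projection"))
  px <- projection$pixels
  if (length(dim(px)) == 2L) {
    png::writePNG(t(pmin(pmax(px / 255, 0), 1)), path)
  } else {
    png::writePNG(aperm(pmin(pmax(px, 0), 1), c(2, 1, 3)), path)
  }
  invisible(path)
}
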