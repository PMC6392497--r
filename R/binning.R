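#' Define cubic expression bins in the left hemisphere
#'
#' Tiles the left half of the atlas grid (voxel columns x <= midline) with
#' non-overlapping cubic bins of physical edge `bin_edge_um` (default 20 um),
#' anchored at the grid origin. A bin is kept iff every voxel of its box lies
#' inside the brain mask. Each kept bin also records its mirror box, the
#' reflection across the midline plane, so expression can be pooled over both
#' hemispheres.
#'
#' The midline is the plane between voxel columns `midline_x` and
#' `midline_x + 1` (default `floor(nx / 2)`, appropriate for atlas frames
#' that are left-right centered); voxel column i mirrors to
#' `2 * midline_x + 1 - i`.
#'
#' @param brain_mask binary [vx_volume].
#' @param bin_edge_um physical bin edge; must be a positive integer multiple
#'   of the voxel spacing on every axis.
#' @param midline_x optional midline column (1-based count of left-hemisphere
#'   columns).
#' @return Object of class `bin_set`: `bin_edge_um`, `k` (bin edge in voxels
#'   per axis), `midline_x`, and `bins`, a data.frame with 1-based box
#'   origins (`x0,y0,z0`), mirrored x origin (`mx0`) and center voxels.
#' @export
define_bins <- function(brain_mask, bin_edge_um = 20, midline_x = NULL) {
  stopifnot(inherits(brain_mask, "vx_volume"))
  check_binary(brain_mask, "brain_mask")
  d <- dim(brain_mask$data)
  sp <- brain_mask$spacing_um
  k <- bin_edge_um / sp
  if (any(abs(k - round(k)) > 1e-6) || any(round(k) < 1))
    stop(sprintf("bin edge %g um is not a positive multiple of the voxel spacing (%s um)",
                 bin_edge_um, paste(sp, collapse = ", ")), call. = FALSE)
  k <- as.integer(round(k))
  if (is.null(midline_x)) midline_x <- d[1] %/% 2L
  midline_x <- as.integer(midline_x)
  if (midline_x < 1L || midline_x > d[1])
    stop("`midline_x` is outside the grid", call. = FALSE)
  if (2L * midline_x > d[1])
    stop("mirrored boxes would fall outside the grid; choose midline_x <= nx/2",
         call. = FALSE)
  x0s <- seq(1L, by = k[1], length.out = max(0L, midline_x %/% k[1]))
  y0s <- seq(1L, by = k[2], length.out = max(0L, d[2] %/% k[2]))
  z0s <- seq(1L, by = k[3], length.out = max(0L, d[3] %/% k[3]))
  rows <- list()
  for (z0 in z0s) for (y0 in y0s) for (x0 in x0s) {
    box <- brain_mask$data[x0 + seq_len(k[1]) - 1L,
                           y0 + seq_len(k[2]) - 1L,
                           z0 + seq_len(k[3]) - 1L]
    if (all(box == 1)) {
      rows[[length(rows) + 1L]] <- c(x0, y0, z0)
    }
  }
  if (length(rows)) {
    m <- do.call(rbind, rows)
    bins <- data.frame(x0 = m[, 1], y0 = m[, 2], z0 = m[, 3])
    # mirror of [x0, x0+k-1] across the midline plane
    bins$mx0 <- 2L * midline_x + 1L - (bins$x0 + k[1] - 1L)
    bins$cx <- bins$x0 + (k[1] - 1L) %/% 2L
    bins$cy <- bins$y0 + (k[2] - 1L) %/% 2L
    bins$cz <- bins$z0 + (k[3] - 1L) %/% 2L
  } else {
    bins <- data.frame(x0 = integer(), y0 = integer(), z0 = integer(),
                       mx0 = integer(), cx = integer(), cy = integer(),
                       cz = integer())
  }
  structure(list(bin_edge_um = bin_edge_um, k = k, midline_x = midline_x,
                 grid = vx_grid(brain_mask), bins = bins),
            class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("<bin_set> %d bins of %g um (%s voxels), midline at column %d\n",
              nrow(x$bins), x$bin_edge_um, paste(x$k, collapse = "x"),
              x$midline_x))
  invisible(x)
}

#' Binned, 0-1 rescaled expression vector for one line
#'
#' For each bin, the raw value is the mean intensity over the union of the
#' bin box and its mirrored right-hemisphere box; the resulting vector is
#' rescaled to \[0, 1\] by dividing by its maximum (an all-zero vector stays
#' zero). Values describe relative expression within a line and are not
#' comparable between lines.
#'
#' @param line_volume [vx_volume] on the bin grid.
#' @param bins a `bin_set` from [define_bins]; must be non-empty.
#' @return Object of class `bin_table`: `line_id`, `values` (one per bin,
#'   in \[0, 1\]), `raw_means`, `centers` (bin center voxels).
#' @export
bin_expression <- function(line_volume, bins) {
  stopifnot(inherits(line_volume, "vx_volume"), inherits(bins, "bin_set"))
  if (!identical(dim(line_volume$data), as.integer(bins$grid$dims)))
    stop("line volume is not on the bin grid", call. = FALSE)
  if (nrow(bins$bins) == 0) stop("empty bin set", call. = FALSE)
  k <- bins$k
  raw <- vapply(seq_len(nrow(bins$bins)), function(i) {
    b <- bins$bins[i, ]
    xs <- b$x0 + seq_len(k[1]) - 1L
    mxs <- b$mx0 + seq_len(k[1]) - 1L
    ys <- b$y0 + seq_len(k[2]) - 1L
    zs <- b$z0 + seq_len(k[3]) - 1L
    mean(c(line_volume$data[xs, ys, zs], line_volume$data[mxs, ys, zs]))
  }, numeric(1))
  mx <- max(raw)
  structure(list(line_id = line_volume$channel,
                 values = if (mx > 0) raw / mx else raw,
                 raw_means = raw,
                 centers = bins$bins[, c("cx", "cy", "cz")]),
            class = "bin_table")
}

#' Write bin tables as a TSV
#'
#' Layout: first three columns are the bin center voxel coordinates, then one
#' column of 0-1 values per line.
#'
#' @param tables list of `bin_table` objects over the same bin set.
#' @param path output TSV path.
#' @param header_lines optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_bin_tsv <- function(tables, path, header_lines = NULL) {
  stopifnot(length(tables) > 0)
  df <- tables[[1]]$centers
  names(df) <- c("center_x", "center_y", "center_z")
  for (tb in tables) df[[tb$line_id]] <- tb$values
  con <- file(path, "w"); on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean expression per anatomical region
#'
#' Given an integer label volume of anatomical regions (0 = background),
#' computes the mean of the line's (optionally 0-1 scaled) intensities per
#' region. Scaling first (the default) makes means reflect relative
#' expression within the line; they cannot be compared between lines.
#' Regions absent from the label volume are simply missing from the result,
#' never reported as zero.
#'
#' @param line_volume [vx_volume].
#' @param labels integer label [vx_volume] on the same grid.
#' @param scale_first divide intensities by the volume maximum before
#'   averaging (default TRUE).
#' @return data.frame with `region` (label value) and `mean_expression`.
#' @export
region_means <- function(line_volume, labels, scale_first = TRUE) {
  stopifnot(inherits(line_volume, "vx_volume"), inherits(labels, "vx_volume"))
  if (!same_grid(line_volume, labels)) stop_grid_mismatch(line_volume, labels)
  lab <- labels$data
  if (any(lab != round(lab))) stop("labels must be integer-valued", call. = FALSE)
  nz <- lab > 0
  if (!any(nz)) stop("label volume has no nonzero labels", call. = FALSE)
  v <- line_volume$data
  if (scale_first) {
    mx <- max(v)
    if (mx > 0) v <- v / mx
  }
  sums <- rowsum(as.vector(v[nz]), group = as.vector(lab[nz]))
  ns <- rowsum(rep(1, sum(nz)), group = as.vector(lab[nz]))
  data.frame(region = as.integer(rownames(sums)),
             mean_expression = as.vector(sums / ns))
}
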