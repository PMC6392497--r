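#' Binarize a normalized volume at a cellular threshold
#'
#' A voxel is set iff its intensity is greater than or equal to the threshold
#' (>=, consistent with coverage counting). Thresholds are the per-line
#' manually defined intensities that separate cellular expression from
#' neuropil or background.
#'
#' @param volume a [vx_volume] with `value_kind = "normalized8"`.
#' @param threshold intensity in \[0, 255\].
#' @return A binary [vx_volume].
#' @export
binarize <- function(volume, threshold) {
  stopifnot(inherits(volume, "vx_volume"))
  if (volume$value_kind != "normalized8")
    stop("binarize expects a normalized8 volume", call. = FALSE)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 255)
    stop("`threshold` must be in [0, 255]", call. = FALSE)
  vx_volume(array(as.integer(volume$data >= threshold), dim(volume$data)),
            spacing_um = volume$spacing_um, value_kind = "binary",
            channel = volume$channel)
}

#' Max-pool downsample a binary mask
#'
#' Reduces resolution by an integer factor (default 4): an output cell is set
#' iff ANY constituent full-resolution voxel is set. Edge cells pool over the
#' truncated remainder. Max pooling guarantees the spatial search has no
#' false negatives at the downsampled resolution.
#'
#' @param mask binary [vx_volume] at full atlas resolution.
#' @param factor integer >= 1.
#' @return A binary [vx_volume] with dims `ceiling(dims / factor)`, spacing
#'   scaled by `factor`, carrying `$downsample_factor` and `$source_line`.
#' @export
downsample_mask <- function(mask, factor = 4) {
  stopifnot(inherits(mask, "vx_volume"))
  check_binary(mask)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("`factor` must be >= 1", call. = FALSE)
  d <- dim(mask$data)
  od <- as.integer(ceiling(d / factor))
  pd <- od * factor
  padded <- array(0L, pd)
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask$data
  out <- array(0L, od)
  for (dz in seq_len(factor) - 1L)
    for (dy in seq_len(factor) - 1L)
      for (dx in seq_len(factor) - 1L) {
        sub <- padded[seq(1L + dx, by = factor, length.out = od[1]),
                      seq(1L + dy, by = factor, length.out = od[2]),
                      seq(1L + dz, by = factor, length.out = od[3]), drop = FALSE]
        out <- pmax(out, sub)
      }
  res <- vx_volume(array(as.integer(out), od),
                   spacing_um = mask$spacing_um * factor,
                   value_kind = "binary", channel = mask$channel)
  res$downsample_factor <- factor
  res$source_line <- mask$channel
  res
}

#' Pack / unpack an 8x8x8 binary block
#'
#' The 512 binary voxels of an 8x8x8 block are packed into exactly 64 bytes:
#' voxels are linearized x-fastest (then y, then z), and bit i of byte j
#' (least-significant-bit first) holds linear voxel `8j + i`. This fixed
#' order makes fragment files bit-exact across implementations.
#' `unpack_block` inverts `pack_block` exactly.
#'
#' @param bits 8x8x8 array (or any length-512 vector in x-fastest order) of
#'   0/1 values.
#' @return `pack_block`: a raw vector of length 64. `unpack_block`: an
#'   8x8x8 integer array of 0/1.
#' @export
pack_block <- function(bits) {
  b <- as.logical(bits)
  if (length(b) != 512L || anyNA(b))
    stop("`bits` must be 512 binary values (an 8x8x8 block)", call. = FALSE)
  packBits(b, type = "raw")
}

#' @rdname pack_block
#' @param payload raw vector of length 64.
#' @export
unpack_block <- function(payload) {
  if (!is.raw(payload) || length(payload) != 64L)
    stop("`payload` must be exactly 64 raw bytes", call. = FALSE)
  array(as.integer(rawToBits(payload)), c(8L, 8L, 8L))
}

block_key <- function(bx, by, bz) sprintf("%d_%d_%d", bx, by, bz)

#' Build the bit-packed fragment store
#'
#' Pads the downsampled grid with zeros to multiples of 8, splits each line's
#' occupancy mask into 8x8x8 blocks of 64 packed bytes, and, for every block
#' coordinate, concatenates the payloads of all lines in registry order into
#' one fragment. With n lines each fragment is `64 * n` bytes (e.g. 16,896
#' bytes, about 17 kb, for a 264-line library), the unit a search client
#' downloads per sub-volume.
#'
#' @param registry an [atlas_registry], a line-record data.frame, or a
#'   character vector of line ids; its order defines the slot order.
#' @param masks named list of downsampled binary masks (from
#'   [downsample_mask]), all on one grid, covering every registry line.
#' @return An object of class `fragment_store`: `grid_dims` (downsampled),
#'   `block_dims`, `factor`, `line_order`, and `fragments` (named list of raw
#'   vectors keyed `"bx_by_bz"`, 0-based block coordinates).
#' @export
build_fragments <- function(registry, masks) {
  line_order <- if (inherits(registry, "atlas_registry")) registry$lines$line_id
    else if (is.data.frame(registry)) registry$line_id
    else as.character(registry)
  missing_lines <- setdiff(line_order, names(masks))
  if (length(missing_lines))
    stop("missing mask for line(s): ", paste(missing_lines, collapse = ", "),
         call. = FALSE)
  masks <- masks[line_order]
  for (m in masks) { stopifnot(inherits(m, "vx_volume")); check_binary(m) }
  for (m in masks[-1]) if (!same_grid(masks[[1]], m))
    stop_grid_mismatch(masks[[1]], m, "downsampled masks")
  factor <- masks[[1]]$downsample_factor
  if (is.null(factor)) factor <- 1L
  d <- dim(masks[[1]]$data)
  nb <- as.integer(ceiling(d / 8))
  pd <- nb * 8L
  padded <- lapply(masks, function(m) {
    p <- array(0L, pd)
    p[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- m$data
    p
  })
  n_lines <- length(line_order)
  fragments <- list()
  for (bz in seq_len(nb[3]) - 1L)
    for (by in seq_len(nb[2]) - 1L)
      for (bx in seq_len(nb[1]) - 1L) {
        frag <- raw(64L * n_lines)
        xr <- bx * 8L + 1:8; yr <- by * 8L + 1:8; zr <- bz * 8L + 1:8
        for (li in seq_len(n_lines))
          frag[(li - 1L) * 64L + 1:64] <- packBits(
            as.logical(padded[[li]][xr, yr, zr]), type = "raw")
        fragments[[block_key(bx, by, bz)]] <- frag
      }
  structure(list(grid_dims = d, block_dims = nb, factor = as.integer(factor),
                 spacing_um = masks[[1]]$spacing_um,
                 line_order = line_order, fragments = fragments),
            class = "fragment_store")
}

#' @export
print.fragment_store <- function(x, ...) {
  cat(sprintf("<fragment_store> %d lines, %s downsampled grid (factor %d), %d fragments of %d bytes\n",
              length(x$line_order), paste(x$grid_dims, collapse = "x"),
              x$factor, length(x$fragments), 64L * length(x$line_order)))
  invisible(x)
}

#' Write / read a fragment store directory
#'
#' The on-disk layout mirrors the per-sub-volume fragment files a web client
#' fetches: one `frag_<bx>_<by>_<bz>.bin` of raw bytes per block coordinate,
#' plus a `manifest.json` with the line order, downsample factor and grid
#' dimensions.
#'
#' @param store a `fragment_store`.
#' @param dir directory to create/read.
#' @return For `read_fragment_store`, a `fragment_store`.
#' @export
write_fragment_store <- function(store, dir) {
  stopifnot(inherits(store, "fragment_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(line_order = store$line_order, factor = store$factor,
                   grid_dims = store$grid_dims, block_dims = store$block_dims,
                   spacing_um = store$spacing_um,
                   fragment_bytes = 64L * length(store$line_order))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (key in names(store$fragments))
    writeBin(store$fragments[[key]], file.path(dir, sprintf("frag_%s.bin", key)))
  invisible(dir)
}

#' @rdname write_fragment_store
#' @export
read_fragment_store <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop(sprintf("index manifest not found: %s", mpath), call. = FALSE)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  n_bytes <- 64L * length(m$line_order)
  nb <- as.integer(m$block_dims)
  fragments <- list()
  for (bz in seq_len(nb[3]) - 1L)
    for (by in seq_len(nb[2]) - 1L)
      for (bx in seq_len(nb[1]) - 1L) {
        key <- block_key(bx, by, bz)
        fragments[[key]] <- readBin(file.path(dir, sprintf("frag_%s.bin", key)),
                                    "raw", n = n_bytes)
      }
  structure(list(grid_dims = as.integer(m$grid_dims), block_dims = nb,
                 factor = as.integer(m$factor),
                 spacing_um = as.numeric(m$spacing_um),
                 line_order = m$line_order, fragments = fragments),
            class = "fragment_store")
}

#' Define a spatial search box
#'
#' Boxes are specified at FULL atlas resolution as 0-based, half-open voxel
#' ranges `[lo, hi)` on each axis.
#'
#' @param lo,hi integer triples with `lo <= hi` component-wise.
#' @return An object of class `search_box`.
#' @export
search_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || anyNA(lo) || anyNA(hi))
    stop("`lo` and `hi` must be integer triples", call. = FALSE)
  if (any(hi < lo)) stop("`lo` must be <= `hi` component-wise", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "search_box")
}

# full-resolution half-open box -> downsampled half-open cover, clipped to grid
box_to_downsampled <- function(box, factor, grid_dims) {
  dlo <- pmax(as.integer(floor(box$lo / factor)), 0L)
  dhi <- pmin(as.integer(ceiling(box$hi / factor)), as.integer(grid_dims))
  if (any(dhi <= dlo))
    stop("search box is empty after conversion to the downsampled grid", call. = FALSE)
  list(lo = dlo, hi = dhi)
}

#' Search the fragment index for lines expressed in a box
#'
#' Converts the full-resolution box to its downsampled cover (floor(lo /
#' factor) to ceiling(hi / factor), so no set voxel is missed), then counts
#' each line's set cells inside the cover, touching only fragments that
#' overlap the box. Lines whose count reaches `min_cells` are returned in
#' registry order.
#'
#' @param store a `fragment_store`.
#' @param box a [search_box] at full atlas resolution.
#' @param min_cells minimum number of set downsampled cells (default 1, i.e.
#'   any expression in the box).
#' @return Character vector of line ids in registry order.
#' @export
spatial_search <- function(store, box, min_cells = 1) {
  stopifnot(inherits(store, "fragment_store"), inherits(box, "search_box"))
  if (min_cells < 1) stop("`min_cells` must be >= 1", call. = FALSE)
  ds <- box_to_downsampled(box, store$factor, store$grid_dims)
  n_lines <- length(store$line_order)
  counts <- integer(n_lines)
  b_lo <- as.integer(floor(ds$lo / 8)); b_hi <- as.integer(ceiling(ds$hi / 8)) - 1L
  for (bz in b_lo[3]:b_hi[3])
    for (by in b_lo[2]:b_hi[2])
      for (bx in b_lo[1]:b_hi[1]) {
        frag <- store$fragments[[block_key(bx, by, bz)]]
        if (is.null(frag)) next
        base <- c(bx, by, bz) * 8L
        lx <- (max(ds$lo[1], base[1]):(min(ds$hi[1], base[1] + 8L) - 1L)) - base[1] + 1L
        ly <- (max(ds$lo[2], base[2]):(min(ds$hi[2], base[2] + 8L) - 1L)) - base[2] + 1L
        lz <- (max(ds$lo[3], base[3]):(min(ds$hi[3], base[3] + 8L) - 1L)) - base[3] + 1L
        sel <- array(FALSE, c(8L, 8L, 8L)); sel[lx, ly, lz] <- TRUE
        idx <- which(sel)
        for (li in seq_len(n_lines)) {
          bits <- rawToBits(frag[(li - 1L) * 64L + 1:64])
          counts[li] <- counts[li] + sum(bits[idx] != as.raw(0))
        }
      }
  store$line_order[counts >= min_cells]
}

#' Brute-force reference search over downsampled masks
#'
#' Direct voxel loop over the same converted box, with the same return
#' contract as [spatial_search]; serves as the independent oracle for the
#' packed index.
#'
#' @param masks named list of downsampled binary masks in the desired line
#'   order.
#' @param box a [search_box] at full atlas resolution.
#' @param min_cells minimum set-cell count (default 1).
#' @return Character vector of line ids in mask-list order.
#' @export
brute_force_search <- function(masks, box, min_cells = 1) {
  stopifnot(is.list(masks), length(masks) > 0, inherits(box, "search_box"))
  if (min_cells < 1) stop("`min_cells` must be >= 1", call. = FALSE)
  factor <- masks[[1]]$downsample_factor
  if (is.null(factor)) factor <- 1L
  d <- dim(masks[[1]]$data)
  ds <- box_to_downsampled(box, factor, d)
  xr <- (ds$lo[1] + 1L):ds$hi[1]; yr <- (ds$lo[2] + 1L):ds$hi[2]
  zr <- (ds$lo[3] + 1L):ds$hi[3]
  hits <- vapply(masks, function(m) sum(m$data[xr, yr, zr]) >= min_cells,
                 logical(1))
  names(masks)[hits]
}
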