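#' Estimate the cell-body volume from soma and neuropil markers
#'
#' Brain voxels are split into soma-dominated (cell-body) and neuropil
#' territory using the ratio of a nuclear/soma marker channel to a synapse/
#' neuropil marker channel: within the brain mask, a voxel belongs to the
#' cell-body volume iff `soma / (soma + neuropil) >= ratio_threshold`.
#' Voxels where both channels are zero carry no evidence and are excluded.
#'
#' @param soma,neuropil grid-compatible marker [vx_volume]s.
#' @param brain_mask binary [vx_volume] on the same grid.
#' @param ratio_threshold soma fraction cutoff in (0, 1); default 0.5
#'   (soma signal at least as strong as neuropil).
#' @return A binary [vx_volume] — the cell-body mask.
#' @export
cellbody_mask <- function(soma, neuropil, brain_mask, ratio_threshold = 0.5) {
  stopifnot(inherits(soma, "vx_volume"), inherits(neuropil, "vx_volume"),
            inherits(brain_mask, "vx_volume"))
  if (!same_grid(soma, neuropil)) stop_grid_mismatch(soma, neuropil, "marker channels")
  if (!same_grid(soma, brain_mask)) stop_grid_mismatch(soma, brain_mask, "soma/brain_mask")
  check_binary(brain_mask, "brain_mask")
  if (!is.numeric(ratio_threshold) || ratio_threshold <= 0 || ratio_threshold >= 1)
    stop("`ratio_threshold` must be in (0, 1)", call. = FALSE)
  tot <- soma$data + neuropil$data
  ratio <- ifelse(tot > 0, soma$data / tot, -1)  # -1 = excluded (no evidence)
  inside <- (brain_mask$data == 1) & (ratio >= ratio_threshold)
  vx_volume(array(as.integer(inside), dim(soma$data)),
            spacing_um = soma$spacing_um, value_kind = "binary",
            channel = "cellbody_mask")
}

#' Coverage of the cell-body volume by one line
#'
#' Counts mask voxels with super-threshold expression (>= the line's cellular
#' threshold) and reports the covered fraction — the selectivity measure of a
#' transgenic line.
#'
#' @param line_volume normalized8 [vx_volume] of the line.
#' @param record one line record (single-row data.frame or list) with at
#'   least `line_id` and `cell_threshold`.
#' @param mask binary [vx_volume] (usually the cell-body mask).
#' @return data.frame with `line_id`, `covered_voxels`, `mask_voxels`,
#'   `coverage_fraction`.
#' @export
line_coverage <- function(line_volume, record, mask) {
  stopifnot(inherits(line_volume, "vx_volume"), inherits(mask, "vx_volume"))
  if (!same_grid(line_volume, mask)) stop_grid_mismatch(line_volume, mask)
  check_binary(mask)
  n_mask <- sum(mask$data)
  if (n_mask == 0) stop("mask is empty", call. = FALSE)
  thr <- record$cell_threshold
  covered <- sum(line_volume$data[mask$data == 1] >= thr)
  data.frame(line_id = record$line_id,
             covered_voxels = covered,
             mask_voxels = n_mask,
             coverage_fraction = covered / n_mask,
             stringsAsFactors = FALSE)
}

#' Per-voxel line-count map
#'
#' For each cell-body-mask voxel, the number of (non-excluded) lines with
#' super-threshold expression there; zero outside the mask. Lines flagged
#' `exclude_from_coverage` are dropped before counting.
#'
#' @param volumes named list of normalized8 [vx_volume]s keyed by line id.
#' @param records line-record data.frame covering those lines.
#' @param mask binary [vx_volume].
#' @return A [vx_volume] of integer counts (`value_kind = "label"`).
#' @export
line_count_map <- function(volumes, records, mask) {
  stopifnot(is.data.frame(records), inherits(mask, "vx_volume"))
  check_binary(mask)
  keep <- records[!records$exclude_from_coverage, , drop = FALSE]
  if (nrow(keep) == 0) stop("no lines to count (all excluded or empty list)", call. = FALSE)
  missing_vols <- setdiff(keep$line_id, names(volumes))
  if (length(missing_vols))
    stop("missing volume for line(s): ", paste(missing_vols, collapse = ", "),
         call. = FALSE)
  counts <- array(0L, dim(mask$data))
  for (i in seq_len(nrow(keep))) {
    v <- volumes[[keep$line_id[i]]]
    if (!same_grid(v, mask)) stop_grid_mismatch(v, mask, keep$line_id[i])
    counts <- counts + (v$data >= keep$cell_threshold[i])
  }
  counts <- counts * mask$data
  vx_volume(array(as.integer(counts), dim(mask$data)),
            spacing_um = mask$spacing_um, value_kind = "label",
            channel = "line_count")
}

#' Library-level coverage summary
#'
#' Summarizes how completely a driver library tiles the cell-body volume:
#' the fraction of mask voxels labeled by at least one line, the mean number
#' of lines per voxel, the per-line coverage distribution (median and range)
#' and a fixed-width histogram of coverage fractions for library plots.
#'
#' @param count_map integer count [vx_volume] from [line_count_map].
#' @param mask binary [vx_volume] used to build the count map.
#' @param reports data.frame of per-line rows from [line_coverage]
#'   (excluded lines already absent).
#' @param excluded character vector of line ids that were excluded, recorded
#'   for provenance.
#' @param n_hist_bins number of equal-width histogram bins on
#'   \[0, max coverage\] (default 50).
#' @return Object of class `library_summary`.
#' @export
library_summary <- function(count_map, mask, reports, excluded = character(),
                            n_hist_bins = 50) {
  stopifnot(inherits(count_map, "vx_volume"), inherits(mask, "vx_volume"),
            is.data.frame(reports))
  check_binary(mask)
  if (!same_grid(count_map, mask)) stop_grid_mismatch(count_map, mask)
  if (sum(mask$data) == 0) stop("mask is empty", call. = FALSE)
  cm <- count_map$data[mask$data == 1]
  fr <- reports$coverage_fraction
  hist_upper <- max(fr, 0)
  breaks <- if (hist_upper > 0) seq(0, hist_upper, length.out = n_hist_bins + 1)
            else c(0, 1)
  hist_counts <- if (hist_upper > 0)
    graphics::hist(fr, breaks = breaks, plot = FALSE)$counts
  else c(length(fr))
  structure(list(
    fraction_covered_ge1 = mean(cm >= 1),
    mean_lines_per_voxel = mean(cm),
    median_coverage = stats::median(fr),
    coverage_range = if (length(fr)) range(fr) else c(NA_real_, NA_real_),
    hist_breaks = breaks,
    hist_counts = hist_counts,
    per_line = reports,
    excluded = excluded
  ), class = "library_summary")
}

#' @export
print.library_summary <- function(x, ...) {
  cat(sprintf(
    "<library_summary> %d lines (%d excluded)\n  union coverage >=1 line: %.1f%%\n  mean lines per voxel:    %.2f\n  median line coverage:    %.2f%% (range %.2f%% - %.2f%%)\n",
    nrow(x$per_line), length(x$excluded), 100 * x$fraction_covered_ge1,
    x$mean_lines_per_voxel, 100 * x$median_coverage,
    100 * x$coverage_range[1], 100 * x$coverage_range[2]))
  invisible(x)
}

#' Convert a coverage fraction to an estimated neuron count
#'
#' Multiplies a line's cell-body coverage fraction by the total neuron count
#' of the larval brain and rounds to a given number of significant figures;
#' e.g. a 6% median coverage of a 92,000-neuron brain equates to roughly
#' 5,500 neurons per line.
#'
#' @param coverage_fraction fraction in \[0, 1\].
#' @param total_neurons total neurons in the brain (default 92000, the
#'   stratified-count estimate for the 6 dpf brain).
#' @param sig_figs significant figures to round to (default 2).
#' @return Estimated neuron count (numeric).
#' @export
neurons_per_line <- function(coverage_fraction, total_neurons = 92000,
                             sig_figs = 2) {
  if (any(coverage_fraction < 0 | coverage_fraction > 1))
    stop("`coverage_fraction` must be in [0, 1]", call. = FALSE)
  if (any(total_neurons < 0)) stop("`total_neurons` must be >= 0", call. = FALSE)
  signif(round(coverage_fraction * total_neurons), sig_figs)
}

#' Write per-line coverage reports as TSV
#'
#' Columns `line_id covered_voxels mask_voxels coverage_fraction`.
#'
#' @param reports data.frame of [line_coverage] rows.
#' @param path output TSV path.
#' @param header_lines optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(reports, path, header_lines = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(reports, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
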