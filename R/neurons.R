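#' Assign brain voxels to neuronal-density bins
#'
#' Neuron density varies across the brain with the local balance of cell
#' bodies and neuropil. Each brain voxel gets the soma ratio
#' `r = soma / (soma + synapse)` (0 where both channels are zero) and voxels
#' are cut into `n_bins` equal-population bins of r (rank-based quantile
#' intervals; tied values share a bin). Equal-population bins guarantee every
#' bin is large enough to place sampling volumes in.
#'
#' @param soma,synapse marker [vx_volume]s (nuclear/soma vs synaptic marker).
#' @param brain_mask binary [vx_volume] on the same grid.
#' @param n_bins number of density bins (default 5).
#' @return Object of class `density_binning`: `n_bins`, `bin_label` (a label
#'   [vx_volume], 0 outside the brain, 1..n_bins inside), `bin_fractions`
#'   (voxel share per bin, summing to 1), `spacing_um`, `n_brain_voxels`,
#'   `brain_volume_um3`.
#' @export
density_bins <- function(soma, synapse, brain_mask, n_bins = 5) {
  stopifnot(inherits(soma, "vx_volume"), inherits(synapse, "vx_volume"),
            inherits(brain_mask, "vx_volume"))
  if (!same_grid(soma, synapse)) stop_grid_mismatch(soma, synapse, "marker channels")
  if (!same_grid(soma, brain_mask)) stop_grid_mismatch(soma, brain_mask, "soma/brain_mask")
  check_binary(brain_mask, "brain_mask")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  inside <- brain_mask$data == 1
  n <- sum(inside)
  if (n == 0) stop("brain mask is empty", call. = FALSE)
  tot <- soma$data[inside] + synapse$data[inside]
  r <- ifelse(tot > 0, soma$data[inside] / tot, 0)
  rk <- rank(r, ties.method = "min")
  bin <- pmin(n_bins, as.integer(ceiling(rk * n_bins / n)))
  lab <- array(0L, dim(soma$data))
  lab[inside] <- bin
  fractions <- tabulate(bin, nbins = n_bins) / n
  voxel_um3 <- prod(soma$spacing_um)
  structure(list(n_bins = n_bins,
                 bin_label = vx_volume(lab, spacing_um = soma$spacing_um,
                                       value_kind = "label",
                                       channel = "density_bin"),
                 bin_fractions = fractions,
                 spacing_um = soma$spacing_um,
                 n_brain_voxels = n,
                 brain_volume_um3 = n * voxel_um3),
            class = "density_binning")
}

#' @export
print.density_binning <- function(x, ...) {
  cat(sprintf("<density_binning> %d bins over %d brain voxels (%.3g um^3)\n",
              x$n_bins, x$n_brain_voxels, x$brain_volume_um3))
  cat("  bin fractions:", paste(sprintf("%.3f", x$bin_fractions), collapse = " "), "\n")
  invisible(x)
}

#' Plan representative sampling volumes per density bin
#'
#' Draws `boxes_per_bin` cubic sampling volumes (default 5 of 30 um edge) for
#' each density bin by seeded uniform rejection sampling: a candidate box is
#' accepted for bin b iff b is the modal nonzero bin label among its voxels
#' (majority-label rule) and it does not overlap an already accepted box.
#' Bins with zero voxel share are skipped (they need no samples); a non-empty
#' bin that cannot host its boxes is an error naming the bin. Deterministic
#' given `seed`.
#'
#' @param binning a `density_binning`.
#' @param boxes_per_bin boxes per bin (default 5).
#' @param edge_um cubic box edge; must be commensurate with the voxel
#'   spacing (default 30).
#' @param seed integer RNG seed.
#' @param max_tries rejection-sampling attempts per bin before giving up.
#' @return Object of class `sample_plan`: `edge_um`, `k` (box edge in voxels
#'   per axis), `box_volume_um3`, `boxes` (data.frame `bin, x0, y0, z0`,
#'   1-based origins) and `counts` (NULL until observed counts are attached).
#' @export
plan_samples <- function(binning, boxes_per_bin = 5, edge_um = 30, seed = 1,
                         max_tries = 5000) {
  stopifnot(inherits(binning, "density_binning"))
  if (boxes_per_bin < 1) stop("`boxes_per_bin` must be >= 1", call. = FALSE)
  k <- edge_um / binning$spacing_um
  if (any(abs(k - round(k)) > 1e-6) || any(round(k) < 1))
    stop(sprintf("box edge %g um is not a multiple of the voxel spacing (%s um)",
                 edge_um, paste(binning$spacing_um, collapse = ", ")), call. = FALSE)
  k <- as.integer(round(k))
  lab <- binning$bin_label$data
  d <- dim(lab)
  if (any(d < k)) stop("sampling box is larger than the grid", call. = FALSE)
  set.seed(as.integer(seed))
  accepted <- list()
  failed_bins <- integer()
  occupied <- which(binning$bin_fractions > 0)
  for (b in occupied) {
    got <- 0L
    for (try in seq_len(max_tries)) {
      if (got >= boxes_per_bin) break
      x0 <- sample.int(d[1] - k[1] + 1L, 1L)
      y0 <- sample.int(d[2] - k[2] + 1L, 1L)
      z0 <- sample.int(d[3] - k[3] + 1L, 1L)
      box <- lab[x0 + seq_len(k[1]) - 1L, y0 + seq_len(k[2]) - 1L,
                 z0 + seq_len(k[3]) - 1L]
      counts <- tabulate(box[box > 0], nbins = binning$n_bins)
      if (sum(counts) == 0 || which.max(counts) != b) next
      overlap <- FALSE
      for (a in accepted) {
        if (all(abs(c(x0, y0, z0) - a$lo) < k)) { overlap <- TRUE; break }
      }
      if (overlap) next
      accepted[[length(accepted) + 1L]] <- list(bin = b, lo = c(x0, y0, z0))
      got <- got + 1L
    }
    if (got < boxes_per_bin) failed_bins <- c(failed_bins, b)
  }
  if (length(failed_bins))
    stop("could not place ", boxes_per_bin, " sampling box(es) in bin(s): ",
         paste(failed_bins, collapse = ", "),
         " (bin too small or too fragmented)", call. = FALSE)
  m <- do.call(rbind, lapply(accepted, function(a) c(a$bin, a$lo)))
  structure(list(edge_um = edge_um, k = k,
                 box_volume_um3 = prod(k * binning$spacing_um),
                 boxes = data.frame(bin = m[, 1], x0 = m[, 2], y0 = m[, 3],
                                    z0 = m[, 4]),
                 counts = NULL),
            class = "sample_plan")
}

#' Attach observed neuron counts to a sample plan
#'
#' Counting neurons inside the sampled boxes (e.g. from nuclear-localized
#' reporter images) is outside the estimator; counts are supplied here, one
#' per planned box in row order.
#'
#' @param plan a `sample_plan`.
#' @param counts non-negative numeric vector, one count per box.
#' @return The plan with `$counts` set.
#' @export
set_counts <- function(plan, counts) {
  stopifnot(inherits(plan, "sample_plan"))
  if (length(counts) != nrow(plan$boxes))
    stop(sprintf("expected %d counts (one per box), got %d",
                 nrow(plan$boxes), length(counts)), call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  plan$counts <- as.numeric(counts)
  plan
}

#' Stratified estimate of total neuron number
#'
#' Scales the mean neuron density observed in each density bin's sampling
#' boxes by the fraction of the brain that bin covers:
#' `total = V_brain * sum_b fraction_b * mean(count_b) / V_box`. The
#' standard error combines the per-bin standard errors of the mean over
#' independent bins:
#' `se^2 = V_brain^2 * sum_b fraction_b^2 * sem_b^2 / V_box^2`.
#'
#' @param plan a `sample_plan` with counts attached.
#' @param binning the `density_binning` the plan was drawn from.
#' @param brain_volume_um3 brain volume in um^3 (default: from `binning`).
#' @return Object of class `neuron_estimate`: `total`, `se`, `per_bin`
#'   (bin, n boxes, mean count, sem, density per um^3), `brain_volume_um3`.
#' @export
estimate_total <- function(plan, binning,
                           brain_volume_um3 = binning$brain_volume_um3) {
  stopifnot(inherits(plan, "sample_plan"), inherits(binning, "density_binning"))
  if (is.null(plan$counts))
    stop("plan has no observed counts; use set_counts()", call. = FALSE)
  vb <- plan$box_volume_um3
  per_bin <- do.call(rbind, lapply(seq_len(binning$n_bins), function(b) {
    idx <- plan$boxes$bin == b
    if (!any(idx)) {
      if (binning$bin_fractions[b] > 0)
        stop(sprintf("no sampled boxes for bin %d", b), call. = FALSE)
      return(data.frame(bin = b, n_boxes = 0L, mean_count = 0, sem_count = 0,
                        density_per_um3 = 0))  # empty bin contributes nothing
    }
    cts <- plan$counts[idx]
    nb <- length(cts)
    sem <- if (nb > 1) stats::sd(cts) / sqrt(nb) else 0
    data.frame(bin = b, n_boxes = nb, mean_count = mean(cts), sem_count = sem,
               density_per_um3 = mean(cts) / vb)
  }))
  fr <- binning$bin_fractions
  total <- brain_volume_um3 * sum(fr * per_bin$density_per_um3)
  se <- brain_volume_um3 * sqrt(sum(fr^2 * per_bin$sem_count^2)) / vb
  structure(list(total = total, se = se, per_bin = per_bin,
                 brain_volume_um3 = brain_volume_um3),
            class = "neuron_estimate")
}

#' @export
print.neuron_estimate <- function(x, ...) {
  cat(sprintf("<neuron_estimate> %s +/- %s neurons (brain volume %.3g um^3)\n",
              format(signif(x$total, 3), big.mark = ","),
              format(signif(x$se, 2), big.mark = ","), x$brain_volume_um3))
  invisible(x)
}

#' Write a sample plan (with counts) as TSV
#'
#' Columns `bin box_lo_x box_lo_y box_lo_z count` (count NA if unobserved).
#'
#' @param plan a `sample_plan`.
#' @param path output TSV path.
#' @param header_lines optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_plan_tsv <- function(plan, path, header_lines = NULL) {
  df <- plan$boxes
  names(df) <- c("bin", "box_lo_x", "box_lo_y", "box_lo_z")
  df$count <- if (is.null(plan$counts)) NA_real_ else plan$counts
  con <- file(path, "w"); on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
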