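#' Phantom brain specification
#'
#' Parameters for the synthetic fixtures used to exercise every stage of the
#' toolkit without the original imaging data. The default grid is
#' 128 x 64 x 64 voxels at 2 um isotropic: small enough for seconds-scale
#' work, large enough for 20 um bins, 30 um sampling boxes and 8x8x8 index
#' blocks to be non-degenerate. Generators are pure functions of
#' (spec, seed): identical inputs give identical outputs.
#'
#' @param dims integer triple of grid dimensions.
#' @param spacing_um voxel spacing in um.
#' @param seed integer RNG seed.
#' @param n_lines number of synthetic lines.
#' @param clusters_per_line expression clusters per line.
#' @param cluster_radius_um Gaussian cluster radius (sd) in um.
#' @param intensity_range range of cluster peak intensities (0..255).
#' @param symmetric make the brain mask exactly left-right mirror symmetric.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(128, 64, 64), spacing_um = c(2, 2, 2),
                         seed = 1, n_lines = 10, clusters_per_line = 3,
                         cluster_radius_um = 12,
                         intensity_range = c(120, 255), symmetric = TRUE) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 8))
    stop("degenerate dims: need three values >= 8", call. = FALSE)
  structure(list(dims = dims, spacing_um = as.numeric(spacing_um),
                 seed = as.integer(seed), n_lines = as.integer(n_lines),
                 clusters_per_line = as.integer(clusters_per_line),
                 cluster_radius_um = cluster_radius_um,
                 intensity_range = intensity_range,
                 symmetric = isTRUE(symmetric)),
            class = "phantom_spec")
}

#' Generate a phantom brain with soma and neuropil channels
#'
#' The brain mask is an ellipsoid centered on the grid. The soma and
#' neuropil marker channels are smooth complementary radial fields that
#' emulate the observed anatomy — a soma-dominant shell (cell bodies
#' enriched toward the brain surface) around a neuropil-dominant core — so
#' that [cellbody_mask] and [density_bins] have non-trivial structure.
#' Inside the mask the two channels sum to 255 everywhere. With
#' `symmetric = TRUE` all outputs equal their mirror across the midline.
#'
#' @param spec a [phantom_spec].
#' @return List with binary `brain_mask` and raw `soma`, `neuropil`
#'   [vx_volume]s.
#' @export
make_phantom_brain <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  set.seed(spec$seed)
  center <- (d + 1) / 2
  if (!spec$symmetric) center <- center + c(stats::runif(1, 0.5, 1.5), 0, 0)
  semi <- c(0.45, 0.42, 0.42) * d
  x2 <- ((seq_len(d[1]) - center[1]) / semi[1])^2
  y2 <- ((seq_len(d[2]) - center[2]) / semi[2])^2
  z2 <- ((seq_len(d[3]) - center[3]) / semi[3])^2
  r2 <- outer(outer(x2, y2, `+`), z2, `+`)
  inside <- r2 <= 1
  u <- sqrt(pmin(r2, 1))  # normalized radius in [0, 1]
  soma_frac <- 0.15 + 0.8 * u^2   # soma-dominant shell, neuropil-dominant core
  soma <- array(0, d); neuropil <- array(0, d)
  soma[inside] <- round(255 * soma_frac[inside])
  neuropil[inside] <- 255 - soma[inside]
  list(brain_mask = vx_volume(array(as.integer(inside), d),
                              spacing_um = spec$spacing_um,
                              value_kind = "binary", channel = "brain_mask"),
       soma = vx_volume(soma, spacing_um = spec$spacing_um,
                        value_kind = "raw", channel = "soma_marker"),
       neuropil = vx_volume(neuropil, spacing_um = spec$spacing_um,
                            value_kind = "raw", channel = "neuropil_marker"))
}

#' Generate a synthetic line expression volume
#'
#' Stands in for a registered, averaged line scan: Gaussian intensity blobs
#' centered at uniformly sampled in-mask voxels, clipped to the brain mask,
#' on the normalized 0..255 scale. Ground-truth cluster centers are returned
#' alongside.
#'
#' @param mask binary brain-mask [vx_volume].
#' @param n_clusters number of expression clusters (>= 0).
#' @param radius_um Gaussian sd in um.
#' @param seed integer RNG seed.
#' @param peak_range range of cluster peak intensities.
#' @param channel line id stamped on the volume.
#' @return List with `volume` (normalized8 [vx_volume]) and `centers`
#'   (n_clusters x 3 matrix of voxel coordinates).
#' @export
make_line_volume <- function(mask, n_clusters, radius_um = 12, seed = 1,
                             peak_range = c(120, 255), channel = "") {
  stopifnot(inherits(mask, "vx_volume"))
  check_binary(mask)
  if (n_clusters < 0) stop("`n_clusters` must be >= 0", call. = FALSE)
  d <- dim(mask$data)
  set.seed(as.integer(seed))
  acc <- array(0, d)
  centers <- matrix(numeric(0), ncol = 3,
                    dimnames = list(NULL, c("x", "y", "z")))
  if (n_clusters > 0) {
    in_idx <- which(mask$data == 1)
    pick <- sample(in_idx, n_clusters, replace = FALSE)
    centers <- matrix(0, nrow = n_clusters, ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
    sigma_vox <- radius_um / mask$spacing_um
    for (ci in seq_len(n_clusters)) {
      pos <- arrayInd(pick[ci], d)
      centers[ci, ] <- pos
      amp <- stats::runif(1, peak_range[1], peak_range[2])
      gx <- exp(-((seq_len(d[1]) - pos[1])^2) / (2 * sigma_vox[1]^2))
      gy <- exp(-((seq_len(d[2]) - pos[2])^2) / (2 * sigma_vox[2]^2))
      gz <- exp(-((seq_len(d[3]) - pos[3])^2) / (2 * sigma_vox[3]^2))
      acc <- acc + amp * outer(outer(gx, gy), gz)
    }
  }
  v <- round(pmin(acc, 255)) * mask$data
  list(volume = vx_volume(array(v, d), spacing_um = mask$spacing_um,
                          value_kind = "normalized8", channel = channel),
       centers = centers)
}

#' Generate a synthetic line library with registry
#'
#' Emits a phantom brain plus `k_cre + k_gal4 + k_fp` synthetic line volumes
#' and a matching registry. When `k_cre >= 1` the first Cre line is a broad,
#' near pan-neuronal line flagged `exclude_from_coverage` (the analogue of
#' an extremely broadly expressed driver that would distort library coverage
#' statistics). Optionally writes everything (NIfTI volumes + registry TSV)
#' to a directory.
#'
#' @param k_cre,k_gal4,k_fp line counts per driver (>= 0).
#' @param seed integer RNG seed.
#' @param spec [phantom_spec] for the underlying brain (its seed is
#'   overridden by `seed`).
#' @param dir optional output directory.
#' @return List with `registry` (an [atlas_registry]), `volumes` (named list
#'   of normalized8 volumes), `brain_mask`, `soma`, `neuropil`, `centers`
#'   (named list of planted cluster centers).
#' @export
make_registry <- function(k_cre, k_gal4, k_fp, seed = 1,
                          spec = phantom_spec(), dir = NULL) {
  if (k_cre < 0 || k_gal4 < 0 || k_fp < 0)
    stop("line counts must be >= 0", call. = FALSE)
  spec$seed <- as.integer(seed)
  phantom <- make_phantom_brain(spec)
  ids <- c(if (k_cre > 0) sprintf("cre-%02d", seq_len(k_cre)),
           if (k_gal4 > 0) sprintf("gal4-%02d", seq_len(k_gal4)),
           if (k_fp > 0) sprintf("fp-%02d", seq_len(k_fp)))
  drivers <- c(rep("Cre", k_cre), rep("Gal4", k_gal4), rep("FP", k_fp))
  n <- length(ids)
  if (n == 0) stop("need at least one line", call. = FALSE)
  set.seed(as.integer(seed))
  thresholds <- sample(30:80, n, replace = TRUE)
  n_averaged <- sample(3:10, n, replace = TRUE)
  construction <- sample(c("enhancer_trap", "promoter_transgenic"), n,
                         replace = TRUE, prob = c(0.8, 0.2))
  mapped <- stats::runif(n) < 0.65
  exclude <- rep(FALSE, n)
  volumes <- list(); centers <- list()
  for (i in seq_len(n)) {
    if (drivers[i] == "Cre" && i == 1L) {
      # broad pan-neuronal analogue: uniform strong expression over the brain
      exclude[i] <- TRUE
      volumes[[ids[i]]] <- vx_volume(
        array(200 * phantom$brain_mask$data, spec$dims),
        spacing_um = spec$spacing_um, value_kind = "normalized8",
        channel = ids[i])
      centers[[ids[i]]] <- matrix(numeric(0), ncol = 3)
    } else {
      lv <- make_line_volume(phantom$brain_mask,
                             n_clusters = spec$clusters_per_line,
                             radius_um = spec$cluster_radius_um,
                             seed = seed * 1000L + i,
                             peak_range = spec$intensity_range,
                             channel = ids[i])
      volumes[[ids[i]]] <- lv$volume
      centers[[ids[i]]] <- lv$centers
    }
  }
  lines <- data.frame(
    line_id = ids, driver = drivers, construction = construction,
    cell_threshold = thresholds, n_averaged = n_averaged,
    exclude_from_coverage = exclude,
    mapped_chrom = ifelse(mapped, sprintf("chr%d", sample(1:25, n, replace = TRUE)), NA),
    mapped_pos = ifelse(mapped, sample.int(5e7, n), NA),
    zfin_id = NA_character_, stringsAsFactors = FALSE)
  volume_paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_volume(phantom$brain_mask, file.path(dir, "brain_mask.nii.gz"))
    write_volume(phantom$soma, file.path(dir, "soma.nii.gz"))
    write_volume(phantom$neuropil, file.path(dir, "neuropil.nii.gz"))
    volume_paths <- stats::setNames(file.path(dir, paste0(ids, ".nii.gz")), ids)
    for (id in ids) write_volume(volumes[[id]], volume_paths[[id]])
    write_registry(lines, file.path(dir, "registry.tsv"),
                   header_lines = sprintf("synthetic line registry, seed %d", seed))
  }
  reg <- atlas_registry(lines, grid = vx_grid(phantom$brain_mask),
                        brain_mask = phantom$brain_mask,
                        volume_paths = volume_paths)
  list(registry = reg, volumes = volumes, brain_mask = phantom$brain_mask,
       soma = phantom$soma, neuropil = phantom$neuropil, centers = centers)
}

#' Simulate neuron counts for a sampling plan
#'
#' Emulates manual neuron counting in the planned 30 um volumes: each box in
#' bin b draws Poisson(`densities[b] * box_volume`) neurons. The ground-truth
#' total implied by the per-bin densities is returned for estimator checks:
#' `true_total = sum_b densities[b] * fraction_b * brain_volume`.
#'
#' @param binning a `density_binning`.
#' @param densities per-bin neuron densities in neurons per um^3.
#' @param plan a `sample_plan` drawn from `binning`.
#' @param seed integer RNG seed.
#' @return List with `plan` (counts attached), `counts`, `true_total`.
#' @export
make_nuclei_counts <- function(binning, densities, plan, seed = 1) {
  stopifnot(inherits(binning, "density_binning"), inherits(plan, "sample_plan"))
  if (length(densities) != binning$n_bins)
    stop(sprintf("need %d densities (one per bin)", binning$n_bins), call. = FALSE)
  if (any(densities < 0)) stop("densities must be non-negative", call. = FALSE)
  set.seed(as.integer(seed))
  lambda <- densities[plan$boxes$bin] * plan$box_volume_um3
  counts <- stats::rpois(nrow(plan$boxes), lambda)
  true_total <- sum(densities * binning$bin_fractions) * binning$brain_volume_um3
  list(plan = set_counts(plan, counts), counts = counts,
       true_total = true_total)
}
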