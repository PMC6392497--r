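#' Default toolkit configuration
#'
#' All tunable defaults in one place: 8-bit normalization saturates the top
#' 1e-4 of pixels; the search index downsamples masks 4x and packs 8x8x8
#' blocks; expression bins are 20 um cubes; neuron estimation uses 5 density
#' bins sampled with 5 boxes of 30 um edge each against a 92,000-neuron
#' whole-brain reference; pool deconvolution calls a site at >= 10 reads in
#' both pools of a pair with <= 2 background reads elsewhere, merging sites
#' within 100 bp. Every value can be overridden by a YAML config file and by
#' command-line flags (flags win), and is recorded in output provenance
#' headers.
#'
#' @return Named list of defaults.
#' @export
voxatlas_defaults <- function() {
  list(
    saturation_fraction = 1e-4,
    downsample = 4L,
    block_edge = 8L,
    bin_edge_um = 20,
    n_density_bins = 5L,
    boxes_per_bin = 5L,
    sample_edge_um = 30,
    total_neurons = 92000L,
    cellbody_ratio = 0.5,
    pool_min_reads = 10L,
    pool_max_bg_reads = 2L,
    pool_presence_min = 1L,
    merge_window_bp = 100L,
    min_cells = 1L
  )
}

#' Load configuration, merging a YAML file over the defaults
#'
#' @param path optional YAML file; unknown keys are rejected.
#' @return Named list of settings.
#' @export
load_config <- function(path = NULL) {
  cfg <- voxatlas_defaults()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    over <- yaml::read_yaml(path)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  cfg
}

provenance_header <- function(cfg, seed = NULL, extra = NULL) {
  c(sprintf("voxatlas %s", as.character(utils::packageVersion("voxatlas"))),
    sprintf("config: %s", paste(sprintf("%s=%s", names(cfg),
                                        vapply(cfg, format, "")), collapse = " ")),
    if (!is.null(seed)) sprintf("seed: %d", as.integer(seed)),
    extra)
}
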