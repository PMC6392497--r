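#' Line registry
#'
#' The registry is the ordered collection of transgenic line records that
#' defines the line order of the search index. Each record carries the driver
#' type (Gal4, Cre or FP reporter), how the line was constructed, the
#' manually defined cellular intensity threshold on the normalized 0..255
#' scale, how many larvae were averaged into the representative image,
#' whether to exclude the line from library coverage statistics (used for
#' lines with extremely broad, near pan-neuronal expression), and the mapped
#' integration locus where known.
#'
#' @param lines data.frame with columns `line_id`, `driver` (Gal4/Cre/FP),
#'   `construction` (enhancer_trap/promoter_transgenic/BAC), `cell_threshold`
#'   (0..255), `n_averaged` (>= 1), `exclude_from_coverage` (logical),
#'   `mapped_chrom`, `mapped_pos`, `zfin_id` (last three may be NA).
#' @param grid optional grid (see [vx_grid]) of the atlas.
#' @param brain_mask optional binary [vx_volume] brain mask on that grid.
#' @param volume_paths optional named character vector, line_id -> file path.
#' @return An object of class `atlas_registry`.
#' @export
atlas_registry <- function(lines, grid = NULL, brain_mask = NULL,
                           volume_paths = NULL) {
  lines <- validate_line_records(lines)
  if (!is.null(brain_mask)) {
    stopifnot(inherits(brain_mask, "vx_volume"))
    check_binary(brain_mask, "brain_mask")
    if (!is.null(grid) &&
        !identical(as.integer(dim(brain_mask$data)), as.integer(grid$dims)))
      stop("brain_mask is not on the registry grid", call. = FALSE)
    if (is.null(grid)) grid <- vx_grid(brain_mask)
  }
  structure(list(lines = lines, grid = grid, brain_mask = brain_mask,
                 volume_paths = volume_paths),
            class = "atlas_registry")
}

registry_columns <- c("line_id", "driver", "construction", "cell_threshold",
                      "n_averaged", "exclude_from_coverage",
                      "mapped_chrom", "mapped_pos", "zfin_id")

validate_line_records <- function(lines) {
  stopifnot(is.data.frame(lines))
  missing_cols <- setdiff(registry_columns, names(lines))
  if (length(missing_cols))
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  lines <- lines[registry_columns]
  if (anyDuplicated(lines$line_id))
    stop("duplicate line_id in registry: ",
         paste(unique(lines$line_id[duplicated(lines$line_id)]), collapse = ", "),
         call. = FALSE)
  bad <- !lines$driver %in% c("Gal4", "Cre", "FP")
  if (any(bad))
    stop("unknown driver for line(s): ", paste(lines$line_id[bad], collapse = ", "),
         call. = FALSE)
  if (any(lines$cell_threshold < 0 | lines$cell_threshold > 255))
    stop("cell_threshold must be within the normalized range [0, 255]", call. = FALSE)
  if (any(lines$n_averaged < 1)) stop("n_averaged must be >= 1", call. = FALSE)
  low <- lines$n_averaged < 3
  if (any(low))
    warning("line(s) averaged from fewer than 3 larvae: ",
            paste(lines$line_id[low], collapse = ", "), call. = FALSE)
  lines$exclude_from_coverage <- as.logical(lines$exclude_from_coverage)
  lines
}

#' @export
print.atlas_registry <- function(x, ...) {
  cat(sprintf("<atlas_registry> %d lines (%s)\n", nrow(x$lines),
              paste(sprintf("%s: %d", names(table(x$lines$driver)),
                            as.integer(table(x$lines$driver))), collapse = ", ")))
  invisible(x)
}

#' Read / write a line registry TSV
#'
#' Tab-separated with header
#' `line_id driver construction cell_threshold n_averaged exclude_from_coverage
#' mapped_chrom mapped_pos zfin_id`; lines starting with `#` are comments.
#'
#' @param path TSV path.
#' @return For `read_registry`, a validated line-record data.frame.
#' @export
read_registry <- function(path) {
  if (!file.exists(path))
    stop(sprintf("registry file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_line_records(df)
}

#' @rdname read_registry
#' @param lines line-record data.frame.
#' @param header_lines optional character vector of provenance comment lines
#'   written before the header (each prefixed `# `).
#' @export
write_registry <- function(lines, path, header_lines = NULL) {
  lines <- suppressWarnings(validate_line_records(lines))
  con <- file(path, "w"); on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(lines, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published line-library composition summary
#'
#' Per-category line counts of the 264-line ZBB2 transgenic library
#' (enhancer-trap vs promoter/BAC transgenic, by Gal4/Cre/FP driver), with the
#' number of lines per category whose genomic driver locus is known. Shipped
#' as a plain-text fixture and used for bookkeeping checks.
#'
#' @return data.frame with columns `construction`, `driver`, `n_lines`,
#'   `n_mapped`.
#' @export
zbb2_line_summary <- function() {
  path <- system.file("extdata", "zbb2_line_summary.tsv", package = "voxatlas")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
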