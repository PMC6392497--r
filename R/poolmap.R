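#' Design a combinatorial sequencing pool layout
#'
#' Assigns each line to a distinct unordered pair of pools so that every line
#' is exclusively represented in exactly two pools; a genomic site enriched
#' in exactly one pool pair then identifies its line. With `n_pools` pools at
#' most `choose(n_pools, 2)` lines can be deconvolved. Pairs are assigned
#' greedily to the least-loaded pools (seed-shuffled tie-breaking), keeping
#' pool sizes balanced; deterministic given `seed`.
#'
#' @param line_ids character vector of line ids.
#' @param n_pools number of pools (e.g. 15).
#' @param seed integer RNG seed for tie shuffling.
#' @return Object of class `pool_design`: `n_pools` and `assignment`, a
#'   data.frame `line_id, pool1, pool2` with 1-based pool indices,
#'   `pool1 < pool2`.
#' @export
design_pools <- function(line_ids, n_pools, seed = 1) {
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids)) stop("duplicate line ids", call. = FALSE)
  n_pools <- as.integer(n_pools)
  if (n_pools < 2) stop("`n_pools` must be >= 2", call. = FALSE)
  capacity <- choose(n_pools, 2)
  if (length(line_ids) > capacity)
    stop(sprintf("%d lines exceed the capacity of %d pools: at most choose(%d, 2) = %d distinct pool pairs",
                 length(line_ids), n_pools, n_pools, capacity), call. = FALSE)
  pairs <- t(utils::combn(n_pools, 2))
  set.seed(as.integer(seed))
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]  # shuffled tie order
  used <- logical(nrow(pairs))
  load <- integer(n_pools)
  out <- matrix(0L, nrow = length(line_ids), ncol = 2)
  for (i in seq_along(line_ids)) {
    avail <- which(!used)
    pair_load <- load[pairs[avail, 1]] + load[pairs[avail, 2]]
    pick <- avail[which.min(pair_load)]
    out[i, ] <- pairs[pick, ]
    used[pick] <- TRUE
    load[pairs[pick, ]] <- load[pairs[pick, ]] + 1L
  }
  structure(list(n_pools = n_pools,
                 assignment = data.frame(line_id = line_ids,
                                         pool1 = out[, 1], pool2 = out[, 2],
                                         stringsAsFactors = FALSE)),
            class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  load <- tabulate(c(x$assignment$pool1, x$assignment$pool2), x$n_pools)
  cat(sprintf("<pool_design> %d lines over %d pools (pool sizes %d-%d)\n",
              nrow(x$assignment), x$n_pools, min(load), max(load)))
  invisible(x)
}

pool_cols <- function(table) grep("^pool_", names(table), value = TRUE)

validate_site_table <- function(table) {
  stopifnot(is.data.frame(table))
  pc <- pool_cols(table)
  if (!all(c("chrom", "pos") %in% names(table)) || length(pc) == 0)
    stop("site table needs columns chrom, pos, pool_0 ... pool_{P-1}", call. = FALSE)
  if (nrow(table) == 0) stop("site table is empty", call. = FALSE)
  if (any(table$pos < 0)) stop("positions must be non-negative", call. = FALSE)
  if (any(as.matrix(table[pc]) < 0))
    stop("pool counts must be non-negative", call. = FALSE)
  table
}

#' Remove off-target sites present in every pool
#'
#' Sequences recovered in all pools cannot come from any single line (each
#' line occupies only two pools) and are treated as off-target capture. A
#' site is "present" in a pool iff its count is at least `presence_min`.
#' Idempotent.
#'
#' @param table site table: data.frame with columns `chrom`, `pos` and
#'   `pool_0 ... pool_{P-1}` of non-negative read counts.
#' @param presence_min minimum count for presence (default 1).
#' @return List with `table` (retained sites) and `removed` (off-target rows).
#' @export
filter_offtarget <- function(table, presence_min = 1) {
  table <- validate_site_table(table)
  if (presence_min < 1) stop("`presence_min` must be >= 1", call. = FALSE)
  counts <- as.matrix(table[pool_cols(table)])
  everywhere <- rowSums(counts >= presence_min) == ncol(counts)
  list(table = table[!everywhere, , drop = FALSE],
       removed = table[everywhere, , drop = FALSE])
}

#' Merge nearby integration sites
#'
#' Read scatter around a true integration point produces clusters of
#' positions; sites on the same chromosome within `window` bp of the running
#' cluster start are merged (counts summed, position = cluster start) before
#' assignment.
#'
#' @param table site table.
#' @param window merge window in bp (default 100).
#' @return Merged site table.
#' @export
merge_sites <- function(table, window = 100) {
  table <- validate_site_table(table)
  pc <- pool_cols(table)
  table <- table[order(table$chrom, table$pos), , drop = FALSE]
  cluster <- integer(nrow(table))
  cid <- 0L; last_chrom <- NULL; start_pos <- -Inf
  for (i in seq_len(nrow(table))) {
    if (is.null(last_chrom) || table$chrom[i] != last_chrom ||
        table$pos[i] - start_pos > window) {
      cid <- cid + 1L
      last_chrom <- table$chrom[i]
      start_pos <- table$pos[i]
    }
    cluster[i] <- cid
  }
  merged <- do.call(rbind, lapply(split(seq_len(nrow(table)), cluster), function(idx) {
    row <- table[idx[1], c("chrom", "pos"), drop = FALSE]
    cbind(row, as.data.frame(t(colSums(table[idx, pc, drop = FALSE]))))
  }))
  rownames(merged) <- NULL
  merged
}

#' Assign candidate integration sites to lines
#'
#' A site is assigned to line L iff it shows high and specific enrichment in
#' L's pool pair: count >= `min_reads` in BOTH of L's pools AND count <=
#' `max_bg_reads` in every other pool. Because pool pairs are distinct, a
#' site can satisfy this for at most one line. Unassigned sites are reported
#' with a reason: `below_enrichment` when the site's high pools are a strict
#' subset of some line's pair (signal too weak or background too high for
#' that pair), otherwise `no_matching_signature` (its high pools match no
#' pair). Sites are merged within `merge_window` bp first.
#'
#' @param table site table, already off-target filtered.
#' @param design a `pool_design`; the table must have one `pool_` column per
#'   design pool.
#' @param min_reads minimum count in both pools of the pair (default 10).
#' @param max_bg_reads maximum count tolerated in any other pool (default 2);
#'   must be < `min_reads`.
#' @param merge_window bp window for pre-merging sites (default 100; 0
#'   disables).
#' @return Object of class `site_assignment`: `assigned` (data.frame
#'   `line_id, chrom, pos`), `unassigned` (data.frame `chrom, pos, reason`).
#' @export
assign_sites <- function(table, design, min_reads = 10, max_bg_reads = 2,
                         merge_window = 100) {
  table <- validate_site_table(table)
  stopifnot(inherits(design, "pool_design"))
  if (!(min_reads > max_bg_reads && max_bg_reads >= 0))
    stop("need min_reads > max_bg_reads >= 0", call. = FALSE)
  pc <- pool_cols(table)
  if (length(pc) != design$n_pools)
    stop(sprintf("table has %d pool columns but design has %d pools",
                 length(pc), design$n_pools), call. = FALSE)
  if (merge_window > 0) table <- merge_sites(table, merge_window)
  counts <- as.matrix(table[pc])
  asg <- design$assignment
  assigned <- list(); unassigned <- list()
  for (i in seq_len(nrow(table))) {
    high <- which(counts[i, ] >= min_reads)
    low_ok <- counts[i, ] <= max_bg_reads
    hit <- which(vapply(seq_len(nrow(asg)), function(j) {
      pr <- c(asg$pool1[j], asg$pool2[j])
      all(pr %in% high) && all(low_ok[-pr])
    }, logical(1)))
    if (length(hit) == 1L) {
      assigned[[length(assigned) + 1L]] <-
        data.frame(line_id = asg$line_id[hit], chrom = table$chrom[i],
                   pos = table$pos[i], stringsAsFactors = FALSE)
    } else {
      partial <- any(vapply(seq_len(nrow(asg)), function(j) {
        pr <- c(asg$pool1[j], asg$pool2[j])
        all(high %in% pr)
      }, logical(1)))
      reason <- if (partial) "below_enrichment" else "no_matching_signature"
      unassigned[[length(unassigned) + 1L]] <-
        data.frame(chrom = table$chrom[i], pos = table$pos[i],
                   reason = reason, stringsAsFactors = FALSE)
    }
  }
  empty_a <- data.frame(line_id = character(), chrom = character(),
                        pos = integer(), stringsAsFactors = FALSE)
  empty_u <- data.frame(chrom = character(), pos = integer(),
                        reason = character(), stringsAsFactors = FALSE)
  structure(list(
    assigned = if (length(assigned)) do.call(rbind, assigned) else empty_a,
    unassigned = if (length(unassigned)) do.call(rbind, unassigned) else empty_u
  ), class = "site_assignment")
}

#' @export
print.site_assignment <- function(x, ...) {
  cat(sprintf("<site_assignment> %d assigned, %d unassigned\n",
              nrow(x$assigned), nrow(x$unassigned)))
  if (nrow(x$unassigned))
    print(table(x$unassigned$reason))
  invisible(x)
}

#' Simulate a pooled integration-site sequencing experiment
#'
#' Test harness for the deconvolution procedure: each planted line's site
#' receives Poisson(`signal_reads`) counts in that line's two pools, every
#' (site, pool) cell receives Poisson(`noise_rate`) background, and
#' `n_offtarget` extra sites are present in all pools. Deterministic given
#' `seed`.
#'
#' @param design a `pool_design`.
#' @param planted data.frame `line_id, chrom, pos` of true integration sites
#'   (line ids must be in the design).
#' @param signal_reads mean on-target reads per pool (default 100).
#' @param noise_rate mean background reads per (site, pool) cell (default 0.2).
#' @param n_offtarget number of all-pool off-target sites (default 5).
#' @param seed integer RNG seed.
#' @return List with `table` (site table) and `truth` (the planted
#'   data.frame).
#' @export
simulate_pool_experiment <- function(design, planted, signal_reads = 100,
                                     noise_rate = 0.2, n_offtarget = 5,
                                     seed = 1) {
  stopifnot(inherits(design, "pool_design"), is.data.frame(planted))
  if (signal_reads < 0 || noise_rate < 0 || n_offtarget < 0)
    stop("parameters must be non-negative", call. = FALSE)
  bad <- setdiff(planted$line_id, design$assignment$line_id)
  if (length(bad))
    stop("planted line(s) not in design: ", paste(bad, collapse = ", "),
         call. = FALSE)
  set.seed(as.integer(seed))
  P <- design$n_pools
  n_sites <- nrow(planted) + n_offtarget
  counts <- matrix(stats::rpois(n_sites * P, noise_rate), nrow = n_sites)
  asg <- design$assignment
  for (i in seq_len(nrow(planted))) {
    j <- match(planted$line_id[i], asg$line_id)
    pr <- c(asg$pool1[j], asg$pool2[j])
    counts[i, pr] <- counts[i, pr] + stats::rpois(2, signal_reads)
  }
  chrom <- c(planted$chrom, rep("chrU", n_offtarget))
  pos <- c(planted$pos,
           if (n_offtarget > 0) sample.int(1e7, n_offtarget) else integer())
  if (n_offtarget > 0) {
    ot_rows <- nrow(planted) + seq_len(n_offtarget)
    counts[ot_rows, ] <- counts[ot_rows, ] +
      1L + matrix(stats::rpois(n_offtarget * P, signal_reads), nrow = n_offtarget)
  }
  tab <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  for (p in seq_len(P)) tab[[sprintf("pool_%d", p - 1L)]] <- counts[, p]
  list(table = tab, truth = planted)
}

#' Read / write site tables and assignments
#'
#' Site tables are TSV with header `chrom pos pool_0 ... pool_{P-1}`;
#' assignments can also be written as BED (0-based half-open, name =
#' line_id).
#'
#' @param path file path.
#' @return For `read_site_table`, a validated site table.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("site table not found: %s", path), call. = FALSE)
  validate_site_table(utils::read.delim(path, comment.char = "#",
                                        stringsAsFactors = FALSE))
}

#' @rdname read_site_table
#' @param table site table.
#' @param header_lines optional provenance comment lines.
#' @export
write_site_table <- function(table, path, header_lines = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_site_table
#' @param assignment a `site_assignment`.
#' @export
write_assignment_bed <- function(assignment, path) {
  stopifnot(inherits(assignment, "site_assignment"))
  a <- assignment$assigned
  bed <- data.frame(chrom = a$chrom, start = a$pos, end = a$pos + 1L,
                    name = a$line_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
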