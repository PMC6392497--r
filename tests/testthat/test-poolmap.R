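# Pool design, off-target filtering, site assignment, simulation.

test_that("design_pools gives every line a distinct pair and balances pools", {
  d1 <- design_pools("only", 2)
  expect_equal(sort(unname(unlist(d1$assignment[1, c("pool1", "pool2")]))),
               c(1, 2))

  # capacity: choose(15, 2) = 105 lines fit; the 106th does not
  ok <- design_pools(sprintf("l%03d", 1:105), 15, seed = 1)
  expect_equal(nrow(ok$assignment), 105)
  expect_error(design_pools(sprintf("l%03d", 1:106), 15),
               "choose\\(15, 2\\) = 105")

  d <- design_pools(sprintf("l%02d", 1:55), 15, seed = 2)
  a <- d$assignment
  pairs <- paste(pmin(a$pool1, a$pool2), pmax(a$pool1, a$pool2))
  expect_equal(anyDuplicated(pairs), 0)
  expect_true(all(a$pool1 != a$pool2))
  load <- tabulate(c(a$pool1, a$pool2), 15)
  expect_lte(max(load) - min(load), 1)
})

test_that("design invariants hold over randomized sizes", {
  set.seed(3)
  for (trial in 1:20) {
    np <- sample(4:12, 1)
    nl <- sample.int(choose(np, 2), 1)
    d <- design_pools(sprintf("x%03d", seq_len(nl)), np, seed = trial)
    a <- d$assignment
    expect_true(all(a$pool1 >= 1 & a$pool2 <= np & a$pool1 != a$pool2))
    expect_equal(anyDuplicated(paste(a$pool1, a$pool2)), 0)
  }
})

make_table <- function(counts, chrom = NULL, pos = NULL) {
  n <- nrow(counts)
  df <- data.frame(chrom = chrom %||% rep("chr1", n),
                   pos = pos %||% (seq_len(n) * 1000L))
  for (p in seq_len(ncol(counts))) df[[sprintf("pool_%d", p - 1)]] <- counts[, p]
  df
}

test_that("filter_offtarget removes exactly the sites present in all pools", {
  tab <- make_table(rbind(c(5, 5, 5, 5),    # everywhere -> removed
                          c(9, 0, 0, 0),    # one pool -> retained
                          c(3, 3, 0, 3)))   # missing one pool -> retained
  f <- filter_offtarget(tab)
  expect_equal(f$removed$pos, 1000)
  expect_equal(f$table$pos, c(2000, 3000))

  set.seed(4)
  counts <- matrix(stats::rpois(50 * 6, 1.2), ncol = 6)
  rt <- make_table(counts)
  got <- filter_offtarget(rt, presence_min = 2)
  oracle <- which(apply(counts >= 2, 1, all))
  expect_equal(got$removed$pos, rt$pos[oracle])
  # idempotent
  again <- filter_offtarget(got$table, presence_min = 2)
  expect_equal(again$table, got$table)
  expect_equal(nrow(again$removed), 0)

  expect_error(filter_offtarget(tab[0, ]), "empty")
})

test_that("merge_sites clusters nearby positions and sums counts", {
  tab <- make_table(rbind(c(10, 0), c(5, 1), c(0, 8)),
                    chrom = c("chr1", "chr1", "chr2"),
                    pos = c(100L, 150L, 120L))
  m <- merge_sites(tab, window = 100)
  expect_equal(nrow(m), 2)
  chr1 <- m[m$chrom == "chr1", ]
  expect_equal(chr1$pos, 100)
  expect_equal(c(chr1$pool_0, chr1$pool_1), c(15, 1))
})

test_that("assign_sites requires high, specific enrichment in exactly one pair", {
  design <- design_pools(c("A", "B", "C"), 5, seed = 1)
  prA <- unlist(design$assignment[1, c("pool1", "pool2")])
  counts <- matrix(0L, nrow = 3, ncol = 5)
  counts[1, prA] <- 50L                      # clean signature for A
  counts[2, 1:3] <- 40L                      # high in three pools
  counts[3, prA[1]] <- 40L                   # only half of A's pair
  tab <- make_table(counts)

  asg <- assign_sites(tab, design, min_reads = 10, max_bg_reads = 2)
  expect_equal(asg$assigned$line_id, "A")
  expect_equal(asg$assigned$pos, 1000)
  reasons <- asg$unassigned$reason[order(asg$unassigned$pos)]
  expect_equal(reasons, c("no_matching_signature", "below_enrichment"))

  # monotone in min_reads: raising it never adds assignments
  loose <- assign_sites(tab, design, min_reads = 10, max_bg_reads = 2)
  strict <- assign_sites(tab, design, min_reads = 60, max_bg_reads = 2)
  expect_true(all(strict$assigned$pos %in% loose$assigned$pos))

  expect_error(assign_sites(tab, design, min_reads = 2, max_bg_reads = 2),
               "min_reads > max_bg_reads")
  expect_error(assign_sites(make_table(matrix(1L, 2, 3)), design), "pool columns")
})

test_that("simulated experiments are deterministic and clean without noise", {
  design <- design_pools(sprintf("L%02d", 1:10), 6, seed = 5)
  planted <- data.frame(line_id = sprintf("L%02d", 1:10), chrom = "chr2",
                        pos = seq_len(10) * 5000L)
  s1 <- simulate_pool_experiment(design, planted, seed = 9)
  s2 <- simulate_pool_experiment(design, planted, seed = 9)
  expect_identical(s1$table, s2$table)

  clean <- simulate_pool_experiment(design, planted, noise_rate = 0,
                                    n_offtarget = 0, seed = 10)
  counts <- as.matrix(clean$table[grep("^pool_", names(clean$table))])
  for (i in 1:10) {
    pr <- unlist(design$assignment[i, c("pool1", "pool2")])
    expect_true(all(counts[i, -pr] == 0))
  }
  expect_error(simulate_pool_experiment(design,
                                        data.frame(line_id = "zz", chrom = "c",
                                                   pos = 1L)),
               "not in design")
})

test_that("deconvolution recovers planted sites with perfect precision and high recall", {
  n_lines <- 50
  ids <- sprintf("L%02d", seq_len(n_lines))
  design <- design_pools(ids, 15, seed = 1)
  planted <- data.frame(line_id = ids, chrom = "chr3",
                        pos = seq_len(n_lines) * 10000L)
  tp <- 0L; fp <- 0L; total <- 0L
  for (seed in 1:20) {
    sim <- simulate_pool_experiment(design, planted, signal_reads = 100,
                                    noise_rate = 0.2, n_offtarget = 5,
                                    seed = seed)
    filtered <- filter_offtarget(sim$table)
    asg <- assign_sites(filtered$table, design)
    key_truth <- paste(planted$line_id, planted$pos)
    key_got <- paste(asg$assigned$line_id, asg$assigned$pos)
    tp <- tp + sum(key_got %in% key_truth)
    fp <- fp + sum(!key_got %in% key_truth)
    total <- total + n_lines
  }
  precision <- tp / (tp + fp)
  recall <- tp / total
  expect_equal(precision, 1.0)
  expect_gte(recall, 0.95)
})

test_that("site tables and assignments round trip through disk formats", {
  tab <- make_table(matrix(c(20L, 20L, 0L, 0L, 1L, 0L), nrow = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(tab, path, header_lines = "fixture")
  expect_equal(read_site_table(path), tab)

  design <- design_pools(c("A", "B"), 3, seed = 1)
  counts <- matrix(0L, 1, 3)
  counts[1, unlist(design$assignment[1, c("pool1", "pool2")])] <- 30L
  asg <- assign_sites(make_table(counts), design)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_assignment_bed(asg, bed)
  lines <- readLines(bed)
  expect_match(lines[1], "^chr1\t1000\t1001\tA$")
})
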