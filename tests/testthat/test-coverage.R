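# Cell-body mask, per-line coverage, count maps, library summaries.

test_that("cellbody_mask applies the soma-fraction ratio rule", {
  dims <- c(10, 8, 6)
  brain <- rand_mask(dims, p = 0.7, seed = 1)
  soma <- rand_volume(dims, seed = 2)
  zero <- vx_volume(array(0, dims))

  # neuropil everywhere zero, soma positive -> ratio 1 -> whole brain
  pos <- vx_volume(array(10, dims))
  expect_equal(cellbody_mask(pos, zero, brain)$data, brain$data)
  # soma everywhere zero -> empty mask
  expect_equal(sum(cellbody_mask(zero, pos, brain)$data), 0)

  neuropil <- rand_volume(dims, seed = 3)
  got <- cellbody_mask(soma, neuropil, brain, ratio_threshold = 0.5)
  oracle <- array(0L, dims)
  for (i in seq_along(oracle)) {
    tot <- soma$data[i] + neuropil$data[i]
    if (brain$data[i] == 1 && tot > 0 && soma$data[i] / tot >= 0.5)
      oracle[i] <- 1L
  }
  expect_equal(got$data, oracle)
  expect_error(cellbody_mask(soma, neuropil, brain, ratio_threshold = 1),
               "\\(0, 1\\)")
  expect_error(cellbody_mask(soma, rand_volume(c(2, 2, 2)), brain),
               "grid mismatch")
})

test_that("line_coverage counts super-threshold mask voxels", {
  dims <- c(10, 10, 4)
  mask <- rand_mask(dims, p = 0.5, seed = 4)
  rec <- list(line_id = "l1", cell_threshold = 50)

  bright <- vx_volume(array(255, dims), value_kind = "normalized8")
  expect_equal(line_coverage(bright, rec, mask)$coverage_fraction, 1.0)

  dark <- vx_volume(array(0, dims), value_kind = "normalized8")
  expect_equal(line_coverage(dark, list(line_id = "l1", cell_threshold = 1),
                             mask)$coverage_fraction, 0.0)

  # constructed phantom with exactly half of the mask covered
  half_mask <- vx_volume(array(0L, c(8, 8, 8)), value_kind = "binary")
  half_mask$data[, , 1:4] <- 1L
  line <- vx_volume(array(0, c(8, 8, 8)), value_kind = "normalized8")
  line$data[, , 1:2] <- 200
  cov <- line_coverage(line, rec, half_mask)
  expect_identical(cov$coverage_fraction, 0.5)
  expect_equal(cov$covered_voxels, 128)
  expect_equal(cov$mask_voxels, 256)

  empty <- vx_volume(array(0L, dims), value_kind = "binary")
  expect_error(line_coverage(bright, rec, empty), "empty")
})

test_that("line_count_map sums binarized lines and conserves coverage", {
  dims <- c(12, 10, 6)
  mask <- rand_mask(dims, p = 0.6, seed = 5)
  K <- 4
  records <- data.frame(line_id = sprintf("l%d", 1:K),
                        cell_threshold = c(40, 60, 80, 100),
                        exclude_from_coverage = FALSE)
  vols <- lapply(1:K, function(i) rand_volume(dims, seed = 10 + i,
                                              kind = "normalized8", max = 255))
  names(vols) <- records$line_id

  cm <- line_count_map(vols, records, mask)
  oracle <- array(0L, dims)
  for (i in 1:K) oracle <- oracle + (vols[[i]]$data >= records$cell_threshold[i])
  expect_equal(cm$data, array(as.integer(oracle * mask$data), dims))

  reports <- do.call(rbind, lapply(1:K, function(i)
    line_coverage(vols[[i]], records[i, ], mask)))
  expect_equal(sum(cm$data), sum(reports$covered_voxels))  # conservation

  # identical full-coverage lines -> constant K inside the mask
  full <- vx_volume(array(255, dims), value_kind = "normalized8")
  cmK <- line_count_map(stats::setNames(rep(list(full), K), records$line_id),
                        records, mask)
  expect_true(all(cmK$data[mask$data == 1] == K))
  expect_true(all(cmK$data[mask$data == 0] == 0))

  # disjoint lines -> counts in {0, 1}
  a <- vx_volume(array(0, dims), value_kind = "normalized8"); a$data[1:6, , ] <- 255
  b <- vx_volume(array(0, dims), value_kind = "normalized8"); b$data[7:12, , ] <- 255
  cm2 <- line_count_map(list(l1 = a, l2 = b), records[1:2, ], mask)
  expect_true(all(cm2$data %in% 0:1))

  expect_error(line_count_map(vols, records[0, ], mask), "no lines")
})

test_that("library_summary reports union coverage, per-voxel mean and the line distribution", {
  dims <- c(10, 10, 4)
  mask <- vx_volume(array(1L, dims), value_kind = "binary")
  records <- data.frame(line_id = "l1", cell_threshold = 50,
                        exclude_from_coverage = FALSE)
  full <- vx_volume(array(255, dims), value_kind = "normalized8")
  cm <- line_count_map(list(l1 = full), records, mask)
  rep1 <- line_coverage(full, records[1, ], mask)
  s <- library_summary(cm, mask, rep1)
  expect_equal(s$fraction_covered_ge1, 1.0)
  expect_equal(s$mean_lines_per_voxel, 1.0)

  dark <- vx_volume(array(0, dims), value_kind = "normalized8")
  cm0 <- line_count_map(list(l1 = dark), records, mask)
  s0 <- library_summary(cm0, mask, line_coverage(dark, records[1, ], mask))
  expect_equal(s0$fraction_covered_ge1, 0.0)
  expect_equal(s0$mean_lines_per_voxel, 0.0)

  # planted per-line coverages are recovered in the distribution summary
  planted <- c(0.1, 0.25, 0.5)
  mk <- function(frac) {
    v <- vx_volume(array(0, dims), value_kind = "normalized8")
    v$data[seq_len(frac * prod(dims))] <- 255
    v
  }
  recs <- data.frame(line_id = sprintf("p%d", 1:3), cell_threshold = 50,
                     exclude_from_coverage = FALSE)
  vols <- stats::setNames(lapply(planted, mk), recs$line_id)
  reports <- do.call(rbind, lapply(1:3, function(i)
    line_coverage(vols[[i]], recs[i, ], mask)))
  expect_equal(reports$coverage_fraction, planted)
  s3 <- library_summary(line_count_map(vols, recs, mask), mask, reports)
  expect_equal(s3$median_coverage, 0.25)
  expect_equal(s3$coverage_range, c(0.1, 0.5))
  expect_equal(sum(s3$hist_counts), 3)

  # union coverage is monotone as lines are added
  s2 <- library_summary(line_count_map(vols[1:2], recs[1:2, ], mask), mask,
                        reports[1:2, ])
  expect_gte(s3$fraction_covered_ge1, s2$fraction_covered_ge1)
})

test_that("neurons_per_line rounds coverage x total to significant figures", {
  expect_equal(neurons_per_line(0.06, 92000), 5500)
  expect_equal(neurons_per_line(0, 1e6), 0)
  expect_equal(neurons_per_line(1.0, 92000), 92000)
  expect_equal(neurons_per_line(0.0123, 92000, sig_figs = 3), 1130)
  expect_error(neurons_per_line(1.2, 92000), "\\[0, 1\\]")
})
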