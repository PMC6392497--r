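# Binarization, max-pool downsampling, bit packing, fragment store, search.

test_that("binarize applies >= threshold and validates inputs", {
  v <- rand_volume(c(10, 8, 6), seed = 1, kind = "normalized8", max = 255)
  expect_true(all(binarize(v, 0)$data == 1))  # every intensity >= 0
  expect_error(binarize(v, 256), "\\[0, 255\\]")
  expect_error(binarize(rand_volume(c(4, 4, 4)), 10), "normalized8")

  got <- binarize(v, 100)
  expect_equal(got$data, array(as.integer(v$data >= 100), dim(v$data)))
  expect_equal(got$value_kind, "binary")
})

test_that("downsample_mask is an any-reduction over factor^3 cells", {
  m <- vx_volume(array(0L, c(16, 12, 8)), value_kind = "binary")
  m$data[7, 3, 5] <- 1L
  ds <- downsample_mask(m, 4)
  expect_equal(sum(ds$data), 1)
  expect_equal(which(ds$data == 1, arr.ind = TRUE)[1, ],
               c(dim1 = 2, dim2 = 1, dim3 = 2))
  expect_equal(ds$spacing_um, c(4, 4, 4))
  expect_equal(ds$downsample_factor, 4L)

  empty <- vx_volume(array(0L, c(9, 9, 9)), value_kind = "binary")
  expect_true(all(downsample_mask(empty, 4)$data == 0))

  # non-multiple dims: edge cells pool the truncated remainder
  r <- rand_mask(c(37, 22, 15), p = 0.05, seed = 2)
  expect_equal(downsample_mask(r, 4)$data, downsample_oracle(r$data, 4))
  expect_error(downsample_mask(r, 0), ">= 1")
})

test_that("pack_block packs LSB-first in x-fastest order and unpacks exactly", {
  expect_equal(pack_block(array(0L, c(8, 8, 8))), as.raw(rep(0, 64)))
  expect_equal(pack_block(array(1L, c(8, 8, 8))), as.raw(rep(255, 64)))

  single <- array(0L, c(8, 8, 8)); single[1, 1, 1] <- 1L
  payload <- pack_block(single)
  expect_equal(payload[1], as.raw(1))
  expect_true(all(payload[-1] == as.raw(0)))
  expect_equal(unpack_block(payload), single)

  set.seed(3)
  for (rep in 1:32) {
    bits <- array(as.integer(stats::runif(512) < 0.5), c(8, 8, 8))
    p <- pack_block(bits)
    expect_identical(p, pack_oracle(bits))
    expect_identical(unpack_block(p), bits)
  }
  expect_error(pack_block(array(0L, c(4, 4, 4))), "512")
  expect_error(unpack_block(as.raw(1:10)), "64")
})

test_that("fragments concatenate 64-byte slots per line and conserve bytes", {
  fx <- make_search_fixture(n_lines = 5, dims = c(40, 24, 16), seed = 10)
  store <- fx$store
  n_blocks <- prod(store$block_dims)
  expect_true(all(vapply(store$fragments, length, 0L) == 64L * 5L))
  expect_equal(sum(vapply(store$fragments, length, 0L)), 64 * n_blocks * 5)

  # unpacking each line's slot reproduces its (zero-padded) mask block
  d <- dim(fx$masks[[1]]$data)
  pd <- store$block_dims * 8L
  for (li in 1:5) {
    padded <- array(0L, pd)
    padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- fx$masks[[li]]$data
    for (bx in 0:(store$block_dims[1] - 1))
      for (by in 0:(store$block_dims[2] - 1))
        for (bz in 0:(store$block_dims[3] - 1)) {
          frag <- store$fragments[[sprintf("%d_%d_%d", bx, by, bz)]]
          slot <- unpack_block(frag[(li - 1) * 64 + 1:64])
          expect_identical(slot, padded[bx * 8 + 1:8, by * 8 + 1:8, bz * 8 + 1:8])
        }
  }

  one <- build_fragments("a", list(a = fx$masks[[1]]))
  expect_true(all(vapply(one$fragments, length, 0L) == 64L))
  expect_error(build_fragments(c("a", "b"), list(a = fx$masks[[1]])),
               "missing mask")
})

test_that("a 264-line library yields ~17 kb fragments", {
  set.seed(4)
  masks <- list()
  for (i in 1:264) {
    m <- rand_mask(c(16, 16, 16), p = 0.05)
    masks[[sprintf("l%03d", i)]] <- downsample_mask(m, 4)
  }
  store <- build_fragments(names(masks), masks)
  expect_true(all(vapply(store$fragments, length, 0L) == 16896L))
})

test_that("fragment store survives a disk round trip", {
  fx <- make_search_fixture(n_lines = 4, dims = c(20, 20, 12), seed = 11)
  dir <- withr::local_tempdir()
  write_fragment_store(fx$store, dir)
  back <- read_fragment_store(dir)
  expect_identical(back$fragments, fx$store$fragments)
  expect_identical(back$line_order, fx$store$line_order)
  expect_equal(back$factor, fx$store$factor)
  expect_error(read_fragment_store(file.path(dir, "missing")), "manifest")
})

test_that("spatial_search agrees exactly with the brute-force oracle", {
  fx <- make_search_fixture(n_lines = 20, dims = c(40, 24, 16), seed = 12)
  whole <- search_box(c(0, 0, 0), fx$dims)
  has_any <- names(fx$masks)[vapply(fx$masks, function(m) sum(m$data) > 0,
                                    TRUE)]
  expect_identical(spatial_search(fx$store, whole), has_any)

  set.seed(13)
  for (trial in 1:120) {
    lo <- c(sample.int(fx$dims[1], 1), sample.int(fx$dims[2], 1),
            sample.int(fx$dims[3], 1)) - 1L
    hi <- pmin(fx$dims, lo + c(sample.int(16, 1), sample.int(12, 1),
                               sample.int(8, 1)))
    box <- search_box(lo, hi)
    mc <- sample.int(4, 1)
    expect_identical(spatial_search(fx$store, box, mc),
                     brute_force_search(fx$masks, box, mc))
  }
})

test_that("empty masks match nothing and empty boxes are rejected", {
  empty <- downsample_mask(vx_volume(array(0L, c(16, 16, 16)),
                                     value_kind = "binary"), 4)
  store <- build_fragments("e", list(e = empty))
  expect_identical(spatial_search(store, search_box(c(0, 0, 0), c(16, 16, 16))),
                   character(0))
  expect_error(spatial_search(store, search_box(c(16, 0, 0), c(16, 16, 16))),
               "empty")
  expect_error(spatial_search(store, search_box(c(0, 0, 0), c(16, 16, 16)),
                              min_cells = 0), ">= 1")
})

test_that("max-pooling guarantees no false negatives at min_cells = 1", {
  set.seed(14)
  for (trial in 1:25) {
    dims <- c(33, 21, 17)
    m <- vx_volume(array(0L, dims), value_kind = "binary")
    vox <- c(sample.int(dims[1], 1), sample.int(dims[2], 1),
             sample.int(dims[3], 1))
    m$data[vox[1], vox[2], vox[3]] <- 1L
    ds <- downsample_mask(m, 4)
    store <- build_fragments("line", list(line = ds))
    box <- search_box(vox - 1L, vox)  # the single full-res voxel
    expect_identical(spatial_search(store, box), "line")
  }
})
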