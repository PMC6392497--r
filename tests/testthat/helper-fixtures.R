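# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_volume <- function(dims, max = 255, seed = NULL, kind = "raw",
                        spacing = c(1, 1, 1), integer = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  v <- stats::runif(prod(dims), 0, max)
  if (integer) v <- floor(v)
  vx_volume(array(v, dims), spacing_um = spacing, value_kind = kind)
}

rand_mask <- function(dims, p = 0.1, seed = NULL, spacing = c(1, 1, 1)) {
  if (!is.null(seed)) set.seed(seed)
  vx_volume(array(as.integer(stats::runif(prod(dims)) < p), dims),
            spacing_um = spacing, value_kind = "binary")
}

# type-7 quantile computed from first principles (independent of stats::quantile)
quantile7_oracle <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
}

# brute-force any-reduction downsampling over each factor^3 cell
downsample_oracle <- function(arr, f) {
  d <- dim(arr); od <- ceiling(d / f)
  out <- array(0L, od)
  for (i in seq_len(od[1])) for (j in seq_len(od[2])) for (k in seq_len(od[3])) {
    xr <- ((i - 1) * f + 1):min(i * f, d[1])
    yr <- ((j - 1) * f + 1):min(j * f, d[2])
    zr <- ((k - 1) * f + 1):min(k * f, d[3])
    out[i, j, k] <- as.integer(any(arr[xr, yr, zr] == 1))
  }
  out
}

# naive bit packer: bit i of byte j (LSB first) = linear voxel 8j + i
pack_oracle <- function(bits) {
  v <- as.integer(bits)
  bytes <- integer(64)
  for (j in 0:63) for (i in 0:7)
    if (v[8 * j + i + 1] == 1) bytes[j + 1] <- bytes[j + 1] + bitwShiftL(1L, i)
  as.raw(bytes)
}

# small library of downsampled masks + the matching fragment store
make_search_fixture <- function(n_lines = 20, dims = c(40, 24, 16), factor = 4,
                                p = 0.08, seed = 42) {
  set.seed(seed)
  masks <- list()
  for (i in seq_len(n_lines)) {
    full <- rand_mask(dims, p = p)
    masks[[sprintf("line-%02d", i)]] <- downsample_mask(full, factor)
  }
  list(masks = masks,
       store = build_fragments(names(masks), masks),
       dims = dims, factor = factor)
}

the_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom_brain(phantom_spec())
    cache
  }
})
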