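---
title: "voxatlas: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxatlas: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intersectional transgenics (Gal4 x Cre) restrict reporter or effector
expression to neurons that carry both drivers. Designing such experiments
against a library of hundreds of co-registered transgenic line images
requires a set of computational primitives: building normalized, masked,
representative expression volumes; searching them in 3D for lines that label
a region of interest; predicting the intersection of two lines; quantifying
how much of the brain's cell-body volume each line and the whole library
covers; converting coverage into approximate neuron counts; and, on the
molecular side, mapping enhancer-trap integration sites from pooled
sequencing. `voxatlas` implements these stages as composable functions over
a single volume data model.

All volumes live on one shared atlas voxel grid (x = left-right,
y = anterior-posterior, z = dorsal-ventral, spacing in um). Registration to
that grid is assumed done upstream (e.g. with ANTs) and is out of scope:
`read_volume()` takes only the voxel spacing from NIfTI headers and treats
orientation matrices as opaque.

## Representative images: averaging, normalization, masking

A line's representative image is the voxel-wise mean of at least three
registered larvae (`average_scans()` warns below three). Intensities are
then normalized to 8 bits with `normalize_to_8bit()`: the value at the
`1 - f` quantile (default `f = 1e-4`, i.e. the brightest 0.01% of pixels)
saturates at 255 and everything below scales linearly. Numerical choices,
fixed because the outputs feed a bit-exact index:

* The quantile uses linear interpolation (type 7) over **all** voxels by
  default. Whether the original normalization was computed over the whole
  stack or only the masked brain is not something the procedure pins down;
  both are supported (`domain = "mask"`), and all-voxels is the default
  because it needs no mask and is reproducible from the raw stack alone.
* Rounding is round-half-to-even (base R `round()`), then clipped to 0..255.
* An all-zero volume (quantile 0) maps to all zeros rather than dividing by
  zero.

`apply_mask()` zeroes everything outside a binary brain mask; it is
idempotent and leaves in-mask values untouched.

## The spatial-search index

Search must answer "which of N lines express anywhere in this box?" without
touching N full-resolution volumes. The pipeline is:

1. `binarize()` each line at its manually defined cellular threshold
   (super-threshold means `>=`, everywhere in the package).
2. `downsample_mask()` by an integer factor (default 4) with **max pooling**:
   a coarse cell is set iff any constituent voxel is set. This direction of
   pooling guarantees no false negatives — any set full-resolution voxel
   inside a query box implies its line is returned at `min_cells = 1`.
3. `pack_block()` packs each 8x8x8 block of the coarse mask into exactly
   64 bytes. The contract is fixed so fragment files are bit-exact across
   implementations: voxels linearize x-fastest, and bit i of byte j
   (least-significant-bit first) holds linear voxel `8j + i`. Edge blocks
   are zero-padded.
4. `build_fragments()` concatenates, per block coordinate, every line's
   64-byte payload in registry order. One fragment is the unit a client
   fetches: `64 * n_lines` bytes (16,896 bytes, about 17 kb, for 264 lines).

`spatial_search()` converts a full-resolution half-open box `[lo, hi)` to
its downsampled cover — `floor(lo / factor)` to `ceiling(hi / factor)`,
outward rounding again to preserve the no-false-negative property — and
counts set cells per line, touching only overlapping fragments. The search
box is 0-based because the on-disk format is defined in those terms.
`brute_force_search()` is a direct voxel loop with the same contract and
serves as the independent oracle; the test suite checks exact agreement
over hundreds of randomized (library, box, min_cells) instances. The
`min_cells` default of 1 means "any expression in the box"; no
fraction-of-box criterion is applied.

## Intersection prediction and projections

`predict_intersection()` defaults to the voxel-wise **minimum** of the two
normalized intensities. The minimum is symmetric, idempotent, dominated by
both inputs, and degrades gracefully when the two lines' thresholds differ;
a `binary_and` mode (AND of the two thresholded masks) matches how
predicted overlaps are compared against realized triple-transgenic
expression. Predicted overlap is an upper bound on realized co-expression:
intermingled cell types inside one voxel, reporter silencing and biological
variability all shrink the realized pattern, which is why predictions need
experimental verification.

`max_projection()` takes per-ray maxima; `depth_coded_projection()` encodes
the depth of the (first) maximum as hue and the maximum as brightness, with
ties broken toward the viewer and zero rays black.

## Coverage statistics

The cell-body (cellular) volume is estimated from a soma marker and a
neuropil marker: within the brain mask, a voxel is cellular iff
`soma / (soma + neuropil) >= 0.5`. The ratio rule is the natural reading of
"based on the ratio" of the two markers; the threshold is exposed
(`ratio_threshold`) because 0.5 — soma signal at least as strong as
neuropil — is a default, not a measurement. Voxels with no signal in either
channel carry no evidence and are excluded.

Per line, `line_coverage()` reports the fraction of cellular voxels at or
above the line's threshold. `line_count_map()` sums the binarized masks of
all non-excluded lines (broad, near pan-neuronal drivers are flagged
`exclude_from_coverage` and dropped first — one such line would otherwise
push union coverage to ~100% on its own). `library_summary()` derives union
coverage, mean lines per voxel, and the per-line coverage distribution with
a 50-bin equal-width histogram on `[0, max]`. Conservation (sum of the
count map equals the summed per-line covered voxels) is property-tested.
`neurons_per_line()` converts a coverage fraction into an approximate
neuron count against a whole-brain total (default 92,000), rounded to two
significant figures.

## Binned expression and region means

`define_bins()` tiles the left hemisphere with cubic bins (default 20 um)
anchored at the grid origin, keeping a bin only if it lies entirely inside
the brain mask, and records each bin's mirror box across the midline.
Decisions the procedure leaves open, fixed here:

* Midline: the plane between voxel columns `nx/2` and `nx/2 + 1`, a
  parameter because atlas frames are usually but not always centered.
* Anchoring at the origin: bin placement is not otherwise determined, so
  the resulting bin count is data- and anchor-dependent and is not treated
  as a fixed constant of the method.
* The mirror box is pooled unconditionally, even if it extends past the
  mask edge of an asymmetric mask.

`bin_expression()` averages intensity over each bin plus its mirror and
rescales the vector by its maximum, so values are relative within a line
(max 1 unless the line is empty) and not comparable between lines — the
same caveat applies to `region_means()`, which averages 0-1-scaled
intensity per anatomical label (absent labels are missing, never zero).

## Stratified neuron-count estimation

Neuron density is predicted by the local soma/synapse balance, so the brain
is cut into `n_bins = 5` density strata of the ratio
`r = soma / (soma + synapse)` and sampled within strata. How the original
five bins were delimited is not stated; equal-population (quantile) bins
are used because they make every stratum large enough to sample, and the
assignment is rank-based so ties share a bin. `plan_samples()` draws
`boxes_per_bin = 5` cubic volumes of 30 um edge by seeded rejection
sampling under a majority-label rule (a box belongs to the stratum that is
the modal nonzero label among its voxels) with no overlap — a reproducible
stand-in for volumes chosen by eye. Counting neurons inside a box is
outside the estimator: `set_counts()` accepts observed counts, and
`make_nuclei_counts()` supplies simulated ones.

`estimate_total()` computes

    total = V_brain * sum_b fraction_b * mean(count_b) / V_box
    se^2  = V_brain^2 * sum_b fraction_b^2 * sem_b^2 / V_box^2

with `sem_b` the standard error of the mean count in stratum b (zero for a
single box) and strata treated as independent. The estimator is linear in
the counts and unbiased under Poisson sampling; Monte-Carlo tests (200
seeds against planted densities) check unbiasedness within three standard
errors of the mean and ~95% coverage of `total ± 2 se`. With five boxes per
stratum the plug-in sem slightly underestimates tail risk, which is why the
tests accept coverage down to 90%.

## Pooled integration-site deconvolution

`design_pools()` places each line in a distinct pair of pools (capacity
`choose(n_pools, 2)`), greedily filling the least-loaded pair with
seed-shuffled ties so pool sizes stay balanced; the published screen's
"five lines per pool" is treated as a size target, not a constraint, since
pool count and line count are both parameters. Deconvolution then proceeds:

1. `filter_offtarget()` removes sites present (count >= `presence_min`,
   default 1) in **all** pools — no single line can produce that signature.
2. `merge_sites()` collapses sites within 100 bp (read scatter around the
   true integration point); coordinates are 0-based and strand is ignored
   for site identity.
3. `assign_sites()` assigns a site to line L iff it has >= `min_reads`
   (default 10) in both of L's pools and <= `max_bg_reads` (default 2) in
   every other pool. "High and specific enrichment" is operationalized as
   this auditable two-threshold rule rather than a fold-change statistic.
   Distinct pairs make double assignment impossible; failures are reported
   as `below_enrichment` (high pools are a strict subset of some pair) or
   `no_matching_signature` (high pools match no pair).

Simulated experiments (Poisson signal of mean 100 reads in the two true
pools, Poisson background of mean 0.2 everywhere, plus all-pool off-target
sites) recover planted sites with precision 1.0 and recall above 0.95 at
the default thresholds.

## What the synthetic data does and does not show

`make_phantom_brain()` builds an ellipsoidal brain with complementary
radial soma/neuropil fields (soma-dominant shell, neuropil-dominant core);
`make_line_volume()` plants Gaussian expression clusters at known centers;
`make_registry()` assembles a small library including one broad flagged
line; `make_nuclei_counts()` draws Poisson counts from planted densities.
These phantoms have the statistical structure every stage assumes —
known ground truth, exact symmetry, smooth density gradients — and none of
the things real scans have: registration error, intensity inhomogeneity,
microscope noise, asymmetric anatomy, intermingled cell types. Passing
tests therefore demonstrate algorithmic correctness and calibration, not
that the biological headline numbers of any particular dataset are
reproduced; those depend on the original imaging data.

Problem sizes are chosen for desk-scale runs: the default phantom is
128 x 64 x 64 voxels at 2 um (20 um bins and 30 um boxes stay
non-degenerate), search equivalence is checked on 20-line libraries over
hundreds of random boxes, and Monte-Carlo calibrations use 200 (estimator)
and 20 (poolmap) seeds. All generators and samplers are deterministic given
their seed.

## Known limitations

* Sampling boxes may straddle stratum boundaries or the brain edge; the
  majority-label rule tolerates this, and the simulated counts are
  consistent with it, but with real images the operator should prefer boxes
  well inside a stratum.
* `spatial_search()` operates at downsampled resolution: it can return a
  line whose full-resolution expression only touches the query box's
  4x4x4-voxel neighbourhood (no false negatives, occasional near-miss
  false positives).
* The montage rescale is a nearest-neighbour index subsample, chosen so
  montages are bit-exact reproducible and every montage pixel is an actual
  source voxel; it is not an anti-aliased thumbnail.
* Pool deconvolution assumes one integration site per line; lines with
  multiple insertions produce multiple sites with the same pool signature,
  which are all (correctly) assigned to that line.
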