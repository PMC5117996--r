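---
title: "Stitching multi-beam SEM mosaics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitching multi-beam SEM mosaics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Multi-beam scanning electron microscopes (mSEM) image macroscopic tissue
sections at nanometre resolution by scanning dozens of beams in parallel.
One exposure yields a hexagonal multi-beam field of view (mFOV) of 61
single-beam tiles (1288 x 1120 px each); a full acquisition tiles the
specimen with hundreds of overlapping mFOVs and accumulates tens of
thousands of tiles. The stage records an approximate position for every
tile, but stage precision (about 2 um, i.e. roughly 200 px at 10 nm/px) is
orders of magnitude worse than the pixel pitch, and beam-specimen
interactions shift tiles further. `msemstitch` reconstructs the seamless
mosaic: it estimates pairwise translations by phase correlation, repairs
untrustworthy pairings, relaxes all tiles to a global equilibrium with a
damped mass-spring model, composites the registered tiles with feathered
blending, and exports a 256 x 256 tiled pyramid for web map viewers.

This vignette explains each model, every tunable parameter with its default
and units, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the method left room.

## Pairwise alignment

For every pair of tiles whose frames are predicted to overlap, the
translation `p = x_i - x_j` that best aligns their pixel content is
estimated by Fourier phase correlation: both regions are mean-subtracted,
the normalised cross-power spectrum is inverse-transformed to a correlation
surface, and the top `n_peaks` (default 4) surface peaks inside the search
window are considered. Each peak has four periodic interpretations; every
candidate is scored by the Pearson correlation of the overlap pixels it
implies, and the best candidate wins. That maximal Pearson correlation,
clipped to [0, 1], is the pair's quality score `R`. Scoring candidates by
explicit correlation rather than by peak height makes the estimator robust
to the weak, noisy peaks that small overlaps produce.

Only integer shifts are estimated. Residuals and corrections throughout the
pipeline are therefore in whole pixels, which is also the resolution at
which tiles are finally placed. Ties between equally scoring candidates are
broken deterministically (smaller shift magnitude, then lexicographic). No
apodization window is applied by default (`window = "none"`); a Hann taper
is available when tiles show strong edge artefacts.

Two parameters govern the geometry of the search:

* `margin` (pixels, default 150): how far beyond the predicted overlap the
  extracted regions extend. The window must cover the worst-case *relative*
  stage error of a pair, which is twice the per-tile stage precision. At
  full instrument scale (10 nm/px, 2 um precision) that bound is 400 px and
  a 150 px margin relies on typical rather than worst-case errors; at the
  quarter-scale synthetic conditions used throughout the tests (40 nm/px,
  jitter sigma 15 px, precision = 3 sigma = 45 px) the bound is about
  100 px, and that is the margin the benchmark runs use.
* `min_overlap_px` (default 32): the minimum implied-overlap pixel count
  for a candidate shift to be scored at all.

## The overlap graph and stage uncertainty

Edges of the overlap graph are pairs whose frames, placed at their stage
positions, intersect with at least `min_overlap_area` px^2 (default 16 x 16;
slivers below that carry too few pixels for correlation). Because the stage
positions themselves are uncertain, frames are first inflated by the
documented stage precision converted to pixels (`expand`; derived from the
acquisition metadata by the pipeline). Without the inflation, thin true
overlaps hidden by stage error are silently lost; when the overlap
fraction is small relative to the stage error this can fragment the graph
into multiple connected components, and the affected tiles can never be
registered against the rest.

Inflation adds hypothesised edges that the stage alone cannot confirm.
These are marked `weak`, and their alignment is accepted only if it clears
the high-quality bar (`R > 0.9`): a weak edge with mediocre correlation is
far more likely to be a spurious match on smooth texture than a genuine
discovery, and accepting it injects a wrong constraint. Weak edges that
fail the bar are corrected like any rejected pair when their overlap type
has a trustworthy translation estimate, and dropped entirely when it does
not (see below).

Every edge carries an overlap-type label encoding its geometric relation on
the acquisition lattice: the stage displacement quantized to half-frame
units, `INTRA_1.<qx>` for lateral same-row neighbours, `INTRA_2.<qx>.<qy>`
for other same-mFOV relations, and `INTER_<bin>.<qx>.<qy>` across mFOVs
(with the 45-degree direction bin kept as a readable prefix). The
quantization is what guarantees that pairs sharing a label share a true
offset — a pure direction taxonomy groups border relations that sit whole
tile pitches apart, and any statistic pooled over such a group averages
incompatible vectors. Stage jitter far below half a frame never changes a
label.

## Correction of unsatisfactory pairings

A pairing is rejected when any of these criteria fires (first match is
recorded as the reason):

1. `R < 0.5` (`r_min`) — the alignment is no better than chance;
2. weak-evidence edge with `R <= 0.9` (see above);
3. initial residual `r0 = (stage_i - stage_j) - p` longer than 300 px
   (`r0_max`) — the proposed correction is implausibly large;
4. a component of the correction exceeds the corresponding predicted
   overlap dimension — the match lies outside the window where overlap was
   predicted at all;
5. frames placed at relative offset `p` no longer intersect.

Rejected pairings are reset to `R = 0.5` and `p` is replaced by the
centroid (component-wise mean) of the alignment vectors of the high-quality
pairs of the same overlap type — pairs with `R > 0.9` (`r_high`) that were
not themselves rejected. Excluding rejected pairs from the pool matters
twice over: a pair rejected for, say, an implausible residual must not
teach the centroid its translation however well it correlated, and the
exclusion makes the correction operator idempotent (a replaced pair is
reset to `R = 0.5` and can never re-enter the pool, so the table is
identical on a second pass). Types with no high-quality member fall back to
the mean stage-predicted offset of the type, with a warning; weak edges in
that situation are dropped instead, because the edges that exist only due
to stage-uncertainty inflation are a selection-biased sample (only extreme
stage errors create them) and their stage-offset mean is correspondingly
biased.

A last rescue handles quantization at the label boundaries: stage jitter
can push a pair's quantized offset into a singleton label with no
high-quality support, whose stage-offset fallback inherits exactly the
extreme error that created the label. If a populated group's centroid lies
within twice the stage precision of the rejected pair's stage offset
(`snap_tol`, derived from the instrument metadata by the pipeline), that
centroid is used instead: the nearby group is the pair's true lattice
relation. In direct calls to `correct_pairs()` the rescue is off and the
plain per-type fallback applies.

The original residual of a corrected pair is preserved in `r0_orig_x/y`;
the working residual is recomputed from the replacement vector.

Thresholds with pixel units are quoted at full instrument scale
(1288 x 1120 px frames) and must scale with the geometry when the pipeline
runs on scaled data: the benchmark acquisitions use quarter-scale frames,
so their configurations set `r0_max = 75` (= 300/4) and a 100 px alignment
margin. The residual cap is precisely the guard against the confident
wrong matches that blurred, self-similar regions produce — their spurious
translation estimates land at a substantial fraction of the frame size, so
a cap left at full-scale pixels on quarter-scale frames misses them
entirely. Thresholds on the dimensionless correlation (`r_min`, `r_high`)
do not scale.

## Global registration

Each tile is a point mass (`m = 1`), each surviving pair a spring whose
rest configuration is its alignment vector `p` and whose stiffness is

    k_ij = k * R_ij^n,        k = 1, n = 5,

so high-quality alignments pull hard and corrected pairs (R = 0.5,
k_ij = 0.03125) pull thirty times more gently. With damping `c = 0.25` the
dynamics are

    m x.. + c x. + F_k = 0,   F_k(i) = sum_j k_ij * r_ij,
    r_ij = (x_i - x_j) - p_ij.

The centre tile of the first mFOV is anchored (its derivative forced to
zero for all time) to remove the global translation degeneracy; in a
disconnected graph every component gets its own anchor, with a warning. The
system is integrated with an adaptive Dormand-Prince Runge-Kutta scheme
(`deSolve`, method `"ode45"`, `rtol = atol = 1e-8`), evaluating residuals
at checkpoints every `checkpoint_dt = 1` time unit.

Convergence is declared when the RMS of the *changes of the residual
vectors* between consecutive checkpoints stays below `conv_tol = 1e-6` px
twice in a row. Two details deserve emphasis. First, the criterion is on
the movement of the residual vectors, not on the change of the scalar
residual RMS: near a nonzero minimum the scalar's gradient vanishes, and a
scalar-change rule halts integration while tile positions are still a pixel
or more from equilibrium. Second, requiring two consecutive sub-tolerance
checkpoints is a tie-break against the underdamped transient, whose
oscillation can produce one spuriously small difference at an extremum.
Integration is capped at `t_max = 1e4` time units; hitting the cap is
reported, not fatal.

The equilibrium of this system is exactly the minimiser of the weighted
least-squares objective `sum k_ij * ||(x_i - x_j) - p_ij||^2`, which
`solve_least_squares()` computes directly through the sparse normal
equations (weights `R^n`, or 1 for the unweighted variant). The direct
solvers are the reference implementation the relaxation is tested against;
the package's property suite requires agreement within 0.5 px per
coordinate on random instances up to 200 tiles, and total mechanical energy
(kinetic plus spring potential) to be non-increasing across checkpoints
within 1e-6 relative tolerance.

Of the method's parameters, `n` is the one with real leverage: it sets how
steeply influence falls with alignment quality (at `n = 5` a pair at
R = 0.8 has a third of the pull of a perfect pair; at R = 0.5, a thirtieth).
`m`, `k` and `c` only shape the transient, not the equilibrium. The damping
ratio implied by the defaults is c/(2 sqrt(mk)) = 0.125; an effective ratio
quoted as about 0.14 elsewhere would correspond to a slightly smaller
effective stiffness, as produced by R-weighting, but nothing in the
pipeline depends on this number.

## Compositing and pyramid export

Registered positions are rounded to integer pixels and every output pixel
is the weight-normalised blend `sum(w * I) / sum(w)` of the covering tiles,
with the per-tile weight proportional to 1 + the pixel's Chebyshev distance
to the nearest frame edge. This distance feathering suppresses visible
seams; it deliberately replaces the non-linear multi-band blending used by
some stitching stacks, and no gain compensation is attempted — intensity
steps between tiles with different gain remain visible (smoothly faded) in
the composite. Uncovered canvas is set to the background value (0; SEM
void is dark). The canvas is processed in fixed-size chunks written to an
on-disk store (PNG chunks plus a JSON manifest), so peak memory scales with
the chunk area, never the canvas.

The pyramid partitions the full-resolution mosaic into 256 x 256 PNG tiles
(edge tiles padded with background), then repeatedly groups squares of four
tiles and downsamples 512 -> 256 by 2 x 2 block averaging — chosen over
fancier kernels because block means conserve intensity, which the test
suite checks level against level to half a gray value — until a level fits
in a single tile. Tile files follow the slippy-map template
`(maxzoom-zoom)/y/y_x_(maxzoom-zoom).png`, so directory `0/` is full
resolution and the coarsest level is a single tile; a manifest JSON and a
static HTML stub point any web map viewer at the directory.

## The synthetic acquisition generator

Every test runs against acquisitions generated with known ground truth:

* **Scene**: band-limited noise — coarse (8 px grid) plus fine (4 px grid)
  bilinear noise plus full-band grain — normalised to mean 128, sd 30, and
  quantized to 8 bits. The grain term matters: real micrographs carry fine
  texture well above the quantization floor, and without it the
  high-frequency phase of the cross-power spectrum is dominated by rounding
  noise and phase correlation degrades badly. An optional ring-motif
  overlay mimics concentric lamellar structure. Autocorrelation length of
  the mixture is several pixels, so correlation peaks are well defined.
* **Geometry**: hexagonal mFOVs with rows of 5,6,7,8,9,8,7,6,5 tiles
  (61; the smaller centred-hexagonal counts 1/7/19/37 are available),
  horizontal pitch `width * (1 - overlap_fraction)`, vertical pitch chosen
  so adjacent rows overlap by at least the same fraction, alternate rows
  offset by half a pitch; mFOV grids are pitched so border tiles of
  neighbouring mFOVs overlap like intra-mFOV neighbours. The default frame
  is 322 x 280 px — the instrument's 1288 x 1120 at quarter scale — so full
  multi-mFOV benchmarks run in seconds to minutes; the full-scale frame is
  a configuration choice away.
* **Stage error**: tile pixel content is cropped from the scene at exact
  lattice positions; the *recorded* stage positions are the lattice plus
  integer-rounded iid Gaussian jitter (default sigma 15 px, the quarter-
  scale analogue of micrometre-class stage precision). Jitter is metadata
  error only, exactly like a real stage. An optional per-mFOV common offset
  emulates the correlated part of real stage error (off by default). The
  written metadata declares a stage precision of 3 sigma, which is what the
  pipeline's graph inflation and margins are derived from.
* **Artifacts**: DARK regions attenuate the signal into a strength-scaled
  noise floor; BLUR regions additionally smear with a Gaussian whose radius
  grows with strength. Both model secondary-electron shielding: signal is
  lost to noise, not merely rescaled — a pure rescaling would leave Pearson
  correlation (scale-invariant) untouched and no correction would ever
  trigger, and pure smearing leaves mutually-similar blurred neighbours
  above the rejection threshold. Regions are specified in ground-truth
  coordinates and cut across tile borders like real specimen topography.

What passing tests on this generator do **not** show: robustness to
non-translational distortion (lens distortion, charging drift within a
tile, specimen warping), to per-tile gain and offset variation beyond what
affine-invariance of Pearson correlation absorbs, to correlated stage
error, or to content-free regions (blood vessel lumina) that defeat
correlation in real tissue. Those failure modes motivate the correction
stage but are only partially emulated.

## Problem sizes and numerical choices

The acceptance-grade checks run, by the package's own choice, at these
sizes: 20 random spring instances up to 200 tiles for the solver-oracle and
energy properties; a 3 x 3 mFOV grid of 61 tiles each (549 tiles, ~1500
pairs, scene about 8200 x 7100 px) at 6% overlap and jitter sigma 15 for
ground-truth recovery; the same grid with 10% of tiles corrupted for the
artifact pipeline; 100 noise-free pairs with known integer shifts for
phase-correlation exactness; and mosaics of 256^2, 512^2 and 1000 x 700 px
for pyramid conformance.

Degenerate inputs are handled explicitly: zero-variance regions flag the
pair rather than produce NaN; pairs referencing unknown tiles are hard
errors; an empty tile list yields an empty graph; a disconnected graph
registers per component with per-component anchors; springs with R = 0
exert no force, and a tile isolated by zero-stiffness springs is pinned at
its stage position to keep the direct solve well posed.

## Known limitations

Translation-only alignment cannot compensate rotations or scale changes;
residual error against the direct solvers reflects integration tolerance,
not model differences, but both share the translation model's bias on
distorted data. The blending is seam-suppressing, not gain-compensating.
The inter-mFOV type taxonomy assumes an approximately lattice-like mFOV
arrangement; acquisitions with irregular mFOV placement would need labels
derived from matched rather than quantized offsets. Very large mosaics are
bounded by the chunk store's one-file-per-chunk layout, not by memory.
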