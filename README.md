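# msemstitch

Reconstruction of seamless gigapixel mosaics from multi-beam scanning
electron microscopy (mSEM) acquisitions, in R.

An mSEM images a macroscopic specimen — cortical bone, brain tissue — as
tens of thousands of overlapping single-beam tiles, acquired 61 at a time
in hexagonal multi-beam fields of view (mFOVs). The microscope stage
records an initial position for every tile, but stage precision (~2 µm,
i.e. ~200 px at 10 nm/px) is far coarser than the pixel pitch, so the raw
montage is visibly misaligned. `msemstitch` turns tiles plus stage metadata
into a seamless, web-browsable map:

1. **Pairwise alignment** — for every pair of overlapping tiles, the
   translation `p_ij` maximising alignment and a correlation coefficient
   `R_ij ∈ [0, 1]` are estimated by Fourier phase correlation, with
   candidate peaks scored by the Pearson correlation of the overlap pixels
   they imply.
2. **Correction** — pairings are rejected when `R < 0.5`, when the initial
   residual `‖r₀‖ = ‖(x_i − x_j) − p‖` exceeds 300 px, when the implied
   shift exceeds the predicted overlap dimensions, or when it leaves no
   overlap at all; rejected pairings are reset to `R = 0.5` and `p` is
   replaced by the centroid of the high-quality (`R > 0.9`) alignment
   vectors of the same overlap type.
3. **Global registration** — every tile is a unit point mass, every pair a
   spring with rest offset `p_ij` and stiffness `k·R_ij⁵`; with damping
   `c = 0.25` the system `m ẍ + c ẋ + F_k = 0`,
   `F_k(i) = Σ_j k_ij r_ij`, `r_ij = (x_i − x_j) − p_ij` is integrated to
   equilibrium with an adaptive Runge–Kutta scheme (one anchor tile fixed).
   The equilibrium minimises `Σ k_ij ‖r_ij‖²`, and sparse unweighted/
   weighted least-squares reference solvers are built in for comparison.
4. **Compositing and export** — registered tiles are blended with
   distance-feathered weights into a chunked on-disk mosaic and exported as
   a 256×256 PNG tile pyramid using the slippy-map directory scheme
   `(maxzoom−zoom)/y/y_x_(maxzoom−zoom).png`.

A synthetic-acquisition module generates complete mSEM-like datasets with
known ground truth — hexagonal 61-tile mFOVs, configurable overlap and
frame size, Gaussian stage jitter, dark/blurred artifact regions — so the
entire pipeline is testable and benchmarkable without microscope data.

## Worked example

Simulate a 2×2 grid of 7-tile hexagonal mFOVs (128×112 px frames, 10 %
overlap, stage jitter σ = 5 px), then stitch it end to end:

```r
library(msemstitch)

spec  <- acquisition_spec(mfov_grid = c(2, 2), tiles_per_mfov = 7L,
                          tile_frame = c(128L, 112L), overlap_fraction = 0.10,
                          jitter_sigma = 5, seed = 42L)
size  <- acquisition_scene_size(spec)
scene <- generate_scene(size[1], size[2], seed = 7)
synth <- generate_acquisition(scene, spec)

res <- run_stitch(stitch_config(out_dir = "stitch_run", margin = 32,
                                render = TRUE, chunk_size = 512L), synth)
#> [graph] 28 tiles (frame inflation 15 px)
#> [graph] 58 overlapping pairs
#> [correct] 1 / 55 pairs corrected
#> [done] RMS 11.06 -> 0.44 px (96.0% reduction) in 5.0 s

res$registration
#> <msem_registration> msd: 28 tiles, 55 springs
#>   residual RMS 11.060 -> 0.442 px (96.0% reduction)
```

The messages tell the story: 28 tiles produce 58 candidate overlaps (the
frames are inflated by the declared stage precision before intersecting, so
true overlaps hidden by stage error are not lost); alignment plus
correction keeps 55 springs, one of which was replaced by a per-type
estimate; relaxing the spring system reduces the pairwise residual RMS
from 11.06 px (pure stage error) to 0.44 px. `tidy(res$registration)`
returns the per-tile positions, `glance(...)` the one-row fit summary, and
`autoplot(...)` the convergence trace; `stitch_run/pyramid/` contains the
browsable tile pyramid, e.g. `0/2/2_5_0.png` for the full-resolution tile
at column 5, row 2.

Against the generator's ground truth, the recovered positions agree to well
under a pixel (RMS after removing the anchor's gauge):

```r
pos <- tidy(res$registration)
idx <- match(pos$tile_id, synth$truth$tile_id)
dx <- pos$x - synth$truth$true_x[idx]; dy <- pos$y - synth$truth$true_y[idx]
sqrt(mean((dx - mean(dx))^2 + (dy - mean(dy))^2))
#> [1] 0.0166016
```

A thin command-line front end wrapping the same functions is installed at
`inst/cli/msem-stitch.R` (`simulate`, `run`, `compare-solvers`).

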