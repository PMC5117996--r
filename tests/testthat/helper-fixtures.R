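# Shared fixtures, built in code. Heavier objects are memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small textured scene.
small_scene <- function(width = 400, height = 300, seed = 3) {
  memo(sprintf("scene_%d_%d_%d", width, height, seed),
       function() generate_scene(width, height, seed = seed))
}

# One 7-tile hexagonal mFOV acquisition with modest jitter.
small_hex <- function(seed = 42L, jitter = 5) {
  memo(sprintf("hex7_%d_%g", seed, jitter), function() {
    spec <- acquisition_spec(
      mfov_grid = c(1L, 1L), tiles_per_mfov = 7L,
      tile_frame = c(128L, 112L), overlap_fraction = 0.10,
      jitter_sigma = jitter, seed = seed
    )
    sz <- acquisition_scene_size(spec)
    scene <- generate_scene(sz[1], sz[2], seed = seed + 1L)
    list(synth = generate_acquisition(scene, spec), scene = scene, spec = spec)
  })
}

# 2x2 grid of 7-tile mFOVs: has inter-mFOV pairs, still fast.
small_grid <- function(seed = 42L, jitter = 5) {
  memo(sprintf("grid22_%d_%g", seed, jitter), function() {
    spec <- acquisition_spec(
      mfov_grid = c(2L, 2L), tiles_per_mfov = 7L,
      tile_frame = c(128L, 112L), overlap_fraction = 0.10,
      jitter_sigma = jitter, seed = seed
    )
    sz <- acquisition_scene_size(spec)
    scene <- generate_scene(sz[1], sz[2], seed = seed + 1L)
    list(synth = generate_acquisition(scene, spec), scene = scene, spec = spec)
  })
}

# Two tiles carved from one scene with exact stage positions.
two_tile_pair <- function(offset_x = 100L, w = 128L, h = 112L) {
  scene <- small_scene()
  tibble::tibble(
    tile_id = c("a", "b"), mfov_id = 1L, beam_index = 0:1,
    x = c(0, offset_x), y = c(0, 0), width = w, height = h,
    image = list(scene[1:h, 1:w], scene[1:h, (offset_x + 1):(offset_x + w)])
  )
}

# Band-limited noise region (deterministic, textured at all frequencies).
noise_region <- function(h, w, seed) {
  set.seed(seed)
  m <- matrix(rnorm(h * w), h, w)
  sm <- msemstitch:::gaussian_blur(m, 1.5)
  sm + 0.2 * matrix(rnorm(h * w), h, w)
}

# Gauge-aligned RMS distance between recovered and true positions.
truth_rms <- function(positions, truth) {
  idx <- match(positions$tile_id, truth$tile_id)
  dx <- positions$x - truth$true_x[idx]
  dy <- positions$y - truth$true_y[idx]
  sqrt(mean((dx - mean(dx))^2 + (dy - mean(dy))^2))
}
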