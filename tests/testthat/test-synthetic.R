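test_that("scenes are deterministic in the seed and decorrelated across seeds", {
  a1 <- generate_scene(200, 150, seed = 5)
  a2 <- generate_scene(200, 150, seed = 5)
  expect_identical(a1, a2)
  cors <- vapply(1:10, function(k) {
    s1 <- generate_scene(320, 240, seed = 2000 + k)
    s2 <- generate_scene(320, 240, seed = 7000 + k)
    cor(as.vector(s1), as.vector(s2))
  }, 1)
  expect_true(all(abs(cors) < 0.1))
})

test_that("every 64x64 scene patch has nonzero variance", {
  s <- generate_scene(256, 192, seed = 8)
  for (y in seq(1, 192 - 63, by = 64)) {
    for (x in seq(1, 256 - 63, by = 64)) {
      expect_gt(stats::var(as.vector(s[y:(y + 63), x:(x + 63)])), 0)
    }
  }
})

test_that("hex layouts have the canonical row structure and full adjacency", {
  lay <- hex_layout(61L, 322L, 280L, 0.06)
  expect_equal(nrow(lay), 61L)
  expect_equal(as.vector(table(lay$row)), c(5L, 6L, 7L, 8L, 9L, 8L, 7L, 6L, 5L))
  expect_equal(nrow(hex_layout(1L)), 1L)
  expect_equal(hex_layout(1L)$dx, 0L)
  expect_error(hex_layout(13L), "centred hexagonal")
  expect_error(hex_layout(61L, overlap_fraction = 0.01), "overlap_fraction")
  # offsets pairwise distinct; adjacency graph (overlapping frames) connected
  expect_equal(anyDuplicated(lay[, c("dx", "dy")]), 0L)
  n <- nrow(lay)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      wov <- min(lay$dx[a], lay$dx[b]) + 322 - max(lay$dx[a], lay$dx[b])
      hov <- min(lay$dy[a], lay$dy[b]) + 280 - max(lay$dy[a], lay$dy[b])
      adj[a, b] <- adj[b, a] <- wov > 0 && hov > 0
    }
  }
  comp <- msemstitch:::graph_components(n, row(adj)[adj], col(adj)[adj])
  expect_equal(max(comp), 1L)
})

test_that("zero jitter gives stage positions equal to ground truth", {
  spec <- acquisition_spec(tiles_per_mfov = 7L, tile_frame = c(64L, 56L),
                          overlap_fraction = 0.1, jitter_sigma = 0, seed = 2L)
  sz <- acquisition_scene_size(spec)
  scene <- generate_scene(sz[1], sz[2], seed = 3L)
  synth <- generate_acquisition(scene, spec)
  expect_equal(synth$acq$tiles$x, synth$truth$true_x)
  expect_equal(synth$acq$tiles$y, synth$truth$true_y)
})

test_that("tile crops are bit-identical to the scene and jitter has the right scale", {
  fx <- small_grid(jitter = 15)
  synth <- fx$synth
  for (k in c(1L, 9L, 20L)) {
    tx <- synth$truth$true_x[k]; ty <- synth$truth$true_y[k]
    crop <- fx$scene[(ty + 1):(ty + 112), (tx + 1):(tx + 128)]
    expect_identical(synth$acq$tiles$image[[k]], crop)
  }
  err <- c(synth$acq$tiles$x - synth$truth$true_x,
           synth$acq$tiles$y - synth$truth$true_y)
  expect_lt(abs(sd(err) - 15), 0.2 * 15)
  # determinism: same spec, same acquisition; geometry invariant in the seed
  synth2 <- generate_acquisition(fx$scene, fx$spec)
  expect_identical(synth2$acq$tiles$x, synth$acq$tiles$x)
  spec_b <- fx$spec; spec_b$seed <- fx$spec$seed + 1L
  synth3 <- generate_acquisition(fx$scene, spec_b)
  expect_identical(synth3$truth, synth$truth)
  expect_false(identical(synth3$acq$tiles$x, synth$acq$tiles$x))
})

test_that("a too-small scene is rejected", {
  spec <- acquisition_spec(tiles_per_mfov = 7L, tile_frame = c(64L, 56L))
  expect_error(generate_acquisition(matrix(0L, 50, 50), spec), "smaller than")
})

test_that("artifact injection is the identity at zero strength and darkens fully at one", {
  fx <- small_hex()
  synth <- fx$synth
  regions <- artifact_regions_for_tiles(synth, frac = 0.3, strength = 0, seed = 3)
  out <- inject_artifacts(synth, regions, seed = 4)
  for (k in seq_len(nrow(synth$acq$tiles))) {
    expect_equal(out$acq$tiles$image[[k]], synth$acq$tiles$image[[k]],
                 ignore_attr = TRUE, tolerance = 0)
  }
  dark <- regions
  dark$kind <- "DARK"
  dark$strength <- 1
  out2 <- inject_artifacts(synth, dark, seed = 4)
  vi <- match(dark$tile_id[1], out2$acq$tiles$tile_id)
  expect_lt(mean(out2$acq$tiles$image[[vi]]), 5)  # at the noise floor
  expect_true(out2$acq$tiles$artifact[vi])
})

test_that("a strong blur drops pairwise correlation with an untouched neighbour below 0.5", {
  fx <- small_hex()
  synth <- fx$synth
  pairs <- build_overlap_graph(synth$acq, expand = 20)
  al_before <- align_pairs(pairs, synth$acq, margin = 32)
  victim <- "m001_b03"
  vi <- match(victim, synth$truth$tile_id)
  blur <- tibble::tibble(
    x = synth$truth$true_x[vi], y = synth$truth$true_y[vi],
    w = 128, h = 112, kind = "BLUR", strength = 0.9
  )
  blurred <- inject_artifacts(synth, blur, seed = 6)
  al_after <- align_pairs(pairs, blurred$acq, margin = 32)
  incident <- al_after$tile_i == victim | al_after$tile_j == victim
  expect_true(all(al_before$R[incident] > 0.9))
  expect_true(all(al_after$R[incident] < 0.5))
})

test_that("random spring instances are connected and reproducible", {
  inst <- simulate_spring_instance(50, seed = 14)
  expect_equal(nrow(inst$tiles), 50L)
  i <- match(inst$pairs$tile_i, inst$tiles$tile_id)
  j <- match(inst$pairs$tile_j, inst$tiles$tile_id)
  expect_equal(max(msemstitch:::graph_components(50L, i, j)), 1L)
  expect_true(all(inst$pairs$R >= 0.3 & inst$pairs$R <= 1))
  inst2 <- simulate_spring_instance(50, seed = 14)
  expect_identical(inst, inst2)
})
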