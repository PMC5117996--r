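# A hand-built pair table exercising each rejection rule. Tiles are 100x100
# with a 20x100 predicted overlap.
correction_fixture <- function() {
  tiles <- tibble::tibble(
    tile_id = c("a", "b"), mfov_id = 1L, beam_index = 0:1,
    x = c(0, 80), y = c(0, 0), width = 100L, height = 100L,
    image = vector("list", 2)
  )
  pair <- build_overlap_graph(tiles)
  list(tiles = tiles, pair = pair)
}

with_alignment <- function(pair, R, p_x, p_y, stage_dx = -80, stage_dy = 0) {
  pair$R <- R
  pair$p_x <- p_x
  pair$p_y <- p_y
  pair$r0_x <- stage_dx - p_x
  pair$r0_y <- stage_dy - p_y
  pair
}

# A chain of four laterally overlapping tiles whose stage offset between
# consecutive tiles is x_i - x_j = 15, with three hand-set alignments.
lateral_chain_fixture <- function(p_x, R) {
  tiles <- tibble::tibble(
    tile_id = letters[1:4], mfov_id = 1L, beam_index = 0:3,
    x = c(0, -15, -30, -45), y = 0, width = 100L, height = 100L,
    image = vector("list", 4)
  )
  pairs <- tibble::tibble(
    tile_i = letters[1:3], tile_j = letters[2:4],
    type = "LATERAL", ov_x = NA_real_, ov_y = NA_real_,
    ov_w = 85, ov_h = 100,
    R = R, p_x = p_x, p_y = 0,
    r0_x = 15 - p_x, r0_y = 0, corrected = "NONE"
  )
  list(tiles = tiles, pairs = pairs)
}

test_that("each rejection criterion fires with its own reason, in order", {
  fx <- correction_fixture()
  # (1) low correlation
  low_r <- with_alignment(fx$pair, R = 0.4, p_x = -80, p_y = 0)
  out <- flag_unsatisfactory(low_r, fx$tiles)
  expect_true(out$unsatisfactory)
  expect_equal(out$reason, "LOW_R")
  # (2) long initial residual (350 px) at high R
  long <- with_alignment(fx$pair, R = 0.95, p_x = -80 - 350, p_y = 0)
  long$r0_x <- 350; long$r0_y <- 0   # residual length 350
  long$p_x <- -430
  out <- flag_unsatisfactory(long, fx$tiles)
  expect_true(out$unsatisfactory)
  expect_equal(out$reason, "LONG_RESIDUAL")
  # (3) shift beyond the predicted overlap dimensions, residual short enough
  shift <- with_alignment(fx$pair, R = 0.95, p_x = -80 - 25, p_y = 0)
  out <- flag_unsatisfactory(shift, fx$tiles)
  expect_equal(out$reason, "SHIFT_EXCEEDS_OVERLAP")
  # (4) translation under which frames no longer overlap
  gone <- with_alignment(fx$pair, R = 0.95, p_x = -80, p_y = 0)
  gone$p_y <- 120; gone$r0_y <- -120; gone$ov_h <- 150
  gone$ov_w <- 130  # keep (3) silent so (4) is reached
  out <- flag_unsatisfactory(gone, fx$tiles)
  expect_equal(out$reason, "NO_OVERLAP")
  # all criteria pass
  good <- with_alignment(fx$pair, R = 0.95, p_x = -85, p_y = 2)
  out <- flag_unsatisfactory(good, fx$tiles)
  expect_false(out$unsatisfactory)
  expect_equal(out$reason, "NONE")
})

test_that("translation table is the centroid of satisfactory high-quality vectors", {
  fx <- lateral_chain_fixture(p_x = c(10, 20, 300), R = c(0.95, 0.92, 0.3))
  tab <- estimate_translation_table(fx$pairs, fx$tiles)
  expect_equal(tab$p_x, 15)
  expect_equal(tab$p_y, 0)
  expect_false(tab$fallback)
  # constant set: centroid equals the constant
  fx2 <- lateral_chain_fixture(p_x = c(12, 12, 300), R = c(0.95, 0.92, 0.3))
  tab2 <- estimate_translation_table(fx2$pairs, fx2$tiles)
  expect_equal(tab2$p_x, 12)
  # a rejected pair never feeds the pool, however high its R: pair 1 has
  # R = 0.95 but a 350 px initial residual
  fx3 <- lateral_chain_fixture(p_x = c(-335, 20, 300), R = c(0.95, 0.92, 0.3))
  tab3 <- estimate_translation_table(fx3$pairs, fx3$tiles)
  expect_equal(tab3$p_x, 20)
  # no high-quality member: stage-offset fallback, flagged and warned
  fx4 <- lateral_chain_fixture(p_x = c(13, 17, 300), R = c(0.5, 0.5, 0.5))
  expect_warning(tab4 <- estimate_translation_table(fx4$pairs, fx4$tiles),
                 "falling back")
  expect_true(tab4$fallback)
  expect_equal(tab4$p_x, 15)  # mean stage offset x_i - x_j
})

test_that("correct_pairs resets flagged pairs to R = 0.5 with table p and is idempotent", {
  fx <- small_hex()
  synth <- fx$synth
  pairs <- build_overlap_graph(synth$acq, expand = 20)
  al <- align_pairs(pairs, synth$acq, margin = 32)
  # replace one tile by pure noise: its incident pairs must be corrected,
  # everything else bit-identical
  noisy <- synth$acq
  victim <- "m001_b03"
  set.seed(5)
  vi <- match(victim, noisy$tiles$tile_id)
  noisy$tiles$image[[vi]] <- matrix(runif(112 * 128, 0, 255), 112, 128)
  al_noisy <- align_pairs(pairs, noisy, margin = 32)
  corr <- correct_pairs(al_noisy, noisy)
  incident <- corr$tile_i == victim | corr$tile_j == victim
  expect_true(all(corr$corrected[incident] != "NONE"))
  expect_true(all(corr$R[incident] == 0.5))
  others_before <- al_noisy[!incident, ]
  others_after <- corr[!incident, setdiff(names(corr), c("r0_orig_x", "r0_orig_y"))]
  expect_equal(others_after, others_before)
  # corrected pairs satisfy the R criterion afterwards
  reflagged <- flag_unsatisfactory(corr, noisy)
  expect_true(all(reflagged$reason != "LOW_R"))
  # corrected r0 is recomputed from stage positions and replacement p
  i <- match(corr$tile_i, noisy$tiles$tile_id)
  j <- match(corr$tile_j, noisy$tiles$tile_id)
  expect_equal(corr$r0_x, (noisy$tiles$x[i] - noisy$tiles$x[j]) - corr$p_x)
  expect_equal(corr$r0_y, (noisy$tiles$y[i] - noisy$tiles$y[j]) - corr$p_y)
  # idempotence
  expect_equal(correct_pairs(corr, noisy), corr)
})

test_that("a fully satisfactory pair table passes through unchanged", {
  tiles <- two_tile_pair(offset_x = 100L)
  pairs <- align_pairs(build_overlap_graph(tiles), tiles, margin = 24)
  corr <- correct_pairs(pairs, tiles)
  expect_equal(corr[, names(pairs)], pairs)
  expect_true(all(corr$corrected == "NONE"))
})
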