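test_that("blend weight map peaks centrally, is positive, and is flip-symmetric", {
  w <- blend_weight_map(21, 15)
  expect_equal(dim(w), c(15L, 21L))
  expect_true(all(w > 0))
  expect_equal(max(w), 1)
  expect_equal(w[8, 11], 1)                      # centre pixel is the maximum
  expect_equal(min(w), w[1, 1])                  # corner is the minimum
  expect_equal(w, w[15:1, ], ignore_attr = TRUE) # vertical flip
  expect_equal(w, w[, 21:1], ignore_attr = TRUE) # horizontal flip
})

test_that("a single tile composites to itself bit-exactly", {
  scene <- small_scene()
  img <- scene[1:64, 1:80]
  tiles <- tibble::tibble(tile_id = "a", mfov_id = 1L, beam_index = 0L,
                          x = 37, y = 12, width = 80L, height = 64L,
                          image = list(img))
  store <- withr::local_tempdir()
  mf <- composite_mosaic(tiles, tibble::tibble(tile_id = "a", x = 37, y = 12),
                         store, chunk_size = 256L)
  expect_equal(c(mf$width, mf$height), c(80L, 64L))
  expect_equal(c(mf$origin_x, mf$origin_y), c(37, 12))
  out <- read_mosaic_region(store, 0, 0, 80, 64)
  expect_equal(out, matrix(as.numeric(img), 64, 80), tolerance = 0)
})

test_that("perfectly registered overlapping tiles reproduce the source bit-exactly", {
  scene <- small_scene()
  tiles <- two_tile_pair(offset_x = 100L)
  store <- withr::local_tempdir()
  mf <- composite_mosaic(tiles, tibble::tibble(tile_id = c("a", "b"),
                                               x = c(0, 100), y = c(0, 0)),
                         store, chunk_size = 512L)
  out <- read_mosaic_region(store, 0, 0, mf$width, mf$height)
  src <- scene[1:112, 1:228]
  expect_equal(out, matrix(as.numeric(src), 112, 228), tolerance = 0)
})

test_that("chunked compositing equals single-chunk compositing", {
  fx <- small_hex()
  pos <- dplyr::transmute(fx$synth$truth, tile_id, x = true_x, y = true_y)
  s1 <- withr::local_tempdir(); s2 <- withr::local_tempdir()
  mf1 <- composite_mosaic(fx$synth$acq, pos, s1, chunk_size = 150L)
  mf2 <- composite_mosaic(fx$synth$acq, pos, s2, chunk_size = 4096L)
  expect_equal(mf1$width, mf2$width)
  a <- read_mosaic_region(s1, 0, 0, mf1$width, mf1$height)
  b <- read_mosaic_region(s2, 0, 0, mf2$width, mf2$height)
  expect_equal(a, b, tolerance = 0)
})

test_that("registered synthetic mosaic matches the ground-truth scene closely", {
  fx <- small_grid()
  synth <- fx$synth
  pairs <- align_pairs(build_overlap_graph(synth$acq, expand = 20),
                       synth$acq, margin = 32)
  corr <- correct_pairs(pairs, synth$acq)
  reg <- solve_least_squares(synth$acq, corr, weighted = TRUE)
  pos <- tidy(reg)[, c("tile_id", "x", "y")]
  # remove the anchor gauge before comparing against scene coordinates
  idx <- match(pos$tile_id, synth$truth$tile_id)
  pos$x <- pos$x - round(mean(pos$x - synth$truth$true_x[idx]))
  pos$y <- pos$y - round(mean(pos$y - synth$truth$true_y[idx]))
  store <- withr::local_tempdir()
  mf <- composite_mosaic(synth$acq, pos, store, chunk_size = 1024L)
  out <- read_mosaic_region(store, 0, 0, mf$width, mf$height)
  src <- fx$scene[(mf$origin_y + 1):(mf$origin_y + mf$height),
                  (mf$origin_x + 1):(mf$origin_x + mf$width)]
  covered <- out > 0
  expect_lt(mean(abs(out - src)[covered]), 1)
})

test_that("an empty tile set cannot be composited", {
  empty <- tibble::tibble(tile_id = character(), mfov_id = integer(),
                          beam_index = integer(), x = double(), y = double(),
                          width = integer(), height = integer(), image = list())
  expect_error(composite_mosaic(empty, tibble::tibble(tile_id = character(),
                                                      x = double(), y = double()),
                                withr::local_tempdir()),
               "empty")
})

test_that("bilinear placement reduces to integer placement at integer positions", {
  tiles <- two_tile_pair(offset_x = 100L)
  pos <- tibble::tibble(tile_id = c("a", "b"), x = c(0, 100), y = c(0, 0))
  s1 <- withr::local_tempdir(); s2 <- withr::local_tempdir()
  composite_mosaic(tiles, pos, s1, chunk_size = 512L, bilinear = FALSE)
  composite_mosaic(tiles, pos, s2, chunk_size = 512L, bilinear = TRUE)
  a <- read_mosaic_region(s1, 0, 0, 228, 112)
  b <- read_mosaic_region(s2, 0, 0, 228, 112)
  expect_equal(a, b, tolerance = 0)
  # a half-pixel position blends the two neighbouring placements
  one <- tiles[1, ]
  pos_h <- tibble::tibble(tile_id = "a", x = 0.5, y = 0)
  s3 <- withr::local_tempdir()
  mf <- composite_mosaic(one, pos_h, s3, chunk_size = 512L, bilinear = TRUE)
  out <- read_mosaic_region(s3, 0, 0, mf$width, mf$height)
  img <- one$image[[1]]
  interior <- out[10, 11]   # x index 10 (0-based), covered by both splats
  expect_equal(interior, round((img[10, 10] + img[10, 11]) / 2), tolerance = 1)
})
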