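# Blended compositing into a chunked on-disk mosaic store. Real mosaics are
# far larger than memory, so the canvas is processed in fixed-size chunks:
# the store is a directory of 8-bit grayscale PNG chunk files plus a JSON
# manifest (canvas size, chunk size, canvas origin, background value).
# Seams are suppressed by distance-feathered linear blending.

#' Feathered blending weight map for one tile frame
#'
#' Per-pixel weight proportional to `1 +` the pixel's Chebyshev distance to
#' the nearest frame edge, normalised so the central maximum is 1. Strictly
#' positive everywhere, maximal at the frame centre, minimal at the corners;
#' the composite divides by the total weight so single-tile regions are
#' reproduced exactly.
#'
#' @param width,height Frame dimensions in pixels.
#' @return A `height` x `width` numeric weight matrix in `(0, 1]`.
#' @export
blend_weight_map <- function(width, height) {
  stopifnot(width >= 1, height >= 1)
  dx <- pmin(seq_len(width) - 1L, width - seq_len(width))
  dy <- pmin(seq_len(height) - 1L, height - seq_len(height))
  w <- outer(dy + 1, dx + 1, pmin)
  w / max(w)
}

mosaic_manifest_path <- function(store) file.path(store, "mosaic.json")

read_mosaic_manifest <- function(store) {
  p <- mosaic_manifest_path(store)
  if (!file.exists(p)) abort(paste0("not a mosaic store: '", store, "'"))
  jsonlite::read_json(p, simplifyVector = TRUE)
}

chunk_file <- function(store, cy, cx) {
  file.path(store, sprintf("chunk_%d_%d.png", cy, cx))
}

#' Composite registered tiles into a chunked mosaic store
#'
#' Places every tile at its (rounded) registered position and blends
#' overlapping tiles with the feathered weights of [blend_weight_map()]:
#' each output pixel is `sum(w * I) / sum(w)` over covering tiles, with
#' uncovered pixels set to `background`. The canvas is the bounding box of
#' all placed tiles and is processed chunk by chunk, so peak memory is
#' proportional to the chunk area, never the canvas area.
#'
#' @param tiles An `msem_acquisition` or tiles tibble (images in memory).
#' @param positions Position tibble (`tile_id`, `x`, `y`); e.g.
#'   `tidy(registration)`.
#' @param store Output directory for the chunk store (created if needed).
#' @param chunk_size Chunk side in pixels; must be at least the tile frame
#'   dimensions (default 2048).
#' @param background Intensity for uncovered pixels (default 0; SEM void
#'   regions are dark).
#' @param bilinear Place tiles at their fractional positions by bilinear
#'   splatting over the four neighbouring integer placements (default
#'   `FALSE`: positions are rounded to the nearest integer pixel, consistent
#'   with the integer-shift alignment model).
#' @return The manifest list (invisibly contains `width`, `height`,
#'   `origin_x`, `origin_y`, `chunk_size`, `background`).
#' @export
composite_mosaic <- function(tiles, positions, store, chunk_size = 2048L,
                             background = 0, bilinear = FALSE) {
  tiles <- as_tile_table(tiles)
  if (nrow(tiles) == 0L) abort("cannot composite an empty tile set")
  idx <- tile_index(tiles, positions$tile_id)
  if (length(idx) < nrow(tiles)) abort("positions must cover all tiles")
  if (bilinear) {
    px <- floor(positions$x)
    py <- floor(positions$y)
    frac_x <- positions$x - px
    frac_y <- positions$y - py
  } else {
    px <- round(positions$x)
    py <- round(positions$y)
    frac_x <- frac_y <- rep(0, length(px))
  }
  w <- tiles$width[idx]
  h <- tiles$height[idx]
  if (chunk_size < max(w) || chunk_size < max(h)) {
    abort("chunk_size must be at least the tile frame dimensions")
  }
  ox <- min(px)
  oy <- min(py)
  W <- as.integer(max(px + (frac_x > 0) + w) - ox)
  H <- as.integer(max(py + (frac_y > 0) + h) - oy)
  dir.create(store, recursive = TRUE, showWarnings = FALSE)
  wmap <- blend_weight_map(tiles$width[1], tiles$height[1])
  ncx <- ceiling(W / chunk_size)
  ncy <- ceiling(H / chunk_size)
  for (cy in seq_len(ncy) - 1L) {
    for (cx in seq_len(ncx) - 1L) {
      x1 <- cx * chunk_size; y1 <- cy * chunk_size          # canvas coords
      cw <- min(chunk_size, W - x1); ch <- min(chunk_size, H - y1)
      num <- matrix(0, ch, cw)
      den <- matrix(0, ch, cw)
      hit <- which(px - ox < x1 + cw & px - ox + w + 1L > x1 &
                     py - oy < y1 + ch & py - oy + h + 1L > y1)
      for (t in hit) {
        k <- idx[t]
        # bilinear splat over the four neighbouring integer placements;
        # with integer positions only the (0, 0) corner carries weight
        for (cyo in 0:1) {
          for (cxo in 0:1) {
            wb <- (if (cxo) frac_x[t] else 1 - frac_x[t]) *
              (if (cyo) frac_y[t] else 1 - frac_y[t])
            if (wb <= 0) next
            tx <- px[t] + cxo - ox - x1   # tile origin in chunk coords
            ty <- py[t] + cyo - oy - y1
            if (tx >= cw || ty >= ch || tx + w[t] <= 0 || ty + h[t] <= 0) next
            xs <- max(0L, tx):min(cw - 1L, tx + w[t] - 1L)
            ys <- max(0L, ty):min(ch - 1L, ty + h[t] - 1L)
            img <- tiles$image[[k]][ys - ty + 1L, xs - tx + 1L, drop = FALSE]
            wt <- wmap[ys - ty + 1L, xs - tx + 1L, drop = FALSE]
            num[ys + 1L, xs + 1L] <- num[ys + 1L, xs + 1L] + wb * wt * img
            den[ys + 1L, xs + 1L] <- den[ys + 1L, xs + 1L] + wb * wt
          }
        }
      }
      out <- matrix(background, ch, cw)
      covered <- den > 0
      out[covered] <- num[covered] / den[covered]
      write_tile_image(out, chunk_file(store, cy, cx))
    }
  }
  manifest <- list(
    width = W, height = H, origin_x = ox, origin_y = oy,
    chunk_size = as.integer(chunk_size), background = background,
    n_chunks_x = as.integer(ncx), n_chunks_y = as.integer(ncy)
  )
  jsonlite::write_json(manifest, mosaic_manifest_path(store), auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a rectangular region from a mosaic store
#'
#' Assembles the requested region from the chunk files; parts outside the
#' canvas are filled with the store's background value.
#'
#' @param store Mosaic store directory.
#' @param x,y Region top-left in canvas coordinates (0-based).
#' @param width,height Region dimensions in pixels.
#' @return A numeric intensity matrix (0..255 scale).
#' @export
read_mosaic_region <- function(store, x, y, width, height) {
  mf <- read_mosaic_manifest(store)
  out <- matrix(mf$background, height, width)
  cs <- mf$chunk_size
  x2 <- min(x + width, mf$width)
  y2 <- min(y + height, mf$height)
  if (x2 <= max(x, 0) || y2 <= max(y, 0)) return(out)
  cx_range <- (max(x, 0) %/% cs):((x2 - 1L) %/% cs)
  cy_range <- (max(y, 0) %/% cs):((y2 - 1L) %/% cs)
  for (cy in cy_range) {
    for (cx in cx_range) {
      f <- chunk_file(store, cy, cx)
      if (!file.exists(f)) next
      img <- read_tile_image(f)
      gx1 <- max(x, cx * cs); gx2 <- min(x2, cx * cs + ncol(img))
      gy1 <- max(y, cy * cs); gy2 <- min(y2, cy * cs + nrow(img))
      if (gx2 <= gx1 || gy2 <= gy1) next
      out[(gy1 - y + 1L):(gy2 - y), (gx1 - x + 1L):(gx2 - x)] <-
        img[(gy1 - cy * cs + 1L):(gy2 - cy * cs),
            (gx1 - cx * cs + 1L):(gx2 - cx * cs)]
    }
  }
  out
}
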