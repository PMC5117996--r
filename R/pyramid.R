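# Tiled-pyramid export. The full-resolution mosaic is partitioned into
# 256x256 PNG tiles forming the maximum zoom level; each coarser level is
# rendered by grouping squares of four child tiles (512x512) and
# downsampling to one 256x256 tile by 2x2 block averaging, doubling the
# pixel size per unitary decrement in zoom, until a level fits in a single
# tile. Directory layout follows the slippy-map scheme
# "(maxzoom-zoom)/y/y_x_(maxzoom-zoom).png".

#' Pyramid layout for a mosaic size
#'
#' @param width,height Full-resolution mosaic dimensions in pixels.
#' @param tile_size Pyramid tile side (default 256).
#' @return A list of class `pyramid_layout`: `tile_size`, `max_zoom`, and
#'   `levels`, a tibble with one row per zoom (`zoom`, `width`, `height`,
#'   `tiles_x`, `tiles_y`), zoom `max_zoom` being full resolution and zoom 0
#'   a single tile.
#' @export
pyramid_layout <- function(width, height, tile_size = 256L) {
  stopifnot(width >= 1, height >= 1, tile_size >= 1)
  tx <- as.integer(ceiling(width / tile_size))
  ty <- as.integer(ceiling(height / tile_size))
  levels <- list(list(tiles_x = tx, tiles_y = ty,
                      width = as.integer(width), height = as.integer(height)))
  while (tx > 1L || ty > 1L) {
    tx <- as.integer(ceiling(tx / 2))
    ty <- as.integer(ceiling(ty / 2))
    lv <- levels[[length(levels)]]
    levels[[length(levels) + 1L]] <- list(
      tiles_x = tx, tiles_y = ty,
      width = as.integer(ceiling(lv$width / 2)),
      height = as.integer(ceiling(lv$height / 2))
    )
  }
  max_zoom <- length(levels) - 1L
  tab <- dplyr::bind_rows(lapply(levels, tibble::as_tibble))
  tab$zoom <- max_zoom:0L
  structure(
    list(tile_size = as.integer(tile_size), max_zoom = max_zoom,
         levels = tab[order(tab$zoom), c("zoom", "width", "height", "tiles_x", "tiles_y")]),
    class = "pyramid_layout"
  )
}

#' Relative path of one pyramid tile
#'
#' Implements the web-map directory template
#' `"(maxzoom-zoom)/y/y_x_(maxzoom-zoom).png"`, so the full-resolution level
#' lives in directory `0/`.
#'
#' @param zoom Zoom level, 0 (coarsest) to `max_zoom` (full resolution).
#' @param x,y Tile column and row within the level (0-based).
#' @param max_zoom Maximum zoom level of the pyramid.
#' @return Relative path string.
#' @export
pyramid_tile_path <- function(zoom, x, y, max_zoom) {
  if (any(zoom < 0 | zoom > max_zoom)) abort("zoom out of range [0, max_zoom]")
  if (any(x < 0 | y < 0)) abort("tile indices must be non-negative")
  inv <- max_zoom - zoom
  sprintf("%d/%d/%d_%d_%d.png", inv, y, y, x, inv)
}

#' Render the tiled pyramid of a mosaic store
#'
#' Writes the full-resolution level directly from the mosaic chunks (edge
#' tiles padded with the background value), then renders each coarser level
#' from the level below by 2x2 block averaging, and emits a JSON manifest
#' plus a minimal static HTML stub pointing any slippy-map viewer at the
#' tile directory.
#'
#' @param store Mosaic store directory (from [composite_mosaic()]).
#' @param out_dir Output directory for the pyramid.
#' @param tile_size Pyramid tile side (default 256).
#' @return The [pyramid_layout()] used, invisibly.
#' @export
build_pyramid <- function(store, out_dir, tile_size = 256L) {
  mf <- read_mosaic_manifest(store)
  layout <- pyramid_layout(mf$width, mf$height, tile_size)
  mz <- layout$max_zoom
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create out_dir '", out_dir, "'"))
  bg <- mf$background
  ts <- layout$tile_size
  # full-resolution level
  base <- layout$levels[layout$levels$zoom == mz, ]
  for (tyi in seq_len(base$tiles_y) - 1L) {
    for (txi in seq_len(base$tiles_x) - 1L) {
      img <- read_mosaic_region(store, txi * ts, tyi * ts, ts, ts)
      write_pyramid_tile(img, out_dir, mz, txi, tyi, mz)
    }
  }
  # coarser levels from 2x2 squares of children
  for (z in rev(seq_len(mz)) - 1L) {
    lv <- layout$levels[layout$levels$zoom == z, ]
    child <- layout$levels[layout$levels$zoom == z + 1L, ]
    for (tyi in seq_len(lv$tiles_y) - 1L) {
      for (txi in seq_len(lv$tiles_x) - 1L) {
        sq <- matrix(bg, 2L * ts, 2L * ts)
        for (dy in 0:1) {
          for (dx in 0:1) {
            cxi <- 2L * txi + dx
            cyi <- 2L * tyi + dy
            if (cxi >= child$tiles_x || cyi >= child$tiles_y) next
            f <- file.path(out_dir, pyramid_tile_path(z + 1L, cxi, cyi, mz))
            sq[dy * ts + seq_len(ts), dx * ts + seq_len(ts)] <- read_tile_image(f)
          }
        }
        write_pyramid_tile(block_mean_2x2(sq), out_dir, z, txi, tyi, mz)
      }
    }
  }
  manifest <- list(
    tile_size = ts, max_zoom = mz,
    width = mf$width, height = mf$height,
    levels = layout$levels, background = bg,
    path_template = "(maxzoom-zoom)/y/y_x_(maxzoom-zoom).png"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "pyramid.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(pyramid_html_stub(manifest), file.path(out_dir, "index.html"))
  invisible(layout)
}

write_pyramid_tile <- function(img, out_dir, zoom, x, y, max_zoom) {
  rel <- pyramid_tile_path(zoom, x, y, max_zoom)
  path <- file.path(out_dir, rel)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_tile_image(img, path)
  invisible(rel)
}

# 2x2 block mean of an even-dimension matrix.
block_mean_2x2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(h %% 2 == 0, w %% 2 == 0)
  (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
     m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)]) / 4
}

pyramid_html_stub <- function(manifest) {
  c(
    "<!DOCTYPE html>",
    "<html><head><title>mosaic pyramid</title></head><body>",
    sprintf("<p>Tiled pyramid: %d zoom levels (0&ndash;%d), %dx%d px tiles.</p>",
            manifest$max_zoom + 1L, manifest$max_zoom, manifest$tile_size,
            manifest$tile_size),
    "<p>Tile path template: <code>(maxzoom-zoom)/y/y_x_(maxzoom-zoom).png</code>;",
    "point any slippy-map viewer at this directory.</p>",
    "</body></html>"
  )
}
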