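# Overlap graph construction. Tiles are axis-aligned frames placed at their
# stage positions; every pair of frames whose intersection is at least
# min_overlap_area pixels becomes an edge of the graph. Edges carry the
# predicted intersection rectangle and an overlap-type label used later to
# pool translation estimates.

#' Build the tile overlap graph
#'
#' Returns one row per unordered pair of tiles whose frames, placed at their
#' stage positions, intersect with area at least `min_overlap_area`. Within a
#' pair, `tile_i` is the tile that comes first in lexicographic
#' (`mfov_id`, `beam_index`) order; all relative quantities (`p`, residuals)
#' are reported for that orientation, i.e. as optimal `x_i - x_j`.
#'
#' @param tiles An `msem_acquisition` or its tiles tibble.
#' @param min_overlap_area Minimum intersection area in px^2 (default 16 x 16)
#'   below which a pair is dropped; slivers carry too few pixels for phase
#'   correlation to be meaningful.
#' @param expand Stage-uncertainty margin in pixels: each frame is inflated
#'   by this amount on every side before intersecting, so that true overlaps
#'   hidden by stage error still become graph edges. 0 (the default)
#'   intersects the frames exactly as placed; the pipeline passes the
#'   instrument's stage precision converted to pixels. The reported
#'   `overlap_rect` is the (possibly inflated) predicted intersection.
#' @return A tibble with columns `tile_i`, `tile_j`, `type`, the predicted
#'   overlap rectangle (`ov_x`, `ov_y`, `ov_w`, `ov_h`, global pixel
#'   coordinates), and placeholder alignment columns (`R`, `p_x`, `p_y`,
#'   `r0_x`, `r0_y`, `corrected = "NONE"`).
#' @export
build_overlap_graph <- function(tiles, min_overlap_area = 256, expand = 0) {
  tiles <- as_tile_table(tiles)
  n <- nrow(tiles)
  empty <- tibble::tibble(
    tile_i = character(), tile_j = character(), type = character(),
    ov_x = double(), ov_y = double(), ov_w = double(), ov_h = double(),
    weak = logical(),
    R = double(), p_x = double(), p_y = double(),
    r0_x = double(), r0_y = double(), corrected = character()
  )
  if (n < 2L) return(empty)
  ord <- order(tiles$mfov_id, tiles$beam_index)
  tl <- tiles[ord, ]
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  x1 <- pmax(tl$x[i] - expand, tl$x[j] - expand)
  y1 <- pmax(tl$y[i] - expand, tl$y[j] - expand)
  x2 <- pmin(tl$x[i] + tl$width[i] + expand, tl$x[j] + tl$width[j] + expand)
  y2 <- pmin(tl$y[i] + tl$height[i] + expand, tl$y[j] + tl$height[j] + expand)
  w <- x2 - x1
  h <- y2 - y1
  keep <- w > 0 & h > 0 & (w * h) >= min_overlap_area
  if (!any(keep)) return(empty)
  i <- i[keep]; j <- j[keep]
  # evidence class: pairs whose *uninflated* predicted overlap is below the
  # area floor only exist because of the stage-uncertainty inflation, and
  # their alignment needs strong correlation evidence to be trusted
  ux1 <- pmax(tl$x[i], tl$x[j])
  uy1 <- pmax(tl$y[i], tl$y[j])
  uw <- pmin(tl$x[i] + tl$width[i], tl$x[j] + tl$width[j]) - ux1
  uh <- pmin(tl$y[i] + tl$height[i], tl$y[j] + tl$height[j]) - uy1
  weak <- !(uw > 0 & uh > 0 & (uw * uh) >= min_overlap_area)
  pairs <- tibble::tibble(
    tile_i = tl$tile_id[i],
    tile_j = tl$tile_id[j],
    type = classify_overlap_type(
      same_mfov = tl$mfov_id[i] == tl$mfov_id[j],
      dx = tl$x[i] - tl$x[j],
      dy = tl$y[i] - tl$y[j],
      width = tl$width[i],
      height = tl$height[i]
    ),
    ov_x = x1[keep], ov_y = y1[keep], ov_w = w[keep], ov_h = h[keep],
    weak = weak,
    R = NA_real_, p_x = NA_real_, p_y = NA_real_,
    r0_x = NA_real_, r0_y = NA_real_, corrected = "NONE"
  )
  pairs[order(pairs$tile_i, pairs$tile_j), ]
}

#' Classify the geometric type of an overlapping pair
#'
#' Every label encodes the pair's geometric relation on the acquisition
#' lattice via the stage displacement `x_i - x_j` quantized to half-frame
#' units `(qx, qy)`. Same-mFOV pairs are `INTRA_1.<qx>` (lateral, same hex
#' row) or `INTRA_2.<qx>.<qy>` (adjacent-row diagonals and any other
#' intra-mFOV relation; the two diagonal directions get distinct `qx`
#' signs). Pairs spanning two mFOVs are `INTER_<b>.<qx>.<qy>` with `b` the
#' 45-degree direction bin (bin 0 centred on +x, counted clockwise on
#' screen, y down). Direction alone is not enough: two border pairs in the
#' same direction bin can sit a whole tile pitch apart, and pooling their
#' translation vectors would average incompatible offsets; the quantized
#' offset is what identifies the relation. Same geometric relation implies
#' the same label, which is what lets the correction stage pool translation
#' estimates per type. Stage jitter well below half a frame never changes a
#' label.
#'
#' @param same_mfov Logical vector: do the two tiles share an mFOV?
#' @param dx,dy Components of the stage displacement `x_i - x_j` in pixels.
#' @param width,height Tile frame dimensions in pixels (the lateral/diagonal
#'   separation and the lattice quantum are relative to the frame).
#' @return Character vector of type labels.
#' @export
classify_overlap_type <- function(same_mfov, dx, dy, width, height) {
  qx <- round(2 * dx / width)
  qy <- round(2 * dy / height)
  intra <- ifelse(abs(dy) < height / 4,
                  sprintf("INTRA_1.%d", qx),
                  sprintf("INTRA_2.%d.%d", qx, qy))
  ang <- atan2(dy, dx) * 180 / pi
  bin <- (round(ang / 45) %% 8 + 8) %% 8
  ifelse(same_mfov, intra, sprintf("INTER_%d.%d.%d", bin, qx, qy))
}

# Look up tile rows for a pair table; errors on unknown ids.
tile_index <- function(tiles, ids) {
  idx <- match(ids, tiles$tile_id)
  if (anyNA(idx)) {
    abort(paste0("unknown tile_id '", ids[which(is.na(idx))[1]], "'"))
  }
  idx
}
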