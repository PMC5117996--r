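# Pairwise translation estimation by Fourier phase correlation.
#
# Shift convention: phase_correlate(a, b) returns the integer vector
# s = (sx, sy) maximising the match b(y, x) ~ a(y + sy, x + sx), i.e. the
# position of b's content relative to a's, x right / y down. The correlation
# surface is the inverse transform of the normalised cross-power spectrum;
# each surface peak has four periodic interpretations which are disambiguated
# by scoring the Pearson correlation of the overlap pixels each implies.

#' Phase-correlate two equally sized image regions
#'
#' Estimates the integer translation between two regions from the peak of the
#' inverse-transformed normalised cross-power spectrum, then scores the top
#' candidate peaks by the Pearson correlation of the overlap pixels they
#' imply and returns the best. The quality score `R` is that maximal Pearson
#' correlation clipped to `[0, 1]` (negative correlations score 0).
#'
#' @param a,b Numeric matrices of identical dimensions (side >= 8 px).
#' @param max_shift Maximum absolute shift searched, per axis, in pixels.
#' @param n_peaks Number of correlation-surface peaks considered (default 4).
#' @param min_overlap_px Minimum implied-overlap pixel count for a candidate
#'   to be scored.
#' @param window `"none"` (default) or `"hann"` apodization applied after
#'   mean subtraction.
#' @param subpixel Refine the winning integer shift by fitting a parabola
#'   through the correlation scores of its axis neighbours (default `FALSE`:
#'   integer shifts, matching the whole-pixel residual model used
#'   downstream).
#' @return A list with `shift` (c(sx, sy); fractional when
#'   `subpixel = TRUE`), `R`, `n_peaks_tested`, and `degenerate` (TRUE when
#'   either region has zero variance, in which case `shift = c(0, 0)` and
#'   `R = 0`).
#' @export
phase_correlate <- function(a, b, max_shift, n_peaks = 4L,
                            min_overlap_px = 32L,
                            window = c("none", "hann"),
                            subpixel = FALSE) {
  window <- match.arg(window)
  stopifnot(is.matrix(a), is.matrix(b))
  if (!all(dim(a) == dim(b))) abort("regions must have identical dimensions")
  if (min(dim(a)) < 8L) abort("regions must be at least 8 px on a side")
  if (max_shift < 0) abort("max_shift must be non-negative")
  H <- nrow(a); W <- ncol(a)
  if (sd(a) == 0 || sd(b) == 0) {
    return(list(shift = c(0L, 0L), R = 0, n_peaks_tested = 0L, degenerate = TRUE))
  }
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  if (window == "hann") {
    wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(H) - 1) / (H - 1))
    wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(W) - 1) / (W - 1))
    taper <- outer(wy, wx)
    a0 <- a0 * taper
    b0 <- b0 * taper
  }
  cp <- fft(a0) * Conj(fft(b0))
  surf <- Re(fft(cp / pmax(Mod(cp), .Machine$double.eps), inverse = TRUE)) / (H * W)
  # restrict to surface bins with at least one periodic interpretation
  # inside the search window
  r0 <- (seq_len(H) - 1L)
  c0 <- (seq_len(W) - 1L)
  row_ok <- pmin(r0, H - r0) <= max_shift
  col_ok <- pmin(c0, W - c0) <= max_shift
  masked <- surf
  masked[!row_ok, ] <- -Inf
  masked[, !col_ok] <- -Inf
  n_take <- min(n_peaks, sum(row_ok) * sum(col_ok))
  peak_idx <- order(masked, decreasing = TRUE)[seq_len(n_take)]
  best <- list(R = -Inf, shift = c(0L, 0L))
  tested <- 0L
  for (idx in peak_idx) {
    pr <- (idx - 1L) %% H        # 0-based row
    pc <- (idx - 1L) %/% H       # 0-based col
    for (dy in unique(c(pr, pr - H))) {
      for (dx in unique(c(pc, pc - W))) {
        if (abs(dy) > max_shift || abs(dx) > max_shift) next
        sc <- shift_ncc(a, b, dx, dy, min_overlap_px)
        if (is.na(sc)) next
        tested <- tested + 1L
        if (better_candidate(sc, c(dx, dy), best)) {
          best <- list(R = sc, shift = c(dx, dy))
        }
      }
    }
  }
  if (!is.finite(best$R)) {
    return(list(shift = c(0L, 0L), R = 0, n_peaks_tested = tested, degenerate = FALSE))
  }
  shift <- as.integer(best$shift)
  out_shift <- if (subpixel) {
    refine_subpixel(a, b, shift, min_overlap_px)
  } else {
    shift
  }
  list(
    shift = out_shift,
    R = min(max(best$R, 0), 1),
    n_peaks_tested = tested,
    degenerate = FALSE
  )
}

# One-dimensional parabolic refinement around the winning integer shift,
# per axis, on the explicit correlation scores.
refine_subpixel <- function(a, b, shift, min_overlap_px) {
  refine_axis <- function(scores) {
    if (anyNA(scores)) return(0)
    denom <- scores[1] - 2 * scores[2] + scores[3]
    if (denom >= 0) return(0)   # not a local maximum
    delta <- 0.5 * (scores[1] - scores[3]) / denom
    max(min(delta, 0.5), -0.5)
  }
  sx <- shift[1]; sy <- shift[2]
  dx <- refine_axis(c(shift_ncc(a, b, sx - 1L, sy, min_overlap_px),
                      shift_ncc(a, b, sx, sy, min_overlap_px),
                      shift_ncc(a, b, sx + 1L, sy, min_overlap_px)))
  dy <- refine_axis(c(shift_ncc(a, b, sx, sy - 1L, min_overlap_px),
                      shift_ncc(a, b, sx, sy, min_overlap_px),
                      shift_ncc(a, b, sx, sy + 1L, min_overlap_px)))
  c(sx + dx, sy + dy)
}

# Pearson correlation of the pixels implied by candidate shift (dx, dy)
# under b(y, x) = a(y + dy, x + dx). NA when the implied overlap is too
# small or constant.
shift_ncc <- function(a, b, dx, dy, min_overlap_px) {
  H <- nrow(a); W <- ncol(a)
  r1 <- max(1L, 1L - dy); r2 <- min(H, H - dy)
  c1 <- max(1L, 1L - dx); c2 <- min(W, W - dx)
  if (r2 < r1 || c2 < c1 || (r2 - r1 + 1L) * (c2 - c1 + 1L) < min_overlap_px) {
    return(NA_real_)
  }
  rb <- r1:r2
  cb <- c1:c2
  va <- as.vector(a[rb + dy, cb + dx, drop = FALSE])
  vb <- as.vector(b[rb, cb, drop = FALSE])
  if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
  cor(va, vb)
}

# Deterministic tie-break: higher correlation, then smaller shift magnitude,
# then lexicographic (sx, sy).
better_candidate <- function(score, shift, best) {
  if (score > best$R + 1e-12) return(TRUE)
  if (score < best$R - 1e-12) return(FALSE)
  m_new <- sum(shift^2)
  m_old <- sum(best$shift^2)
  if (m_new != m_old) return(m_new < m_old)
  if (shift[1] != best$shift[1]) return(shift[1] < best$shift[1])
  shift[2] < best$shift[2]
}

#' Align one overlapping pair of tiles
#'
#' Extracts the predicted overlap rectangle expanded by `margin` from each
#' tile (clipped to each frame), phase-correlates the two regions, and
#' converts the detected region shift into the global alignment vector
#' `p = optimal (x_i - x_j)`. The initial residual `r0 = (stage_i - stage_j)
#' - p` is stored alongside.
#'
#' @param pair One-row slice of the overlap-graph tibble.
#' @param tiles An `msem_acquisition` or tiles tibble.
#' @param margin Search margin in pixels around the predicted overlap
#'   (default 150; choose several times the expected stage error).
#' @param ... Passed on to [phase_correlate()].
#' @return The pair row with `R`, `p_x`, `p_y`, `r0_x`, `r0_y` filled in;
#'   pairs whose expanded regions are below the minimum correlation size are
#'   flagged `corrected = "NO_OVERLAP_RESULT"` with `R = 0`.
#' @export
align_pair <- function(pair, tiles, margin = 150, ...) {
  tiles <- as_tile_table(tiles)
  i <- tile_index(tiles, pair$tile_i)
  j <- tile_index(tiles, pair$tile_j)
  rx <- pair$ov_x - margin
  ry <- pair$ov_y - margin
  rw <- pair$ov_w + 2 * margin
  rh <- pair$ov_h + 2 * margin
  crop_i <- crop_to_frame(tiles, i, rx, ry, rw, rh)
  crop_j <- crop_to_frame(tiles, j, rx, ry, rw, rh)
  stage_d <- c(tiles$x[i] - tiles$x[j], tiles$y[i] - tiles$y[j])
  if (is.null(crop_i) || is.null(crop_j) ||
      min(nrow(crop_i$img), nrow(crop_j$img)) < 8L ||
      min(ncol(crop_i$img), ncol(crop_j$img)) < 8L) {
    pair$R <- 0
    pair$p_x <- stage_d[1]; pair$p_y <- stage_d[2]
    pair$r0_x <- 0; pair$r0_y <- 0
    pair$corrected <- "NO_OVERLAP_RESULT"
    return(pair)
  }
  ch <- min(nrow(crop_i$img), nrow(crop_j$img))
  cw <- min(ncol(crop_i$img), ncol(crop_j$img))
  region_i <- crop_i$img[seq_len(ch), seq_len(cw), drop = FALSE]
  region_j <- crop_j$img[seq_len(ch), seq_len(cw), drop = FALSE]
  d_origin <- c(crop_j$origin[1] - crop_i$origin[1],
                crop_j$origin[2] - crop_i$origin[2])
  max_shift <- min(margin + max(abs(d_origin)), max(ch, cw) - 4)
  pc <- phase_correlate(region_i, region_j, max_shift = max_shift, ...)
  if (pc$degenerate) {
    pair$R <- 0
    pair$p_x <- stage_d[1]; pair$p_y <- stage_d[2]
    pair$r0_x <- 0; pair$r0_y <- 0
    pair$corrected <- "NO_OVERLAP_RESULT"
    return(pair)
  }
  rel_err <- pc$shift - d_origin   # e_i - e_j, stage error difference
  p <- stage_d - rel_err
  pair$R <- pc$R
  pair$p_x <- p[1]; pair$p_y <- p[2]
  pair$r0_x <- rel_err[1]; pair$r0_y <- rel_err[2]
  pair
}

# Crop tile `idx` at the global rectangle (rx, ry, rw, rh), clipped to the
# tile frame; returns NULL when the clipped rectangle is empty. `origin` is
# the actual global position of the crop's top-left pixel.
crop_to_frame <- function(tiles, idx, rx, ry, rw, rh) {
  lx <- round(rx - tiles$x[idx])
  ly <- round(ry - tiles$y[idx])
  x1 <- max(0L, lx); y1 <- max(0L, ly)
  x2 <- min(tiles$width[idx], lx + round(rw))
  y2 <- min(tiles$height[idx], ly + round(rh))
  if (x2 - x1 < 1L || y2 - y1 < 1L) return(NULL)
  img <- tiles$image[[idx]][(y1 + 1L):y2, (x1 + 1L):x2, drop = FALSE]
  list(img = img, origin = c(tiles$x[idx] + x1, tiles$y[idx] + y1))
}

#' Align every pair of the overlap graph
#'
#' Runs [align_pair()] over all rows of a pair table.
#'
#' @inheritParams align_pair
#' @param pairs Overlap-graph tibble from [build_overlap_graph()].
#' @return The pair tibble with alignment columns filled.
#' @export
align_pairs <- function(pairs, tiles, margin = 150, ...) {
  tiles <- as_tile_table(tiles)
  if (nrow(pairs) == 0L) return(pairs)
  rows <- purrr::map(seq_len(nrow(pairs)), function(r) {
    align_pair(pairs[r, ], tiles, margin = margin, ...)
  })
  dplyr::bind_rows(rows)
}

#' Write / read a pair alignment table
#'
#' Delimited-text serialisation of the pair table
#' (`tile_i,tile_j,type,R,p_x,p_y,r0_x,r0_y,corrected` plus the predicted
#' overlap rectangle).
#'
#' @param pairs Pair tibble.
#' @param path Output CSV path.
#' @return `path` invisibly; `read_pair_table()` returns the tibble.
#' @export
write_pair_table <- function(pairs, path) {
  readr::write_csv(pairs, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
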