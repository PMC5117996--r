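# Synthetic mSEM acquisitions with known ground truth. The generator emulates
# the acquisition geometry of the instrument: hexagonal mFOVs (61 tiles in
# rows of 5,6,7,8,9,8,7,6,5), configurable tile frame and overlap fraction,
# stage positions perturbed by Gaussian jitter at the scale of the stage
# precision, and localized dark/blurred artifact regions. Everything is
# deterministic given (spec, seed).

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a ground-truth scene
#'
#' Band-limited noise with spatial autocorrelation length of several pixels
#' (so phase-correlation peaks are well defined) and non-degenerate variance
#' at tile scale, optionally overlaid with ring motifs reminiscent of
#' osteonal lamellae. Deterministic given the seed; intensities are integers
#' in `[0, 255]`.
#'
#' @param width,height Scene dimensions in pixels.
#' @param seed Integer seed.
#' @param texture `"noise"` (default) or `"osteon"` (noise plus ring motifs).
#' @return An integer intensity matrix.
#' @export
generate_scene <- function(width, height, seed = 1L,
                           texture = c("noise", "osteon")) {
  texture <- match.arg(texture)
  stopifnot(width >= 16, height >= 16)
  with_preserved_rng(seed, {
    scene <- upsampled_noise(width, height, grid = 8L)
    scene <- scene + 0.5 * upsampled_noise(width, height, grid = 4L)
    # full-band grain: micrographs carry fine shot-noise-like texture well
    # above the 8-bit quantization floor; without it the high-frequency
    # phase of the cross-power spectrum is meaningless
    scene <- scene + 0.25 * matrix(rnorm(width * height), height, width)
    if (texture == "osteon") {
      n_rings <- max(1L, round(width * height / 6e5))
      cx <- runif(n_rings, 0.1 * width, 0.9 * width)
      cy <- runif(n_rings, 0.1 * height, 0.9 * height)
      rad <- runif(n_rings, 40, min(width, height) / 4)
      for (r in seq_len(n_rings)) {
        scene <- add_ring_motif(scene, cx[r], cy[r], rad[r])
      }
    }
    scene <- (scene - mean(scene)) / sd(scene) * 30 + 128
    scene <- round(pmin(pmax(scene, 0), 255))
    storage.mode(scene) <- "integer"
    scene
  })
}

# White noise on a coarse grid, bilinearly upsampled to (height x width);
# processed in row bands to bound peak memory.
upsampled_noise <- function(width, height, grid) {
  gh <- ceiling(height / grid) + 1L
  gw <- ceiling(width / grid) + 1L
  g <- matrix(rnorm(gh * gw), gh, gw)
  out <- matrix(0, height, width)
  xs <- (seq_len(width) - 1) / grid
  cx0 <- pmin(floor(xs), gw - 2L)
  fx <- xs - cx0
  band <- 512L
  for (y1 in seq(1L, height, by = band)) {
    y2 <- min(y1 + band - 1L, height)
    ys <- (y1:y2 - 1) / grid
    cy0 <- pmin(floor(ys), gh - 2L)
    fy <- ys - cy0
    a00 <- g[cbind(rep(cy0 + 1L, times = width), rep(cx0 + 1L, each = length(ys)))]
    a10 <- g[cbind(rep(cy0 + 2L, times = width), rep(cx0 + 1L, each = length(ys)))]
    a01 <- g[cbind(rep(cy0 + 1L, times = width), rep(cx0 + 2L, each = length(ys)))]
    a11 <- g[cbind(rep(cy0 + 2L, times = width), rep(cx0 + 2L, each = length(ys)))]
    FY <- rep(fy, times = width)
    FX <- rep(fx, each = length(ys))
    vals <- (1 - FY) * (1 - FX) * a00 + FY * (1 - FX) * a10 +
      (1 - FY) * FX * a01 + FY * FX * a11
    out[y1:y2, ] <- matrix(vals, nrow = length(ys))
  }
  out
}

add_ring_motif <- function(scene, cx, cy, radius) {
  h <- nrow(scene); w <- ncol(scene)
  x1 <- max(1L, floor(cx - radius)); x2 <- min(w, ceiling(cx + radius))
  y1 <- max(1L, floor(cy - radius)); y2 <- min(h, ceiling(cy + radius))
  if (x2 <= x1 || y2 <= y1) return(scene)
  xs <- x1:x2; ys <- y1:y2
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  ring <- cos(2 * pi * d / 14) * exp(-(d / radius)^2) * 0.8
  scene[ys, xs] <- scene[ys, xs] + ring * (d <= radius)
  scene
}

hex_rows <- list(
  `1` = 1L, `7` = c(2L, 3L, 2L), `19` = c(3L, 4L, 5L, 4L, 3L),
  `37` = c(4L, 5L, 6L, 7L, 6L, 5L, 4L),
  `61` = c(5L, 6L, 7L, 8L, 9L, 8L, 7L, 6L, 5L)
)

#' Hexagonal in-mFOV tile layout
#'
#' Tile offsets for one hexagonal mFOV: 61 tiles in rows of 5,6,7,8,9,8,7,6,5
#' (centred hexagonal counts 1/7/19/37/61 supported), horizontal pitch
#' `width * (1 - overlap_fraction)`, vertical pitch chosen so adjacent rows
#' overlap by at least the same fraction; alternate rows are offset by half a
#' pitch. Every adjacent pair of tiles overlaps.
#'
#' @param tiles_per_mfov One of 1, 7, 19, 37, 61.
#' @param width,height Tile frame dimensions in pixels.
#' @param overlap_fraction Fractional overlap between lateral neighbours,
#'   within the instrument's 0.024-0.55 range.
#' @return A tibble with `beam_index` (0-based, row-major), `row`, and
#'   integer offsets `dx`, `dy` of each tile's top-left corner.
#' @export
hex_layout <- function(tiles_per_mfov = 61L, width = 322L, height = 280L,
                       overlap_fraction = 0.06) {
  rows <- hex_rows[[as.character(tiles_per_mfov)]]
  if (is.null(rows)) {
    abort("tiles_per_mfov must be a centred hexagonal count: 1, 7, 19, 37 or 61")
  }
  if (overlap_fraction < 0.024 || overlap_fraction > 0.55) {
    abort("overlap_fraction must lie within [0.024, 0.55]")
  }
  pitch_x <- floor(width * (1 - overlap_fraction))
  pitch_y <- floor(height * (1 - overlap_fraction))
  max_row <- max(rows)
  out <- purrr::imap(rows, function(s, r) {
    x0 <- round((max_row - s) * pitch_x / 2)
    tibble::tibble(
      row = r - 1L,
      dx = x0 + (seq_len(s) - 1L) * pitch_x,
      dy = (r - 1L) * pitch_y
    )
  })
  out <- dplyr::bind_rows(out)
  out$beam_index <- seq_len(nrow(out)) - 1L
  out[, c("beam_index", "row", "dx", "dy")]
}

#' Synthetic acquisition specification
#'
#' Defaults emulate the source instrument at quarter scale: 61-tile
#' hexagonal mFOVs, 322 x 280 px frames (1288 x 1120 at full scale), 6 %
#' overlap, and stage jitter of sigma = 15 px, consistent with a stage
#' precision of a couple of micrometres at quarter-scale pixel pitch.
#'
#' @param mfov_grid `(rows, cols)` of mFOVs.
#' @param tiles_per_mfov 1, 7, 19, 37 or 61.
#' @param tile_frame `(width, height)` in pixels.
#' @param overlap_fraction Lateral overlap fraction in `[0.024, 0.55]`.
#' @param jitter_sigma Stage-error standard deviation in pixels (iid per
#'   tile, rounded to integers).
#' @param mfov_offset_sigma Optional per-mFOV common stage offset sigma
#'   (default 0; real stage error is partly shared within an mFOV).
#' @param seed Integer seed.
#' @return A list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(mfov_grid = c(1L, 1L), tiles_per_mfov = 61L,
                             tile_frame = c(322L, 280L),
                             overlap_fraction = 0.06, jitter_sigma = 15,
                             mfov_offset_sigma = 0, seed = 1L) {
  stopifnot(length(mfov_grid) == 2L, all(mfov_grid >= 1L),
            jitter_sigma >= 0, mfov_offset_sigma >= 0)
  structure(
    list(mfov_grid = as.integer(mfov_grid),
         tiles_per_mfov = as.integer(tiles_per_mfov),
         tile_frame = as.integer(tile_frame),
         overlap_fraction = overlap_fraction,
         jitter_sigma = jitter_sigma,
         mfov_offset_sigma = mfov_offset_sigma,
         seed = as.integer(seed)),
    class = "acquisition_spec"
  )
}

# True tile positions (before jitter) for a spec: hex layout replicated on
# the mFOV grid, with mFOV pitch chosen so neighbouring mFOVs' border tiles
# overlap like intra-mFOV neighbours.
true_positions <- function(spec) {
  lay <- hex_layout(spec$tiles_per_mfov, spec$tile_frame[1],
                    spec$tile_frame[2], spec$overlap_fraction)
  pitch_x <- floor(spec$tile_frame[1] * (1 - spec$overlap_fraction))
  pitch_y <- floor(spec$tile_frame[2] * (1 - spec$overlap_fraction))
  max_row <- max(hex_rows[[as.character(spec$tiles_per_mfov)]])
  n_rows <- length(hex_rows[[as.character(spec$tiles_per_mfov)]])
  mfov_pitch_x <- max_row * pitch_x
  mfov_pitch_y <- n_rows * pitch_y
  grid <- expand.grid(gy = seq_len(spec$mfov_grid[1]) - 1L,
                      gx = seq_len(spec$mfov_grid[2]) - 1L)
  mfovs <- purrr::pmap(grid, function(gy, gx) {
    dplyr::mutate(lay,
      mfov_id = gy * spec$mfov_grid[2] + gx + 1L,
      true_x = .data$dx + gx * mfov_pitch_x,
      true_y = .data$dy + gy * mfov_pitch_y
    )
  })
  out <- dplyr::bind_rows(mfovs)
  out$tile_id <- sprintf("m%03d_b%02d", out$mfov_id, out$beam_index)
  out[, c("tile_id", "mfov_id", "beam_index", "true_x", "true_y")]
}

#' Scene size needed for an acquisition spec
#'
#' @param spec An [acquisition_spec()].
#' @return `c(width, height)` in pixels of the smallest scene covering all
#'   true tile positions.
#' @export
acquisition_scene_size <- function(spec) {
  tp <- true_positions(spec)
  c(max(tp$true_x) + spec$tile_frame[1], max(tp$true_y) + spec$tile_frame[2])
}

#' Generate a complete synthetic acquisition
#'
#' Crops every tile from the scene at its true (lattice) position, then
#' perturbs the recorded stage positions with integer-rounded iid Gaussian
#' jitter (plus an optional per-mFOV common offset). Tile pixel content is
#' exact scene content: stage jitter is metadata error only, exactly like a
#' real stage whose recorded coordinates are imprecise.
#'
#' @param scene Integer scene matrix from [generate_scene()], at least
#'   [acquisition_scene_size()] in each dimension.
#' @param spec An [acquisition_spec()].
#' @return A list of class `msem_synthetic`: `acq` (an `msem_acquisition`
#'   whose tile positions are the jittered stage estimates), `truth`
#'   (tibble `tile_id`, `true_x`, `true_y`), and `spec`.
#' @export
generate_acquisition <- function(scene, spec = acquisition_spec()) {
  tp <- true_positions(spec)
  need <- acquisition_scene_size(spec)
  if (ncol(scene) < need[1] || nrow(scene) < need[2]) {
    abort(sprintf("scene (%d x %d) smaller than required %d x %d px",
                  ncol(scene), nrow(scene), need[1], need[2]))
  }
  w <- spec$tile_frame[1]; h <- spec$tile_frame[2]
  images <- purrr::map2(tp$true_x, tp$true_y, function(x, y) {
    scene[(y + 1L):(y + h), (x + 1L):(x + w)]
  })
  with_preserved_rng(spec$seed, {
    jx <- round(rnorm(nrow(tp), 0, spec$jitter_sigma))
    jy <- round(rnorm(nrow(tp), 0, spec$jitter_sigma))
    if (spec$mfov_offset_sigma > 0) {
      mids <- sort(unique(tp$mfov_id))
      ox <- round(rnorm(length(mids), 0, spec$mfov_offset_sigma))
      oy <- round(rnorm(length(mids), 0, spec$mfov_offset_sigma))
      jx <- jx + ox[match(tp$mfov_id, mids)]
      jy <- jy + oy[match(tp$mfov_id, mids)]
    }
    tiles <- tibble::tibble(
      tile_id = tp$tile_id, mfov_id = tp$mfov_id, beam_index = tp$beam_index,
      x = tp$true_x + jx, y = tp$true_y + jy,
      width = w, height = h, image = images
    )
    # metadata describes the emulated instrument: quarter-scale pixel pitch,
    # stage precision = the +/-3 sigma bound of the injected jitter
    acq <- new_acquisition(tiles, meta = list(
      pixel_size_nm = 40,
      stage_precision_um = 3 * spec$jitter_sigma * 40 / 1000,
      tiles_per_mfov = spec$tiles_per_mfov
    ))
    structure(list(acq = acq, truth = tp[, c("tile_id", "true_x", "true_y")],
                   spec = spec),
              class = "msem_synthetic")
  })
}

#' @exportS3Method base::print
print.msem_synthetic <- function(x, ...) {
  cat(sprintf(
    "<msem_synthetic> %dx%d mFOV grid, %d tiles, jitter sigma %g px\n",
    x$spec$mfov_grid[1], x$spec$mfov_grid[2], nrow(x$acq$tiles),
    x$spec$jitter_sigma
  ))
  invisible(x)
}

#' Write a synthetic acquisition to disk
#'
#' Tile images plus metadata in the standard format, and a
#' `ground_truth.csv` (`tile_id,true_x,true_y`) for evaluation.
#'
#' @param synth An `msem_synthetic`.
#' @param dir Output directory.
#' @param format Image format (see [write_acquisition()]).
#' @return The metadata path, invisibly.
#' @export
write_synthetic_acquisition <- function(synth, dir, format = "png") {
  p <- write_acquisition(synth$acq, dir, format = format)
  readr::write_csv(synth$truth, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  invisible(p)
}

#' Inject dark / blurred artifact regions
#'
#' Emulates the topography-induced artifact regions of real acquisitions:
#' `DARK` multiplies in-region intensities by `1 - strength` and adds a
#' little detector noise; `BLUR` convolves the region with a Gaussian whose
#' radius grows with `strength`. Regions are given in global ground-truth
#' coordinates, so they cut across tile boundaries exactly as a specimen
#' concavity would. Geometry and tile order are unchanged.
#'
#' @param synth An `msem_synthetic`.
#' @param artifacts Tibble with columns `x`, `y`, `w`, `h` (global px),
#'   `kind` (`"DARK"` or `"BLUR"`) and `strength` in `[0, 1]`.
#' @param seed Seed for the artifact noise.
#' @return The modified `msem_synthetic` (with an `artifacts` element and a
#'   logical `artifact` column on the tiles marking affected tiles).
#' @export
inject_artifacts <- function(synth, artifacts, seed = 1L) {
  stopifnot(inherits(synth, "msem_synthetic"))
  tiles <- synth$acq$tiles
  truth <- synth$truth
  affected <- rep(FALSE, nrow(tiles))
  with_preserved_rng(seed, {
    for (a in seq_len(nrow(artifacts))) {
      kind <- artifacts$kind[a]
      strength <- artifacts$strength[a]
      if (strength <= 0) next
      ax1 <- artifacts$x[a]; ay1 <- artifacts$y[a]
      ax2 <- ax1 + artifacts$w[a]; ay2 <- ay1 + artifacts$h[a]
      for (t in seq_len(nrow(tiles))) {
        tx <- truth$true_x[t]; ty <- truth$true_y[t]
        x1 <- max(ax1, tx); x2 <- min(ax2, tx + tiles$width[t])
        y1 <- max(ay1, ty); y2 <- min(ay2, ty + tiles$height[t])
        if (x2 <= x1 || y2 <= y1) next
        affected[t] <- TRUE
        img <- tiles$image[[t]]
        rows <- (y1 - ty + 1L):(y2 - ty)
        cols <- (x1 - tx + 1L):(x2 - tx)
        region <- img[rows, cols, drop = FALSE]
        # Both kinds model a shielded/charging detector region: the signal
        # that remains sinks toward the noise floor (signal-to-noise is
        # lost, not just rescaled), so the noise amplitude scales with
        # strength. DARK attenuates; BLUR additionally smears with a
        # Gaussian whose radius grows with strength. strength 0 is the
        # exact identity.
        noise <- function(sd) matrix(rnorm(length(region), 0, sd), nrow(region))
        region <- if (kind == "DARK") {
          region * (1 - strength) + noise(8 * strength)
        } else if (kind == "BLUR") {
          gaussian_blur(region * (1 - 0.5 * strength),
                        sigma = 2 + 14 * strength) + noise(8 * strength)
        } else {
          abort(paste0("unknown artifact kind '", kind, "'"))
        }
        img[rows, cols] <- round(pmin(pmax(region, 0), 255))
        tiles$image[[t]] <- img
      }
    }
  })
  synth$acq$tiles <- dplyr::mutate(tiles, artifact = affected)
  synth$artifacts <- artifacts
  synth
}

#' Full-tile artifact regions covering a fraction of tiles
#'
#' Convenience builder: picks `ceiling(frac * n_tiles)` tiles at random and
#' returns artifact regions covering each whole tile, alternating DARK and
#' BLUR kinds.
#'
#' @param synth An `msem_synthetic`.
#' @param frac Fraction of tiles to corrupt.
#' @param strength Artifact strength (default 0.9).
#' @param seed Seed for tile selection.
#' @return An artifact tibble for [inject_artifacts()], with a `tile_id`
#'   column recording the tile each region covers.
#' @export
artifact_regions_for_tiles <- function(synth, frac = 0.1, strength = 0.9,
                                       seed = 1L) {
  tiles <- synth$acq$tiles
  n <- ceiling(frac * nrow(tiles))
  with_preserved_rng(seed, {
    pick <- sample(nrow(tiles), n)
    tibble::tibble(
      tile_id = tiles$tile_id[pick],
      x = synth$truth$true_x[pick], y = synth$truth$true_y[pick],
      w = tiles$width[pick], h = tiles$height[pick],
      kind = rep(c("DARK", "BLUR"), length.out = n),
      strength = strength
    )
  })
}

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_rows <- function(x) x[c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r)), , drop = FALSE]
  pad_cols <- function(x) x[, c(rep(1L, r), seq_len(ncol(x)), rep(ncol(x), r)), drop = FALSE]
  conv1 <- function(x, along_rows) {
    if (along_rows) {
      xp <- pad_rows(x)
      out <- matrix(0, nrow(x), ncol(x))
      for (o in -r:r) {
        out <- out + k[o + r + 1L] * xp[(1L + r + o):(nrow(x) + r + o), , drop = FALSE]
      }
    } else {
      xp <- pad_cols(x)
      out <- matrix(0, nrow(x), ncol(x))
      for (o in -r:r) {
        out <- out + k[o + r + 1L] * xp[, (1L + r + o):(ncol(x) + r + o), drop = FALSE]
      }
    }
    out
  }
  conv1(conv1(m, TRUE), FALSE)
}

#' Random spring-system instance for solver benchmarking
#'
#' A connected grid of point-mass tiles with springs between lattice
#' neighbours, random alignment quality `R ~ U(0.3, 1)` and noisy optimal
#' offsets `p = true offset + N(0, p_noise)`. No images are attached; the
#' instance exercises the registration solvers only.
#'
#' @param n_tiles Number of tiles (grid cropped to this count).
#' @param seed Integer seed.
#' @param spacing Lattice pitch in pixels.
#' @param jitter_sigma Stage-position error sigma in pixels.
#' @param p_noise Noise sigma on the spring rest offsets.
#' @return A list with `tiles` (tibble without images), `pairs`, and `truth`.
#' @export
simulate_spring_instance <- function(n_tiles = 100L, seed = 1L,
                                     spacing = 300, jitter_sigma = 15,
                                     p_noise = 2) {
  with_preserved_rng(seed, {
    nx <- ceiling(sqrt(n_tiles))
    ny <- ceiling(n_tiles / nx)
    grid <- expand.grid(gx = seq_len(nx) - 1L, gy = seq_len(ny) - 1L)
    grid <- grid[seq_len(n_tiles), ]
    true_x <- grid$gx * spacing
    true_y <- grid$gy * spacing
    tiles <- tibble::tibble(
      tile_id = sprintf("t%04d", seq_len(n_tiles)),
      mfov_id = 1L, beam_index = seq_len(n_tiles) - 1L,
      x = true_x + rnorm(n_tiles, 0, jitter_sigma),
      y = true_y + rnorm(n_tiles, 0, jitter_sigma),
      width = as.integer(spacing + 20), height = as.integer(spacing + 20)
    )
    # springs between horizontal and vertical lattice neighbours
    edges <- list()
    for (t in seq_len(n_tiles)) {
      right <- which(grid$gx == grid$gx[t] + 1L & grid$gy == grid$gy[t])
      down <- which(grid$gx == grid$gx[t] & grid$gy == grid$gy[t] + 1L)
      for (u in c(right, down)) {
        edges[[length(edges) + 1L]] <- c(t, u)
      }
    }
    em <- do.call(rbind, edges)
    i <- pmin(em[, 1], em[, 2])
    j <- pmax(em[, 1], em[, 2])
    pairs <- tibble::tibble(
      tile_i = tiles$tile_id[i], tile_j = tiles$tile_id[j],
      type = ifelse(true_y[i] == true_y[j], "INTRA_1", "INTRA_2"),
      ov_x = NA_real_, ov_y = NA_real_,
      ov_w = 20, ov_h = 20,
      R = runif(length(i), 0.3, 1),
      p_x = (true_x[i] - true_x[j]) + rnorm(length(i), 0, p_noise),
      p_y = (true_y[i] - true_y[j]) + rnorm(length(i), 0, p_noise),
      corrected = "NONE"
    )
    pairs$r0_x <- (tiles$x[i] - tiles$x[j]) - pairs$p_x
    pairs$r0_y <- (tiles$y[i] - tiles$y[j]) - pairs$p_y
    list(
      tiles = tiles,
      pairs = pairs,
      truth = tibble::tibble(tile_id = tiles$tile_id,
                             true_x = true_x, true_y = true_y)
    )
  })
}
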