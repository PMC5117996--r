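# Global registration. Each tile is a unit point mass; each overlapping pair
# is a spring whose rest configuration is the pairwise-optimal relative
# position p and whose stiffness is k * R^n, so high-quality alignments pull
# harder. The damped dynamics
#     m x.. + c x. + F_k = 0,   F_k(i) = sum_j k_ij r_ij,
#     r_ij = (x_i - x_j) - p_ij
# are integrated to equilibrium with an adaptive Runge-Kutta scheme; one tile
# (the centre tile of the first mFOV) is anchored to remove the global
# translation degeneracy. The equilibrium of this system is exactly the
# minimiser of the weighted least-squares objective
#     sum_pairs k_ij * ||(x_i - x_j) - p_ij||^2
# which the sparse solvers below compute directly and serve as reference.

#' Mass-spring-damper parameters
#'
#' @param m Mass per tile (default 1).
#' @param k Maximum spring constant (default 1).
#' @param c Damping coefficient (default 0.25).
#' @param n Stiffness exponent: spring stiffness is `k * R^n` (default 5).
#' @param conv_tol Convergence threshold: the RMS change of the pairwise
#'   residual vectors between consecutive checkpoints must stay below this
#'   value, in pixels (default 1e-6).
#' @param t_max Integration-time cap in simulated time units (default 1e4).
#' @param checkpoint_dt Simulated-time interval between convergence
#'   checkpoints (default 1).
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @return A list of class `msd_params`.
#' @export
msd_params <- function(m = 1, k = 1, c = 0.25, n = 5,
                       conv_tol = 1e-6, t_max = 1e4, checkpoint_dt = 1,
                       rtol = 1e-8, atol = 1e-8) {
  stopifnot(m > 0, k > 0, c >= 0, n >= 0, conv_tol > 0,
            t_max > 0, checkpoint_dt > 0)
  structure(
    list(m = m, k = k, c = c, n = n, conv_tol = conv_tol, t_max = t_max,
         checkpoint_dt = checkpoint_dt, rtol = rtol, atol = atol),
    class = "msd_params"
  )
}

#' Spring stiffness from alignment quality
#'
#' `k * R^n`: the power law concentrates restoring force on pairs with high
#' correlation, so low-quality (often artifact-ridden) pairings barely pull.
#'
#' @param R Correlation coefficient(s) in `[0, 1]`.
#' @param params An [msd_params()] list.
#' @return Stiffness value(s).
#' @export
spring_stiffness <- function(R, params = msd_params()) {
  if (any(R < 0 | R > 1)) abort("R must lie in [0, 1]")
  params$k * R^params$n
}

#' Pairwise residual vectors and their RMS
#'
#' `r_ij = (x_i - x_j) - p_ij` for every pair in the table, and the root mean
#' square of the residual lengths over pairs.
#'
#' @param positions Tibble with columns `tile_id`, `x`, `y`.
#' @param pairs Pair tibble with `tile_i`, `tile_j`, `p_x`, `p_y`.
#' @return A list with `residuals` (tibble `tile_i`, `tile_j`, `r_x`, `r_y`,
#'   `r_len`) and `rms`.
#' @export
pair_residuals <- function(positions, pairs) {
  if (nrow(pairs) == 0L) {
    return(list(
      residuals = tibble::tibble(tile_i = character(), tile_j = character(),
                                 r_x = double(), r_y = double(), r_len = double()),
      rms = NaN
    ))
  }
  i <- match(pairs$tile_i, positions$tile_id)
  j <- match(pairs$tile_j, positions$tile_id)
  if (anyNA(i) || anyNA(j)) {
    missing <- c(pairs$tile_i[is.na(i)], pairs$tile_j[is.na(j)])
    abort(paste0("pair references unknown tile '", missing[1], "'"))
  }
  r_x <- positions$x[i] - positions$x[j] - pairs$p_x
  r_y <- positions$y[i] - positions$y[j] - pairs$p_y
  r_len <- sqrt(r_x^2 + r_y^2)
  list(
    residuals = tibble::tibble(tile_i = pairs$tile_i, tile_j = pairs$tile_j,
                               r_x = r_x, r_y = r_y, r_len = r_len),
    rms = sqrt(mean(r_len^2))
  )
}

# Sparse system assembly. Returns the weighted graph Laplacian K over all
# tiles, the spring "load" vector b (so that the net spring force is
# K %*% X - B per axis), per-pair stiffnesses, and index bookkeeping.
build_spring_system <- function(tiles, pairs, params) {
  n <- nrow(tiles)
  ids <- tiles$tile_id
  i <- tile_index(tiles, pairs$tile_i)
  j <- tile_index(tiles, pairs$tile_j)
  kij <- spring_stiffness(pairs$R, params)
  K <- Matrix::sparseMatrix(
    i = c(i, j, i, j), j = c(i, j, j, i),
    x = c(kij, kij, -kij, -kij),
    dims = c(n, n)
  )
  B <- cbind(
    x = as.vector(Matrix::sparseMatrix(i = i, j = rep(1L, length(i)),
                                       x = kij * pairs$p_x, dims = c(n, 1L))) -
        as.vector(Matrix::sparseMatrix(i = j, j = rep(1L, length(j)),
                                       x = kij * pairs$p_x, dims = c(n, 1L))),
    y = as.vector(Matrix::sparseMatrix(i = i, j = rep(1L, length(i)),
                                       x = kij * pairs$p_y, dims = c(n, 1L))) -
        as.vector(Matrix::sparseMatrix(i = j, j = rep(1L, length(j)),
                                       x = kij * pairs$p_y, dims = c(n, 1L)))
  )
  list(K = K, B = B, kij = kij, i = i, j = j, ids = ids)
}

#' Mass-spring-damper state derivative
#'
#' Evaluates the dynamics at one state: net spring force on tile i is
#' `F_k(i) = sum_j k_ij r_ij` with `r_ij = (x_i - x_j) - p_ij` (sign flipped
#' on the j side), and the acceleration is `-(c v + F_k) / m`. The anchor
#' tile's velocity and acceleration are forced to zero.
#'
#' @param positions Tibble (`tile_id`, `x`, `y`) of current tile positions.
#' @param velocities Tibble (`tile_id`, `vx`, `vy`); defaults to rest.
#' @param tiles An `msem_acquisition` or tiles tibble.
#' @param pairs Pair tibble with `R`, `p_x`, `p_y`.
#' @param params An [msd_params()] list.
#' @param anchor Anchor `tile_id` (default [anchor_tile()]).
#' @return A tibble `tile_id`, `vx`, `vy`, `ax`, `ay`, `fx`, `fy` (net
#'   spring force components).
#' @export
msd_derivative <- function(positions, velocities = NULL, tiles, pairs,
                           params = msd_params(), anchor = NULL) {
  tiles <- as_tile_table(tiles)
  sys <- build_spring_system(tiles, pairs, params)
  idx <- tile_index(tiles, positions$tile_id)
  pos <- matrix(0, nrow(tiles), 2)
  pos[idx, ] <- cbind(positions$x, positions$y)
  vel <- matrix(0, nrow(tiles), 2)
  if (!is.null(velocities)) {
    vidx <- tile_index(tiles, velocities$tile_id)
    vel[vidx, ] <- cbind(velocities$vx, velocities$vy)
  }
  Fk <- as.matrix(sys$K %*% pos - sys$B)
  acc <- -(params$c * vel + Fk) / params$m
  anchor <- anchor %||% anchor_tile(tiles)
  ai <- tile_index(tiles, anchor)
  vel[ai, ] <- 0
  acc[ai, ] <- 0
  tibble::tibble(
    tile_id = tiles$tile_id,
    vx = vel[, 1], vy = vel[, 2],
    ax = acc[, 1], ay = acc[, 2],
    fx = Fk[, 1], fy = Fk[, 2]
  )
}

#' Choose the anchor tile
#'
#' The centre tile of the first mFOV: the tile of the lowest `mfov_id` whose
#' stage position is closest to that mFOV's stage centroid.
#'
#' @param tiles An `msem_acquisition` or tiles tibble.
#' @return A `tile_id`.
#' @export
anchor_tile <- function(tiles) {
  tiles <- as_tile_table(tiles)
  m0 <- tiles[tiles$mfov_id == min(tiles$mfov_id), ]
  cx <- mean(m0$x + m0$width / 2)
  cy <- mean(m0$y + m0$height / 2)
  d2 <- (m0$x + m0$width / 2 - cx)^2 + (m0$y + m0$height / 2 - cy)^2
  m0$tile_id[which.min(d2)]
}

# Connected components of the overlap graph (labels 1..n_comp, indices into
# tiles). Min-label flooding with per-node aggregation of incident labels.
graph_components <- function(n, i, j) {
  comp <- seq_len(n)
  if (length(i)) {
    ends <- c(i, j)
    repeat {
      mn <- pmin(comp[i], comp[j])
      agg <- tapply(c(mn, mn), ends, min)
      nodes <- as.integer(names(agg))
      upd <- pmin(comp[nodes], as.vector(agg))
      if (all(upd == comp[nodes])) break
      comp[nodes] <- upd
    }
  }
  match(comp, unique(comp))
}

#' Register tiles by damped mass-spring relaxation
#'
#' Initialises every tile at its stage position with zero velocity, anchors
#' the centre tile of the first mFOV (its derivative is forced to zero for
#' all time), and integrates the damped spring dynamics with an adaptive
#' Dormand-Prince Runge-Kutta scheme (`deSolve::ode`, method `"ode45"`).
#' The residuals are evaluated at fixed checkpoints of simulated time;
#' integration stops once the RMS change of the residual vectors between
#' consecutive checkpoints stays below `conv_tol` twice in a row, or at
#' `t_max` with a warning.
#'
#' If the overlap graph is disconnected, each connected component is
#' registered independently with its own anchor (warning emitted).
#'
#' @param tiles An `msem_acquisition` or tiles tibble.
#' @param pairs Aligned (and usually corrected) pair tibble.
#' @param params An [msd_params()] list.
#' @param anchor Anchor `tile_id`; default [anchor_tile()].
#' @return An object of class `msem_registration`: positions tibble
#'   (`tile_id`, `x0`, `y0` initial, `x`, `y` final), `rms_trace`
#'   (`t`, `rms`, `energy`), `converged`, `anchor`, `method = "msd"`,
#'   `params`, and the pair table used.
#' @export
integrate_msd <- function(tiles, pairs, params = msd_params(),
                          anchor = NULL) {
  tiles <- as_tile_table(tiles)
  n <- nrow(tiles)
  if (n == 0L) abort("no tiles to register")
  sys <- build_spring_system(tiles, pairs, params)
  comp <- graph_components(n, sys$i, sys$j)
  n_comp <- max(comp)
  if (n_comp > 1L) {
    warn(sprintf(
      "overlap graph has %d connected components; registering each independently",
      n_comp
    ))
  }
  anchor <- anchor %||% anchor_tile(tiles)
  anchor_idx <- tile_index(tiles, anchor)
  # one anchor per component: the requested anchor for its component, the
  # component's centre-most tile otherwise
  anchors <- integer(n_comp)
  for (cc in seq_len(n_comp)) {
    members <- which(comp == cc)
    anchors[cc] <- if (comp[anchor_idx] == cc) anchor_idx else {
      sub <- tiles[members, ]
      members[match(anchor_tile(sub), sub$tile_id)]
    }
  }
  anchored <- rep(FALSE, n)
  anchored[anchors] <- TRUE
  free <- which(!anchored)
  X0 <- cbind(tiles$x, tiles$y)
  m <- params$m
  cdamp <- params$c
  nf <- length(free)
  # Dense free-block system: at the scales a single process integrates the
  # dense matmul is far cheaper per derivative call than sparse dispatch.
  Kd <- as.matrix(sys$K)
  Kff <- Kd[free, free, drop = FALSE]
  Fconst <- Kd[free, anchors, drop = FALSE] %*% X0[anchors, , drop = FALSE] -
    sys$B[free, , drop = FALSE]
  # state = (positions of free tiles (x then y), velocities of free tiles)
  deriv <- function(t, state, parms) {
    posf <- matrix(state[seq_len(2 * nf)], ncol = 2)
    vel <- matrix(state[2 * nf + seq_len(2 * nf)], ncol = 2)
    acc <- -(cdamp * vel + Kff %*% posf + Fconst) / m
    list(c(vel, acc))
  }
  positions_of <- function(state) {
    pos <- X0
    if (nf > 0L) pos[free, ] <- matrix(state[seq_len(2 * nf)], ncol = 2)
    pos
  }
  rms_of <- function(pos) {
    rx <- pos[sys$i, 1] - pos[sys$j, 1] - pairs$p_x
    ry <- pos[sys$i, 2] - pos[sys$j, 2] - pairs$p_y
    sqrt(mean(rx^2 + ry^2))
  }
  energy_of <- function(state, pos) {
    vel <- matrix(state[2 * nf + seq_len(2 * nf)], ncol = 2)
    rx <- pos[sys$i, 1] - pos[sys$j, 1] - pairs$p_x
    ry <- pos[sys$i, 2] - pos[sys$j, 2] - pairs$p_y
    0.5 * m * sum(vel^2) + 0.5 * sum(sys$kij * (rx^2 + ry^2))
  }
  resid_of <- function(pos) {
    cbind(pos[sys$i, 1] - pos[sys$j, 1] - pairs$p_x,
          pos[sys$i, 2] - pos[sys$j, 2] - pairs$p_y)
  }
  state <- c(as.vector(X0[free, , drop = FALSE]), rep(0, 2 * nf))
  rms0 <- rms_of(X0)
  tr_t <- 0; tr_rms <- rms0; tr_energy <- energy_of(state, X0)
  converged <- FALSE
  t_now <- 0
  last_resid <- resid_of(X0)
  below <- 0L
  chunk <- 50L
  while (t_now < params$t_max && nf > 0L) {
    t_end <- min(t_now + chunk * params$checkpoint_dt, params$t_max)
    times <- seq(t_now, t_end, by = params$checkpoint_dt)
    sol <- deSolve::ode(
      y = state, times = times, func = deriv, parms = NULL,
      method = "ode45", rtol = params$rtol, atol = params$atol
    )
    for (r in 2:nrow(sol)) {
      st <- sol[r, -1]
      pos <- positions_of(st)
      rms <- rms_of(pos)
      tr_t <- c(tr_t, sol[r, 1])
      tr_rms <- c(tr_rms, rms)
      tr_energy <- c(tr_energy, energy_of(st, pos))
      # convergence: RMS of the change of the residual vectors between
      # consecutive checkpoints (a direct bound on how much the relative
      # placements still move; the change of the scalar RMS vanishes near
      # any nonzero minimum and would stop integration prematurely)
      resid <- resid_of(pos)
      drms <- sqrt(mean((resid - last_resid)^2))
      last_resid <- resid
      below <- if (drms < params$conv_tol) below + 1L else 0L
      if (below >= 2L) { converged <- TRUE; break }
    }
    state <- sol[min(r, nrow(sol)), -1]
    t_now <- sol[min(r, nrow(sol)), 1]
    if (nrow(sol) < length(times) && !converged) {
      warn("integrator returned early; treating as non-convergence")
      break
    }
    if (converged) break
  }
  trace <- list(tibble::tibble(t = tr_t, rms = tr_rms, energy = tr_energy))
  if (nf == 0L) converged <- TRUE
  if (!converged) {
    warn(sprintf("registration did not converge by t_max = %g (|dRMS| rule)",
                 params$t_max))
  }
  final <- positions_of(state)
  new_registration(tiles, pairs, final, method = "msd", params = params,
                   anchor = tiles$tile_id[anchors],
                   rms_trace = dplyr::bind_rows(trace), converged = converged)
}

#' Register tiles by sparse least squares
#'
#' Minimises `sum_pairs w_ij * ||(x_i - x_j) - p_ij||^2` with the anchor tile
#' fixed, via the sparse linear normal equations (the objective is quadratic,
#' so this is exact). Weights are 1 (`weighted = FALSE`) or `R^n`
#' (`weighted = TRUE`, the spring-stiffness weight). This is the reference
#' solver the relaxation dynamics must agree with at equilibrium.
#'
#' @inheritParams integrate_msd
#' @param weighted Use `R^n` weights instead of unit weights.
#' @return An `msem_registration` (method `"wls"` or `"ls"`).
#' @export
solve_least_squares <- function(tiles, pairs, weighted = TRUE,
                                params = msd_params(), anchor = NULL) {
  tiles <- as_tile_table(tiles)
  n <- nrow(tiles)
  if (n == 0L) abort("no tiles to register")
  p_ls <- if (weighted) params else msd_params(
    m = params$m, k = params$k, c = params$c, n = 0,
    conv_tol = params$conv_tol, t_max = params$t_max,
    checkpoint_dt = params$checkpoint_dt
  )
  sys <- build_spring_system(tiles, pairs, p_ls)
  comp <- graph_components(n, sys$i, sys$j)
  n_comp <- max(comp)
  anchor <- anchor %||% anchor_tile(tiles)
  anchor_idx <- tile_index(tiles, anchor)
  anchors <- integer(n_comp)
  for (cc in seq_len(n_comp)) {
    members <- which(comp == cc)
    anchors[cc] <- if (comp[anchor_idx] == cc) anchor_idx else {
      sub <- tiles[members, ]
      members[match(anchor_tile(sub), sub$tile_id)]
    }
  }
  free <- setdiff(seq_len(n), anchors)
  X0 <- cbind(tiles$x, tiles$y)
  final <- X0
  if (length(free)) {
    Kff <- sys$K[free, free, drop = FALSE]
    rhs <- sys$B[free, , drop = FALSE] -
      sys$K[free, anchors, drop = FALSE] %*% X0[anchors, , drop = FALSE]
    # springs with zero stiffness can isolate a tile: pin it at its stage
    # position by a unit diagonal so the solve stays well-posed
    diag_fix <- which(Matrix::diag(Kff) == 0)
    if (length(diag_fix)) {
      Kff <- Kff + Matrix::sparseMatrix(
        i = diag_fix, j = diag_fix, x = 1, dims = dim(Kff)
      )
      rhs[diag_fix, ] <- X0[free[diag_fix], ]
    }
    sol <- tryCatch(
      as.matrix(Matrix::solve(Kff, rhs)),
      error = function(e) abort(paste0("singular registration system: ",
                                       conditionMessage(e)))
    )
    final[free, ] <- sol
  }
  new_registration(tiles, pairs, final,
                   method = if (weighted) "wls" else "ls",
                   params = params, anchor = tiles$tile_id[anchors],
                   rms_trace = NULL, converged = TRUE)
}

new_registration <- function(tiles, pairs, final, method, params, anchor,
                             rms_trace, converged) {
  positions <- tibble::tibble(
    tile_id = tiles$tile_id,
    x0 = tiles$x, y0 = tiles$y,
    x = final[, 1], y = final[, 2]
  )
  before <- pair_residuals(positions[, c("tile_id")] |>
                             dplyr::mutate(x = positions$x0, y = positions$y0),
                           pairs)
  after <- pair_residuals(positions, pairs)
  structure(
    list(
      positions = positions, pairs = pairs, method = method, params = params,
      anchor = anchor, rms_trace = rms_trace, converged = converged,
      rms_before = before$rms, rms_after = after$rms
    ),
    class = "msem_registration"
  )
}

#' @exportS3Method base::print
print.msem_registration <- function(x, ...) {
  cat(sprintf(
    "<msem_registration> %s: %d tiles, %d springs\n  residual RMS %.3f -> %.3f px (%.1f%% reduction)%s\n",
    x$method, nrow(x$positions), nrow(x$pairs),
    x$rms_before, x$rms_after,
    100 * (1 - x$rms_after / x$rms_before),
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  invisible(x)
}

#' @describeIn integrate_msd Tidy positions: one row per tile with initial and
#'   registered coordinates and the displacement applied.
#' @param x An `msem_registration`.
#' @param ... Unused.
#' @export
tidy.msem_registration <- function(x, ...) {
  dplyr::mutate(x$positions, dx = .data$x - .data$x0, dy = .data$y - .data$y0)
}

#' @describeIn integrate_msd One-row summary: solver, tile/spring counts,
#'   residual RMS before/after, percentage reduction, convergence flag.
#' @export
glance.msem_registration <- function(x, ...) {
  pos0 <- tibble::tibble(tile_id = x$positions$tile_id)
  pos0$x <- x$positions$x0
  pos0$y <- x$positions$y0
  res_b <- pair_residuals(pos0, x$pairs)
  res_a <- pair_residuals(x$positions, x$pairs)
  tibble::tibble(
    method = x$method,
    n_tiles = nrow(x$positions),
    n_pairs = nrow(x$pairs),
    rms_before = x$rms_before,
    rms_after = x$rms_after,
    pct_reduction = 100 * (1 - x$rms_after / x$rms_before),
    mean_r_before = mean(res_b$residuals$r_len),
    mean_r_after = mean(res_a$residuals$r_len),
    converged = x$converged,
    t_final = if (!is.null(x$rms_trace)) max(x$rms_trace$t) else NA_real_
  )
}

#' Registration summary report
#'
#' Residual statistics before and after registration: RMS and mean residual
#' length, percentage reduction, a log-scale histogram of residual lengths,
#' and the per-pair residual table for spatial mapping.
#'
#' @param before_positions,after_positions Position tibbles
#'   (`tile_id`, `x`, `y`) covering all tiles in `pairs`.
#' @param pairs Pair tibble.
#' @param breaks Number of log-scale histogram bins.
#' @return A list with `summary` (one-row tibble), `histogram` (tibble of
#'   log10-spaced bins with before/after counts) and `per_pair` (tibble with
#'   residual lengths before/after per pair).
#' @export
registration_report <- function(before_positions, after_positions, pairs,
                                breaks = 24L) {
  rb <- pair_residuals(before_positions, pairs)
  ra <- pair_residuals(after_positions, pairs)
  lens <- c(rb$residuals$r_len, ra$residuals$r_len)
  pos <- lens[lens > 0]
  if (length(pos)) {
    rng <- range(pos)
    if (rng[1] == rng[2]) rng <- rng * c(0.5, 2)
    edges <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = breaks + 1L)
    hist_tab <- tibble::tibble(
      bin_lo = edges[-length(edges)],
      bin_hi = edges[-1],
      n_before = as.vector(table(cut(rb$residuals$r_len, edges, include.lowest = TRUE))),
      n_after = as.vector(table(cut(ra$residuals$r_len, edges, include.lowest = TRUE)))
    )
  } else {
    hist_tab <- tibble::tibble(bin_lo = double(), bin_hi = double(),
                               n_before = integer(), n_after = integer())
  }
  list(
    summary = tibble::tibble(
      rms_before = rb$rms, rms_after = ra$rms,
      pct_rms_reduction = 100 * (1 - ra$rms / rb$rms),
      mean_before = mean(rb$residuals$r_len),
      mean_after = mean(ra$residuals$r_len),
      pct_mean_reduction = 100 * (1 - mean(ra$residuals$r_len) /
                                    mean(rb$residuals$r_len))
    ),
    histogram = hist_tab,
    per_pair = tibble::tibble(
      tile_i = pairs$tile_i, tile_j = pairs$tile_j,
      r_before = rb$residuals$r_len, r_after = ra$residuals$r_len
    )
  )
}

#' Write registered positions
#'
#' Delimited text `tile_id,x_px,y_px`; the companion `write_rms_trace()`
#' writes the `t,rms` convergence trace.
#'
#' @param reg An `msem_registration`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(reg, path) {
  readr::write_csv(
    tibble::tibble(tile_id = reg$positions$tile_id,
                   x_px = reg$positions$x, y_px = reg$positions$y),
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_positions
#' @export
write_rms_trace <- function(reg, path) {
  tr <- reg$rms_trace %||%
    tibble::tibble(t = double(), rms = double(), energy = double())
  readr::write_csv(tr, path, progress = FALSE)
  invisible(path)
}
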