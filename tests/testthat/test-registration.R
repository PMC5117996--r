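# Minimal graphs with hand-computable equilibria.
chain_tiles <- function(n, spacing = 100) {
  tibble::tibble(
    tile_id = sprintf("t%d", seq_len(n)),
    mfov_id = 1L, beam_index = seq_len(n) - 1L,
    x = (seq_len(n) - 1) * spacing, y = 0,
    width = 120L, height = 120L, image = vector("list", n)
  )
}

chain_pairs <- function(tiles, p_x, p_y = rep(0, length(p_x)), R = 1) {
  n <- nrow(tiles)
  tibble::tibble(
    tile_i = tiles$tile_id[-n], tile_j = tiles$tile_id[-1],
    type = "INTRA_1", ov_x = NA_real_, ov_y = NA_real_, ov_w = 20, ov_h = 120,
    R = R, p_x = p_x, p_y = p_y,
    r0_x = (tiles$x[-n] - tiles$x[-1]) - p_x,
    r0_y = (tiles$y[-n] - tiles$y[-1]) - p_y,
    corrected = "NONE"
  )
}

test_that("spring stiffness follows the R power law and rejects bad R", {
  p <- msd_params()
  expect_equal(spring_stiffness(1, p), 1)
  expect_equal(spring_stiffness(0.5, p), 0.03125)
  expect_equal(spring_stiffness(0, p), 0)
  expect_equal(spring_stiffness(0.8, msd_params(k = 2, n = 3)), 2 * 0.8^3)
  expect_error(spring_stiffness(1.2, p), "\\[0, 1\\]")
})

test_that("pair residuals match their definition and a naive-loop oracle", {
  tiles <- chain_tiles(2)
  pos <- tibble::tibble(tile_id = tiles$tile_id, x = c(0, -10), y = c(0, 0))
  pairs <- chain_pairs(tiles, p_x = 7)
  res <- pair_residuals(pos, pairs)
  expect_equal(res$residuals$r_x, 3)   # (0 - (-10)) - 7
  expect_equal(res$rms, 3)
  # zero-residual configuration
  pos2 <- tibble::tibble(tile_id = tiles$tile_id, x = c(0, -7), y = c(0, 0))
  expect_equal(pair_residuals(pos2, pairs)$rms, 0)
  # random instance vs naive loop
  set.seed(31)
  inst <- simulate_spring_instance(40, seed = 8)
  pos3 <- dplyr::mutate(inst$truth, x = true_x + rnorm(40), y = true_y + rnorm(40))
  got <- pair_residuals(pos3[, c("tile_id", "x", "y")], inst$pairs)
  acc <- 0
  for (r in seq_len(nrow(inst$pairs))) {
    i <- match(inst$pairs$tile_i[r], pos3$tile_id)
    j <- match(inst$pairs$tile_j[r], pos3$tile_id)
    rx <- pos3$x[i] - pos3$x[j] - inst$pairs$p_x[r]
    ry <- pos3$y[i] - pos3$y[j] - inst$pairs$p_y[r]
    acc <- acc + rx^2 + ry^2
  }
  expect_equal(got$rms, sqrt(acc / nrow(inst$pairs)))
  expect_error(pair_residuals(pos3[-1, c("tile_id", "x", "y")], inst$pairs),
               "unknown tile")
})

test_that("state derivative implements the damped spring dynamics", {
  tiles <- chain_tiles(2)
  pairs <- chain_pairs(tiles, p_x = 0)
  # free tile t1 placed so that ITS residual r = (x1 - x2) - p is (3, 4);
  # spring k = 1, anchor t2: acceleration of t1 is -(c v + k r)/m = (-3, -4)
  pos <- tibble::tibble(tile_id = tiles$tile_id, x = c(3, 0), y = c(4, 0))
  d <- msd_derivative(pos, NULL, tiles, pairs, anchor = "t2")
  expect_equal(c(d$ax[1], d$ay[1]), c(-3, -4))
  expect_equal(c(d$ax[2], d$ay[2]), c(0, 0))  # anchor pinned
  # action-reaction: spring force contributions cancel over the pair
  expect_equal(d$fx[1] + d$fx[2], 0)
  expect_equal(d$fy[1] + d$fy[2], 0)
  # zero stiffness: pure damping
  pairs0 <- dplyr::mutate(pairs, R = 0)
  vel <- tibble::tibble(tile_id = tiles$tile_id, vx = c(2, 0), vy = c(-1, 0))
  d0 <- msd_derivative(pos, vel, tiles, pairs0, anchor = "t2")
  expect_equal(c(d0$ax[1], d0$ay[1]), -0.25 * c(2, -1))
})

test_that("a single spring relaxes to its rest offset", {
  tiles <- chain_tiles(2)
  pairs <- chain_pairs(tiles, p_x = -10)  # rest offset x1 - x2 = -10
  reg <- integrate_msd(tiles, pairs, anchor = "t1")
  expect_true(reg$converged)
  expect_equal(reg$positions$x[2] - reg$positions$x[1], 10, tolerance = 1e-3)
  expect_lt(reg$rms_after, 1e-3)
})

test_that("an inconsistent triangle relaxes to the weighted least-squares minimiser", {
  tiles <- chain_tiles(3)
  pairs <- tibble::tibble(
    tile_i = c("t1", "t2", "t1"), tile_j = c("t2", "t3", "t3"),
    type = "INTRA_1", ov_x = NA_real_, ov_y = NA_real_, ov_w = 20, ov_h = 120,
    R = c(1, 0.8, 0.6),
    p_x = c(-100, -100, -215),  # p12 + p23 != p13: inconsistent by 15
    p_y = c(0, 5, 0),
    r0_x = 0, r0_y = 0, corrected = "NONE"
  )
  reg <- integrate_msd(tiles, pairs, anchor = "t1")
  # independent oracle: minimise the weighted objective
  # k1(x1-x2-p1)^2 + k2(x2-x3-p2)^2 + k3(x1-x3-p3)^2 numerically
  k <- spring_stiffness(pairs$R, msd_params())
  obj <- function(v) {
    x2 <- v[1]; x3 <- v[2]; y2 <- v[3]; y3 <- v[4]
    k[1] * ((0 - x2 - pairs$p_x[1])^2 + (0 - y2 - pairs$p_y[1])^2) +
      k[2] * ((x2 - x3 - pairs$p_x[2])^2 + (y2 - y3 - pairs$p_y[2])^2) +
      k[3] * ((0 - x3 - pairs$p_x[3])^2 + (0 - y3 - pairs$p_y[3])^2)
  }
  opt <- optim(c(100, 200, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(reg$positions$x[2], opt$par[1], tolerance = 1e-2)
  expect_equal(reg$positions$x[3], opt$par[2], tolerance = 1e-2)
  expect_equal(reg$positions$y[2], opt$par[3], tolerance = 1e-2)
  expect_equal(reg$positions$y[3], opt$par[4], tolerance = 1e-2)
  # and the sparse solver lands on the same minimiser
  wls <- solve_least_squares(tiles, pairs, weighted = TRUE, anchor = "t1")
  expect_equal(wls$positions$x[2:3], opt$par[1:2], tolerance = 1e-8)
})

test_that("consistent rest offsets are recovered exactly up to the anchor gauge", {
  inst <- simulate_spring_instance(30, seed = 3, p_noise = 0)
  reg <- integrate_msd(inst$tiles, inst$pairs)
  rms <- truth_rms(reg$positions, inst$truth)
  expect_lt(rms, 1e-2)
  expect_lt(reg$rms_after, 1e-2)
})

test_that("least-squares solver handles canonical cases", {
  tiles <- chain_tiles(3)
  # consistent chain: exact recovery, objective zero
  pairs <- chain_pairs(tiles, p_x = c(-90, -110))
  ls <- solve_least_squares(tiles, pairs, weighted = FALSE, anchor = "t1")
  expect_equal(ls$positions$x, c(0, 90, 200))
  expect_equal(ls$rms_after, 0, tolerance = 1e-10)
  # equal weights: weighted and unweighted agree
  pairs_eq <- chain_pairs(tiles, p_x = c(-95, -103), R = 0.7)
  w <- solve_least_squares(tiles, pairs_eq, weighted = TRUE, anchor = "t1")
  u <- solve_least_squares(tiles, pairs_eq, weighted = FALSE, anchor = "t1")
  expect_equal(w$positions$x, u$positions$x, tolerance = 1e-10)
  # two tiles, one pair: free tile lands exactly at anchor - p
  t2 <- chain_tiles(2)
  p2 <- chain_pairs(t2, p_x = -42)
  s2 <- solve_least_squares(t2, p2, weighted = TRUE, anchor = "t1")
  expect_equal(s2$positions$x[2], 42)
})

test_that("gauge shift of all stage positions shifts the solution exactly", {
  inst <- simulate_spring_instance(25, seed = 6)
  reg <- integrate_msd(inst$tiles, inst$pairs)
  shifted_tiles <- dplyr::mutate(inst$tiles, x = x + 50, y = y - 30)
  reg2 <- integrate_msd(shifted_tiles, inst$pairs)
  expect_equal(reg2$positions$x, reg$positions$x + 50, tolerance = 1e-4)
  expect_equal(reg2$positions$y, reg$positions$y - 30, tolerance = 1e-4)
})

test_that("with all springs at zero stiffness positions stay at the stage estimates", {
  inst <- simulate_spring_instance(16, seed = 9)
  pairs0 <- dplyr::mutate(inst$pairs, R = 0)
  reg <- integrate_msd(inst$tiles, pairs0)
  expect_equal(reg$positions$x, inst$tiles$x, tolerance = 1e-8)
  expect_equal(reg$positions$y, inst$tiles$y, tolerance = 1e-8)
  ls <- solve_least_squares(inst$tiles, pairs0, weighted = TRUE)
  expect_equal(ls$positions$x, inst$tiles$x)
})

test_that("residual RMS never increases through registration on random instances", {
  for (s in 1:5) {
    inst <- simulate_spring_instance(40, seed = 100 + s)
    reg <- integrate_msd(inst$tiles, inst$pairs)
    expect_lte(reg$rms_after, reg$rms_before)
  }
})

test_that("registration report totals agree with raw residual recomputation", {
  inst <- simulate_spring_instance(36, seed = 21)
  reg <- integrate_msd(inst$tiles, inst$pairs)
  before <- tibble::tibble(tile_id = inst$tiles$tile_id,
                           x = inst$tiles$x, y = inst$tiles$y)
  rep <- registration_report(before, reg$positions[, c("tile_id", "x", "y")],
                             inst$pairs)
  expect_equal(rep$summary$rms_before, reg$rms_before)
  expect_equal(rep$summary$rms_after, reg$rms_after)
  expect_equal(rep$summary$pct_rms_reduction,
               100 * (1 - reg$rms_after / reg$rms_before))
  # identity: zero reduction; perfect: 100 %
  rep_id <- registration_report(before, before, inst$pairs)
  expect_equal(rep_id$summary$pct_rms_reduction, 0)
  inst0 <- simulate_spring_instance(12, seed = 4, p_noise = 0, jitter_sigma = 10)
  reg0 <- integrate_msd(inst0$tiles, inst0$pairs)
  rep0 <- registration_report(
    tibble::tibble(tile_id = inst0$tiles$tile_id, x = inst0$tiles$x, y = inst0$tiles$y),
    reg0$positions[, c("tile_id", "x", "y")], inst0$pairs
  )
  expect_gt(rep0$summary$pct_rms_reduction, 99.9)
  # histogram covers all pairs in both states
  expect_equal(sum(rep$histogram$n_before), nrow(inst$pairs))
})

test_that("tidy and glance expose positions and fit summary", {
  inst <- simulate_spring_instance(20, seed = 12)
  reg <- integrate_msd(inst$tiles, inst$pairs)
  td <- tidy(reg)
  expect_named(td, c("tile_id", "x0", "y0", "x", "y", "dx", "dy"))
  expect_equal(td$dx, td$x - td$x0)
  gl <- glance(reg)
  expect_equal(gl$n_tiles, 20L)
  expect_equal(gl$method, "msd")
  expect_true(gl$rms_after <= gl$rms_before)
})
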