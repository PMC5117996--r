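# End-to-end orchestration: read -> overlap graph -> pairwise align ->
# correct -> register -> report -> composite -> pyramid, with every stage's
# outputs written under a run directory and the exact configuration echoed
# so a run is reproducible from its echo alone.

#' Pipeline run configuration
#'
#' Defaults follow the reference parameterisation: correction thresholds
#' R = 0.5 / 0.9 and 300 px, spring parameters m = 1, k = 1, c = 0.25,
#' n = 5, convergence at ΔRMS < 1e-6 px.
#'
#' @param tile_dir,metadata_file Input acquisition (ignored when an
#'   acquisition object is passed to [run_stitch()] directly).
#' @param out_dir Run output directory.
#' @param solver `"msd"` (spring relaxation), `"wls"` or `"ls"`.
#' @param margin Pairwise-alignment search margin in pixels.
#' @param min_overlap_area Overlap-graph area floor in px^2.
#' @param graph_expand Stage-uncertainty inflation of the frames during
#'   overlap-graph construction, in pixels; `NULL` (default) derives it from
#'   the acquisition's documented stage precision and pixel size.
#' @param correction A [correction_params()] list.
#' @param msd An [msd_params()] list.
#' @param render Composite the mosaic and pyramid after registration?
#' @param chunk_size Mosaic chunk side in pixels.
#' @param tile_size Pyramid tile side.
#' @param background Mosaic background gray level.
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `stitch_config`.
#' @export
stitch_config <- function(tile_dir = NULL, metadata_file = NULL,
                          out_dir = tempfile("msem_run_"),
                          solver = c("msd", "wls", "ls"),
                          margin = 150, min_overlap_area = 256,
                          graph_expand = NULL,
                          correction = correction_params(),
                          msd = msd_params(),
                          render = FALSE, chunk_size = 2048L,
                          tile_size = 256L, background = 0,
                          seed = 1L) {
  solver <- match.arg(solver)
  structure(
    list(tile_dir = tile_dir, metadata_file = metadata_file,
         out_dir = out_dir, solver = solver, margin = margin,
         min_overlap_area = min_overlap_area, graph_expand = graph_expand,
         correction = correction,
         msd = msd, render = render, chunk_size = chunk_size,
         tile_size = tile_size, background = background,
         seed = as.integer(seed)),
    class = "stitch_config"
  )
}

config_echo <- function(config) {
  ser <- config
  ser$correction <- unclass(ser$correction)
  ser$msd <- unclass(ser$msd)
  unclass(ser)
}

#' Run the full stitching pipeline
#'
#' Executes overlap-graph construction, pairwise phase-correlation
#' alignment, quality-based pair correction, global registration with the
#' chosen solver, residual reporting and (optionally) blended compositing
#' plus pyramid export. All stage outputs and a machine-readable run summary
#' are written under `config$out_dir`; identical inputs and configuration
#' give identical numeric outputs.
#'
#' @param config A [stitch_config()].
#' @param acquisition Optional `msem_acquisition` (or `msem_synthetic`)
#'   already in memory; otherwise the acquisition is read from
#'   `config$tile_dir` / `config$metadata_file`.
#' @return A list with `registration`, `pairs` (corrected), `report`,
#'   `summary` (one-row tibble) and `out_dir`.
#' @export
run_stitch <- function(config = stitch_config(), acquisition = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(acquisition)) {
    if (is.null(config$tile_dir) || is.null(config$metadata_file)) {
      abort("run_stitch: provide an acquisition or tile_dir + metadata_file")
    }
    acquisition <- read_acquisition(config$tile_dir, config$metadata_file)
  }
  if (inherits(acquisition, "msem_synthetic")) acquisition <- acquisition$acq
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config_echo(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  expand <- config$graph_expand %||% stage_error_px(acquisition$meta)
  message(sprintf("[graph] %d tiles (frame inflation %g px)",
                  nrow(acquisition$tiles), expand))
  pairs <- stage("overlap_graph",
                 build_overlap_graph(acquisition, config$min_overlap_area,
                                     expand = expand))
  message(sprintf("[graph] %d overlapping pairs", nrow(pairs)))
  pairs <- stage("align", align_pairs(pairs, acquisition, margin = config$margin))
  write_pair_table(pairs, file.path(out, "pairs_raw.csv"))
  corr_params <- config$correction
  if (is.null(corr_params$snap_tol)) corr_params$snap_tol <- 2 * expand
  corrected <- stage("correct",
                     correct_pairs(pairs, acquisition, corr_params))
  n_corr <- sum(corrected$corrected != "NONE")
  message(sprintf("[correct] %d / %d pairs corrected", n_corr, nrow(corrected)))
  write_pair_table(corrected, file.path(out, "pairs_corrected.csv"))
  write_correction_report(corrected, file.path(out, "correction_report.csv"))
  reg <- stage("register", switch(config$solver,
    msd = integrate_msd(acquisition, corrected, config$msd),
    wls = solve_least_squares(acquisition, corrected, weighted = TRUE,
                              params = config$msd),
    ls = solve_least_squares(acquisition, corrected, weighted = FALSE,
                             params = config$msd)
  ))
  if (!reg$converged) warn("[register] did not converge within t_max")
  write_positions(reg, file.path(out, "positions.csv"))
  if (identical(reg$method, "msd")) {
    write_rms_trace(reg, file.path(out, "rms_trace.csv"))
  }
  before <- tibble::tibble(tile_id = reg$positions$tile_id,
                           x = reg$positions$x0, y = reg$positions$y0)
  report <- stage("report",
                  registration_report(before, reg$positions, corrected))
  readr::write_csv(report$per_pair, file.path(out, "residuals_per_pair.csv"),
                   progress = FALSE)
  mosaic_dim <- NULL
  if (isTRUE(config$render)) {
    store <- file.path(out, "mosaic")
    mf <- stage("composite", composite_mosaic(
      acquisition, tidy(reg)[, c("tile_id", "x", "y")], store,
      chunk_size = config$chunk_size, background = config$background
    ))
    stage("pyramid", build_pyramid(store, file.path(out, "pyramid"),
                                   tile_size = config$tile_size))
    mosaic_dim <- c(mf$width, mf$height)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  summary <- dplyr::bind_cols(
    glance(reg),
    tibble::tibble(
      n_corrected = n_corr,
      # quality summary over the stage-predicted graph (inflation-only
      # edges carry no comparable signal)
      median_R_raw = stats::median(pairs$R[!pairs$weak], na.rm = TRUE),
      solver = config$solver,
      wall_time_s = elapsed
    )
  )
  jsonlite::write_json(as.list(summary), file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf(
    "[done] RMS %.2f -> %.2f px (%.1f%% reduction) in %.1f s",
    summary$rms_before, summary$rms_after, summary$pct_reduction, elapsed
  ))
  list(registration = reg, pairs = corrected, report = report,
       summary = summary, out_dir = out, mosaic_dim = mosaic_dim)
}

#' Compare the three global solvers on one input
#'
#' Runs unweighted least squares, weighted least squares and the spring
#' relaxation on identical aligned-and-corrected pairs and reports, per
#' solver, the residual RMS plus pairwise max/mean position differences
#' between solvers.
#'
#' @inheritParams run_stitch
#' @return A list with `per_solver` (tibble: method, rms_after, pct
#'   reduction) and `differences` (tibble: solver pair, max and mean
#'   coordinate difference in px).
#' @export
compare_solvers <- function(config = stitch_config(), acquisition = NULL) {
  if (is.null(acquisition)) {
    acquisition <- read_acquisition(config$tile_dir, config$metadata_file)
  }
  if (inherits(acquisition, "msem_synthetic")) acquisition <- acquisition$acq
  expand <- config$graph_expand %||% stage_error_px(acquisition$meta)
  pairs <- build_overlap_graph(acquisition, config$min_overlap_area,
                               expand = expand)
  pairs <- align_pairs(pairs, acquisition, margin = config$margin)
  corr_params <- config$correction
  if (is.null(corr_params$snap_tol)) corr_params$snap_tol <- 2 * expand
  corrected <- correct_pairs(pairs, acquisition, corr_params)
  regs <- list(
    ls = solve_least_squares(acquisition, corrected, weighted = FALSE,
                             params = config$msd),
    wls = solve_least_squares(acquisition, corrected, weighted = TRUE,
                              params = config$msd),
    msd = integrate_msd(acquisition, corrected, config$msd)
  )
  per_solver <- dplyr::bind_rows(lapply(regs, glance))
  combos <- utils::combn(names(regs), 2, simplify = FALSE)
  differences <- dplyr::bind_rows(lapply(combos, function(ab) {
    pa <- regs[[ab[1]]]$positions
    pb <- regs[[ab[2]]]$positions
    d <- cbind(pa$x - pb$x, pa$y - pb$y)
    tibble::tibble(
      solver_a = ab[1], solver_b = ab[2],
      max_coord_diff = max(abs(d)),
      mean_position_diff = mean(sqrt(rowSums(d^2)))
    )
  }))
  list(per_solver = per_solver, differences = differences, registrations = regs)
}
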