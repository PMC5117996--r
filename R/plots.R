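# Diagnostic figures: pair-quality maps, residual maps and histograms, and
# the convergence trace of the relaxation.

#' Spatial map of pairwise alignment quality
#'
#' One point per overlapping pair at the midpoint of its two tiles, coloured
#' by the correlation coefficient `R`. Low-R clusters flag artifact regions.
#'
#' @param pairs Aligned pair tibble.
#' @param tiles An `msem_acquisition` or tiles tibble.
#' @return A ggplot object.
#' @export
plot_pair_quality <- function(pairs, tiles) {
  tiles <- as_tile_table(tiles)
  i <- tile_index(tiles, pairs$tile_i)
  j <- tile_index(tiles, pairs$tile_j)
  df <- dplyr::mutate(pairs,
    mx = (tiles$x[i] + tiles$x[j]) / 2,
    my = (tiles$y[i] + tiles$y[j]) / 2
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$mx, .data$my, colour = .data$R)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "R",
                  title = "Pairwise alignment quality")
}

#' Spatial map of residual lengths
#'
#' @param positions Position tibble (`tile_id`, `x`, `y`).
#' @param pairs Pair tibble.
#' @param tiles An `msem_acquisition` or tiles tibble (for pair midpoints).
#' @return A ggplot object.
#' @export
plot_residual_map <- function(positions, pairs, tiles) {
  tiles <- as_tile_table(tiles)
  i <- tile_index(tiles, pairs$tile_i)
  j <- tile_index(tiles, pairs$tile_j)
  res <- pair_residuals(positions, pairs)$residuals
  df <- dplyr::mutate(res,
    mx = (tiles$x[i] + tiles$x[j]) / 2,
    my = (tiles$y[i] + tiles$y[j]) / 2
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$mx, .data$my, colour = .data$r_len)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(trans = "log1p") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "||r|| (px)",
                  title = "Residual lengths")
}

#' Residual-length histogram before vs after registration
#'
#' Log-scale histogram of pairwise residual lengths for two position sets.
#'
#' @inheritParams registration_report
#' @return A ggplot object.
#' @export
plot_residual_histogram <- function(before_positions, after_positions, pairs) {
  rb <- pair_residuals(before_positions, pairs)$residuals
  ra <- pair_residuals(after_positions, pairs)$residuals
  df <- dplyr::bind_rows(
    dplyr::mutate(rb, stage = "before"),
    dplyr::mutate(ra, stage = "after")
  )
  df$stage <- factor(df$stage, levels = c("before", "after"))
  ggplot2::ggplot(df, ggplot2::aes(pmax(.data$r_len, 1e-3), fill = .data$stage)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "||r|| (px)", y = "pairs", fill = NULL,
                  title = "Residual lengths before / after registration")
}

#' @describeIn integrate_msd Convergence diagnostics: residual RMS (and, for
#'   the relaxation solver, mechanical energy) against simulated time; for
#'   the direct solvers, the residual histogram instead.
#' @param object An `msem_registration`.
#' @export
autoplot.msem_registration <- function(object, ...) {
  if (is.null(object$rms_trace)) {
    before <- tibble::tibble(tile_id = object$positions$tile_id,
                             x = object$positions$x0, y = object$positions$y0)
    return(plot_residual_histogram(before, object$positions, object$pairs))
  }
  df <- tidyr::pivot_longer(object$rms_trace, c("rms", "energy"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "simulated time", y = NULL,
                  title = "Relaxation convergence")
}
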