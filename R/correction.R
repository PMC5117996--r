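# Quality-based correction of unsatisfactory pairings. A pairing is rejected
# when any of four criteria fires: low correlation (R < 0.5), long initial
# residual (>300 px), a translation vector exceeding the predicted overlap
# dimensions, or a translation under which the two frames no longer overlap.
# Rejected pairings get R = 0.5 and p replaced by the centroid of the
# high-quality (R > 0.9) translation vectors of the same overlap type.

#' Correction-stage parameters
#'
#' @param r_min Rejection threshold on the correlation coefficient
#'   (default 0.5).
#' @param r0_max Cap on the initial residual length in pixels (default 300).
#' @param r_high High-quality threshold: pairs with `R >` this value feed the
#'   per-type translation centroids (default 0.9).
#' @param snap_tol Rescue radius in pixels for rejected pairs whose overlap
#'   type has no high-quality member: if a *supported* type's centroid lies
#'   within `snap_tol` of the pair's stage-predicted offset, that centroid
#'   is used as the replacement vector (stage jitter near a quantization
#'   boundary can mislabel a pair's geometric relation; the nearby supported
#'   group is its true relation). `NULL` (default) disables the rescue in
#'   direct calls; the pipeline derives it as twice the stage precision.
#' @return A list of class `correction_params`.
#' @export
correction_params <- function(r_min = 0.5, r0_max = 300, r_high = 0.9,
                              snap_tol = NULL) {
  stopifnot(0 <= r_min, r_min < r_high, r_high <= 1, r0_max > 0,
            is.null(snap_tol) || snap_tol >= 0)
  structure(list(r_min = r_min, r0_max = r0_max, r_high = r_high,
                 snap_tol = snap_tol),
            class = "correction_params")
}

#' Flag unsatisfactory pairings
#'
#' Applies the rejection criteria to every pair and records the first reason
#' that fires: `LOW_R` (R below `r_min`), `WEAK_LOW_R` (a weak-evidence pair
#' — predicted overlap below the area floor before stage-uncertainty
#' inflation — that fails to clear the high-quality bar `r_high`),
#' `LONG_RESIDUAL` (initial residual length above `r0_max`),
#' `SHIFT_EXCEEDS_OVERLAP` (a component of `p` departs from the stage
#' prediction by more than the corresponding predicted overlap dimension),
#' or `NO_OVERLAP` (frames placed at relative offset `p` do not intersect).
#' Satisfactory pairs get reason `"NONE"`.
#'
#' @param pairs Aligned pair tibble (columns `R`, `p_x`, `p_y`, `r0_x`,
#'   `r0_y` populated).
#' @param tiles An `msem_acquisition` or tiles tibble (frame sizes).
#' @param params A [correction_params()] list.
#' @return `pairs` with logical column `unsatisfactory` and character column
#'   `reason` added.
#' @export
flag_unsatisfactory <- function(pairs, tiles, params = correction_params()) {
  tiles <- as_tile_table(tiles)
  if (nrow(pairs) == 0L) {
    return(dplyr::mutate(pairs, unsatisfactory = logical(0), reason = character(0)))
  }
  i <- tile_index(tiles, pairs$tile_i)
  j <- tile_index(tiles, pairs$tile_j)
  w_i <- tiles$width[i]; h_i <- tiles$height[i]
  w_j <- tiles$width[j]; h_j <- tiles$height[j]
  r0_len <- sqrt(pairs$r0_x^2 + pairs$r0_y^2)
  # criterion 3: each component of the alignment correction (p relative to
  # the stage prediction) compared against the predicted overlap dimensions
  stage_dx <- tiles$x[i] - tiles$x[j]
  stage_dy <- tiles$y[i] - tiles$y[j]
  exceeds <- abs(pairs$p_x - stage_dx) > pairs$ov_w |
    abs(pairs$p_y - stage_dy) > pairs$ov_h
  # criterion 4: frames at relative offset p must still intersect
  # (frame i at the origin, frame j at -p since p = x_i - x_j)
  ov_w_p <- pmin(w_i, -pairs$p_x + w_j) - pmax(0, -pairs$p_x)
  ov_h_p <- pmin(h_i, -pairs$p_y + h_j) - pmax(0, -pairs$p_y)
  no_overlap <- ov_w_p <= 0 | ov_h_p <= 0
  # weak-evidence pairs (predicted overlap below the area floor before the
  # stage-uncertainty inflation) must clear the high-quality bar
  weak <- if ("weak" %in% names(pairs)) pairs$weak else rep(FALSE, nrow(pairs))
  reason <- dplyr::case_when(
    pairs$R < params$r_min ~ "LOW_R",
    weak & pairs$R <= params$r_high ~ "WEAK_LOW_R",
    r0_len > params$r0_max ~ "LONG_RESIDUAL",
    exceeds ~ "SHIFT_EXCEEDS_OVERLAP",
    no_overlap ~ "NO_OVERLAP",
    .default = "NONE"
  )
  dplyr::mutate(pairs, unsatisfactory = reason != "NONE", reason = reason)
}

#' Per-overlap-type translation estimates
#'
#' For each overlap type, the component-wise mean (centroid) of the alignment
#' vectors `p` over the high-quality pairs of that type: pairs with
#' `R > r_high` that are themselves satisfactory (a pair rejected by any
#' criterion must not feed the centroids, however well it correlated — and
#' excluding rejected pairs is also what makes [correct_pairs()]
#' idempotent, since a replaced pair can never re-enter the pool). Types
#' with no high-quality member fall back to the mean stage-predicted offset
#' of the type, flagged in the `fallback` column.
#'
#' @inheritParams flag_unsatisfactory
#' @return A tibble with columns `type`, `p_x`, `p_y`, `n_high`, `fallback`.
#' @export
estimate_translation_table <- function(pairs, tiles,
                                       params = correction_params()) {
  tiles <- as_tile_table(tiles)
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(type = character(), p_x = double(), p_y = double(),
                          n_high = integer(), fallback = logical()))
  }
  i <- tile_index(tiles, pairs$tile_i)
  j <- tile_index(tiles, pairs$tile_j)
  ok <- !flag_unsatisfactory(pairs, tiles, params)$unsatisfactory
  tab <- pairs |>
    dplyr::mutate(
      stage_dx = tiles$x[i] - tiles$x[j],
      stage_dy = tiles$y[i] - tiles$y[j],
      high = .data$R > params$r_high & ok
    ) |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      n_high = sum(.data$high),
      p_x = if (any(.data$high)) mean(.data$p_x[.data$high]) else mean(.data$stage_dx),
      p_y = if (any(.data$high)) mean(.data$p_y[.data$high]) else mean(.data$stage_dy),
      .groups = "drop"
    ) |>
    dplyr::mutate(fallback = .data$n_high == 0L)
  if (any(tab$fallback)) {
    warn(paste0(
      "no high-quality pairs for overlap type(s) ",
      paste(tab$type[tab$fallback], collapse = ", "),
      "; falling back to stage-predicted offsets"
    ))
  }
  tab[, c("type", "p_x", "p_y", "n_high", "fallback")]
}

#' Correct unsatisfactory pairings
#'
#' Every pair flagged by [flag_unsatisfactory()] has its alignment parameters
#' replaced: `R := r_min` (0.5) and `p :=` the per-type translation estimate
#' from [estimate_translation_table()]. The initial residual `r0` is
#' recomputed from the stage positions and the replacement `p`; the original
#' residual is retained in `r0_orig_x/y` for diagnostics. Satisfactory pairs
#' pass through unchanged. The operation is idempotent.
#'
#' One class of flagged pairs is dropped instead of replaced: weak-evidence
#' pairs (edges that exist only because of stage-uncertainty frame
#' inflation) whose overlap type has no high-quality member to estimate a
#' replacement from. Their existence was hypothesised from uncertain stage
#' geometry, their correlation evidence failed, and the stage-offset
#' fallback for such types is selection-biased (only extreme stage errors
#' create these edges), so the edge carries no usable information.
#'
#' @inheritParams flag_unsatisfactory
#' @return The corrected pair tibble, with `corrected` holding the rejection
#'   reason for replaced pairs; zero-evidence weak pairs are removed.
#' @export
correct_pairs <- function(pairs, tiles, params = correction_params()) {
  tiles <- as_tile_table(tiles)
  if (nrow(pairs) == 0L) return(pairs)
  flagged <- flag_unsatisfactory(pairs, tiles, params)
  tab <- suppressWarnings(estimate_translation_table(pairs, tiles, params))
  weak <- if ("weak" %in% names(pairs)) pairs$weak else rep(FALSE, nrow(pairs))
  drop <- flagged$unsatisfactory & weak &
    tab$fallback[match(flagged$type, tab$type)]
  if (any(drop)) {
    pairs <- pairs[!drop, ]
    flagged <- flagged[!drop, ]
  }
  used_fallback <- unique(flagged$type[flagged$unsatisfactory &
                                         tab$fallback[match(flagged$type, tab$type)]])
  if (length(used_fallback)) {
    warn(paste0(
      "replacement vectors for overlap type(s) ",
      paste(used_fallback, collapse = ", "),
      " estimated from stage-predicted offsets (no high-quality pairs)"
    ))
  }
  i <- tile_index(tiles, pairs$tile_i)
  j <- tile_index(tiles, pairs$tile_j)
  stage_dx <- tiles$x[i] - tiles$x[j]
  stage_dy <- tiles$y[i] - tiles$y[j]
  ti <- match(flagged$type, tab$type)
  bad <- flagged$unsatisfactory
  out <- pairs
  if (!("r0_orig_x" %in% names(out))) {
    out$r0_orig_x <- out$r0_x
    out$r0_orig_y <- out$r0_y
  }
  out$R[bad] <- params$r_min
  out$p_x[bad] <- tab$p_x[ti[bad]]
  out$p_y[bad] <- tab$p_y[ti[bad]]
  # rescue for rejected pairs of sparsely populated unsupported types: a
  # nearby populated group's centroid (within the stage-uncertainty ball of
  # the stage offset) is the pair's true geometric relation, mislabelled by
  # jitter at a quantization boundary; any estimate pooled over several
  # members beats the pair's own selection-biased stage offset
  snap_tol <- params$snap_tol %||% 0
  if (snap_tol > 0 && any(tab$fallback)) {
    counts <- table(pairs$type)
    cand <- tab[tab$n_high > 0L |
                  as.vector(counts[tab$type]) >= 3L, , drop = FALSE]
    rescue <- which(bad & tab$fallback[ti])
    if (nrow(cand) > 0L) {
      for (r in rescue) {
        d2 <- (cand$p_x - stage_dx[r])^2 + (cand$p_y - stage_dy[r])^2
        best <- which.min(d2)
        if (sqrt(d2[best]) <= snap_tol) {
          out$p_x[r] <- cand$p_x[best]
          out$p_y[r] <- cand$p_y[best]
        }
      }
    }
  }
  out$r0_x[bad] <- stage_dx[bad] - out$p_x[bad]
  out$r0_y[bad] <- stage_dy[bad] - out$p_y[bad]
  out$corrected[bad] <- flagged$reason[bad]
  out
}

#' Write a correction report
#'
#' Delimited-text report of the corrected pairs: rejection reason, original
#' and replacement alignment vectors.
#'
#' @param pairs Corrected pair tibble from [correct_pairs()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correction_report <- function(pairs, path) {
  rep_tab <- pairs |>
    dplyr::filter(.data$corrected != "NONE") |>
    dplyr::select(dplyr::any_of(c(
      "tile_i", "tile_j", "type", "corrected", "R",
      "p_x", "p_y", "r0_x", "r0_y", "r0_orig_x", "r0_orig_y"
    )))
  readr::write_csv(rep_tab, path, progress = FALSE)
  invisible(path)
}
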