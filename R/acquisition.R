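# Acquisition container and metadata I/O.
#
# An acquisition is a list with class "msem_acquisition":
#   $tiles  tibble: tile_id (chr), mfov_id (int), beam_index (int),
#           x, y (dbl, stage position of the tile's top-left corner, global
#           pixel frame, x right / y down), width, height (int),
#           image (list of numeric matrices, 0..255 scale)
#   $meta   list: pixel_size_nm, stage_precision_um, tiles_per_mfov
# Stage positions are the microscope's first approximation; the pipeline's
# job is to refine them.

new_acquisition <- function(tiles, meta = list()) {
  meta <- modifyList(
    list(pixel_size_nm = 10, stage_precision_um = 2, tiles_per_mfov = 61L),
    meta
  )
  stopifnot(meta$pixel_size_nm > 0)
  if (nrow(tiles) > 0 && anyDuplicated(tiles$tile_id)) {
    abort("duplicate tile_id in acquisition")
  }
  if (nrow(tiles) > 0) {
    wh <- unique(tiles[, c("width", "height")])
    if (nrow(wh) != 1L) abort("all tiles in an acquisition must share frame size")
    if (wh$width <= 0 || wh$height <= 0) abort("frame size must be positive")
  }
  structure(list(tiles = tiles, meta = meta), class = "msem_acquisition")
}

#' @exportS3Method base::print
print.msem_acquisition <- function(x, ...) {
  cat(sprintf(
    "<msem_acquisition> %d tiles, %d mFOV(s), frame %s, pixel size %g nm\n",
    nrow(x$tiles), length(unique(x$tiles$mfov_id)),
    if (nrow(x$tiles)) paste0(x$tiles$width[1], "x", x$tiles$height[1]) else "?",
    x$meta$pixel_size_nm
  ))
  invisible(x)
}

# Accept either an acquisition or a bare tile tibble.
as_tile_table <- function(x) {
  if (inherits(x, "msem_acquisition")) x$tiles else x
}

#' Read an acquisition from a tile directory and metadata file
#'
#' The metadata file is UTF-8 delimited text with header
#' `tile_id,mfov_id,beam_index,x_px,y_px,file` and optional comment header
#' lines such as `# pixel_size_nm=10`. Coordinates are stage estimates of each
#' tile's top-left corner in global pixel coordinates. If the file instead
#' declares `x_um,y_um` columns, physical coordinates are converted to pixels
#' using the declared pixel size.
#'
#' @param tile_dir Directory containing the tile images referenced by the
#'   metadata `file` column.
#' @param metadata_file Path to the metadata table.
#' @return An `msem_acquisition` (tiles tibble + meta list).
#' @export
read_acquisition <- function(tile_dir, metadata_file) {
  if (!file.exists(metadata_file)) {
    abort(paste0("metadata file not found: '", metadata_file, "'"))
  }
  lines <- readLines(metadata_file, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("#\\s*([A-Za-z_]+)\\s*=\\s*([-0-9.eE+]+)", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- as.numeric(m[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) abort("metadata file has no header row")
  tab <- readr::read_csv(I(paste(body, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("tile_id", "mfov_id", "beam_index", "file")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("metadata missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  physical <- all(c("x_um", "y_um") %in% names(tab))
  if (!physical && !all(c("x_px", "y_px") %in% names(tab))) {
    abort("metadata must declare x_px,y_px (or x_um,y_um) coordinates")
  }
  px_nm <- meta$pixel_size_nm %||% 10
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      abort(paste0("non-numeric or non-finite '", col, "' in metadata row ", bad[1]))
    }
    v
  }
  if (nrow(tab) == 0L) {
    tiles <- tibble::tibble(
      tile_id = character(), mfov_id = integer(), beam_index = integer(),
      x = double(), y = double(), width = integer(), height = integer(),
      image = list()
    )
    return(new_acquisition(tiles, meta = rename_meta(meta)))
  }
  if (physical) {
    x <- num("x_um") * 1000 / px_nm
    y <- num("y_um") * 1000 / px_nm
  } else {
    x <- num("x_px")
    y <- num("y_px")
  }
  if (anyDuplicated(tab$tile_id)) {
    abort(paste0("duplicate tile_id '", tab$tile_id[anyDuplicated(tab$tile_id)], "'"))
  }
  paths <- file.path(tile_dir, tab$file)
  missing_img <- !file.exists(paths)
  if (any(missing_img)) {
    abort(paste0(
      "tile image file missing for tile '", tab$tile_id[which(missing_img)[1]],
      "': '", tab$file[which(missing_img)[1]], "'"
    ))
  }
  images <- lapply(paths, read_tile_image)
  tiles <- tibble::tibble(
    tile_id = tab$tile_id,
    mfov_id = as.integer(num("mfov_id")),
    beam_index = as.integer(num("beam_index")),
    x = x, y = y,
    width = vapply(images, ncol, 1L),
    height = vapply(images, nrow, 1L),
    image = images
  )
  new_acquisition(tiles, meta = rename_meta(meta))
}

# Expected worst-case stage error in pixels, from the documented stage
# precision and pixel size; 0 when either is unknown.
stage_error_px <- function(meta) {
  if (is.null(meta$stage_precision_um) || is.null(meta$pixel_size_nm)) return(0)
  meta$stage_precision_um * 1000 / meta$pixel_size_nm
}

rename_meta <- function(meta) {
  out <- list()
  if (!is.null(meta$pixel_size_nm)) out$pixel_size_nm <- meta$pixel_size_nm
  if (!is.null(meta$stage_precision_um)) out$stage_precision_um <- meta$stage_precision_um
  if (!is.null(meta$tiles_per_mfov)) out$tiles_per_mfov <- as.integer(meta$tiles_per_mfov)
  out
}

#' Write an acquisition to a tile directory and metadata file
#'
#' Writes each tile as an 8-bit grayscale image plus the delimited metadata
#' table understood by [read_acquisition()].
#'
#' @param acq An `msem_acquisition`.
#' @param dir Output directory (created if needed).
#' @param format Image format, `"png"` (default), `"tiff"` or `"bmp"`.
#' @return Path to the metadata file, invisibly.
#' @export
write_acquisition <- function(acq, dir, format = c("png", "tiff", "bmp")) {
  format <- match.arg(format)
  tiles <- as_tile_table(acq)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(tiles$tile_id, ".", format)
  purrr::walk2(tiles$image, file.path(dir, files), write_tile_image)
  meta_path <- file.path(dir, "metadata.csv")
  meta <- if (inherits(acq, "msem_acquisition")) acq$meta else list()
  hdr <- character()
  if (!is.null(meta$pixel_size_nm)) {
    hdr <- c(hdr, sprintf("# pixel_size_nm=%g", meta$pixel_size_nm))
  }
  if (!is.null(meta$stage_precision_um)) {
    hdr <- c(hdr, sprintf("# stage_precision_um=%g", meta$stage_precision_um))
  }
  if (!is.null(meta$tiles_per_mfov)) {
    hdr <- c(hdr, sprintf("# tiles_per_mfov=%d", meta$tiles_per_mfov))
  }
  body <- readr::format_csv(tibble::tibble(
    tile_id = tiles$tile_id, mfov_id = tiles$mfov_id,
    beam_index = tiles$beam_index, x_px = tiles$x, y_px = tiles$y,
    file = files
  ))
  writeLines(c(hdr, sub("\n$", "", body)), meta_path, useBytes = TRUE)
  invisible(meta_path)
}
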