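# Tile image I/O. In memory a tile image is a plain numeric matrix with
# intensities on the 0..255 scale, indexed [y, x] (row = y, origin top-left).

#' Read a grayscale tile image
#'
#' Reads an 8-bit grayscale PNG, TIFF or BMP file into a numeric matrix on the
#' 0..255 intensity scale, rows indexing y (top-down) and columns x.
#' Multi-channel images are reduced to grayscale by channel averaging.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` or `.bmp` file.
#' @return A numeric matrix of intensities in `[0, 255]`.
#' @export
read_tile_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("tile image not found: '", path, "'"))
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("reading TIFF tiles requires the 'tiff' package")
      }
      tiff::readTIFF(path) * 255
    },
    bmp = read_bmp_gray(path),
    abort(paste0("unsupported tile image format: '.", ext, "'"))
  )
  if (length(dim(img)) == 3L) {
    img <- apply(img, c(1L, 2L), mean)
  }
  img
}

#' Write a grayscale tile image
#'
#' Writes a numeric intensity matrix (0..255 scale) as an 8-bit grayscale
#' image. Values are clamped and rounded to the nearest integer gray level.
#'
#' @param img Numeric matrix, intensities on the 0..255 scale.
#' @param path Output path; format chosen from the extension (png/tif/bmp).
#' @return `path`, invisibly.
#' @export
write_tile_image <- function(img, path) {
  stopifnot(is.matrix(img))
  q <- round(pmin(pmax(img, 0), 255))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(q / 255, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("writing TIFF tiles requires the 'tiff' package")
      }
      tiff::writeTIFF(q / 255, path, bits.per.sample = 8L)
    },
    bmp = write_bmp_gray(q, path),
    abort(paste0("unsupported tile image format: '.", ext, "'"))
  )
  invisible(path)
}

# Minimal 8-bit grayscale BMP support (BITMAPINFOHEADER, uncompressed,
# 256-entry gray palette). No installed package reads BMP; the source
# instruments store tiles as bitmap files, so the format is supported here.
read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "BM") abort(paste0("not a BMP file: '", path, "'"))
  data_off <- u32(10L)
  header_size <- u32(14L)
  if (header_size < 40L) abort("unsupported BMP header")
  width <- u32(18L)
  height <- u32(22L)
  bpp <- u16(28L)
  compression <- u32(30L)
  if (bpp != 8L || compression != 0L) {
    abort("only uncompressed 8-bit grayscale BMP is supported")
  }
  row_bytes <- 4L * ceiling(width / 4)
  px <- matrix(0, nrow = height, ncol = width)
  for (r in seq_len(height)) {
    # BMP stores rows bottom-up
    start <- data_off + (r - 1L) * row_bytes
    px[height - r + 1L, ] <- as.integer(raw[start + seq_len(width)])
  }
  px
}

write_bmp_gray <- function(img, path) {
  h <- nrow(img)
  w <- ncol(img)
  row_bytes <- 4L * ceiling(w / 4)
  data_size <- row_bytes * h
  palette_size <- 256L * 4L
  data_off <- 14L + 40L + palette_size
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(data_off + data_size)
  u16(0); u16(0)
  u32(data_off)
  u32(40L)            # BITMAPINFOHEADER
  u32(w); u32(h)
  u16(1L); u16(8L)    # planes, bits per pixel
  u32(0L)             # BI_RGB
  u32(data_size)
  u32(2835L); u32(2835L)  # 72 dpi
  u32(256L); u32(0L)
  pal <- rep(0:255, each = 4)  # gray BGRA palette, alpha byte zeroed
  pal[seq(4, length(pal), by = 4)] <- 0L
  writeBin(as.raw(pal), con)
  q <- round(pmin(pmax(img, 0), 255))
  pad <- row_bytes - w
  for (r in seq.int(h, 1L)) {
    writeBin(as.raw(q[r, ]), con)
    if (pad > 0L) writeBin(as.raw(rep(0L, pad)), con)
  }
  invisible(path)
}
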