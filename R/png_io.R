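# Minimal grayscale PNG writer (8/16-bit, no interlace, filter type 0).
# Reading is delegated to png::readPNG, which decodes both depths losslessly;
# writing is done here because no 16-bit-capable PNG writer is available as an
# R package, and the slice store requires a bit-exact 16-bit round trip.

.crc_table <- local({
  tab <- integer(256)
  poly <- -306674912L # 0xEDB88320 as a signed 32-bit pattern
  for (n in 0:255) {
    c <- n
    for (i in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints) {
    crc <- bitwXor(bitwShiftR(crc, 8L), .crc_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

.png_chunk <- function(type, data) {
  type_raw <- charToRaw(type)
  c(writeBin(length(data), raw(), size = 4L, endian = "big"),
    type_raw, data,
    writeBin(.crc32(c(type_raw, data)), raw(), size = 4L, endian = "big"))
}

.write_png_gray <- function(pixels, path, bit_depth) {
  h <- nrow(pixels); w <- ncol(pixels)
  v <- as.vector(t(pixels)) # scanline (row-major) order
  if (bit_depth == 16L) {
    bytes <- as.raw(as.vector(rbind(v %/% 256L, v %% 256L)))
    row_bytes <- 2L * w
  } else {
    bytes <- as.raw(v)
    row_bytes <- w
  }
  scan_mat <- matrix(bytes, nrow = row_bytes)
  filtered <- rbind(matrix(as.raw(0L), nrow = 1L, ncol = h), scan_mat)
  ihdr <- c(writeBin(w, raw(), size = 4L, endian = "big"),
            writeBin(h, raw(), size = 4L, endian = "big"),
            as.raw(c(bit_depth, 0L, 0L, 0L, 0L))) # grayscale, deflate, no interlace
  idat <- memCompress(as.vector(filtered), type = "gzip") # zlib stream
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(.png_chunk("IHDR", ihdr), con)
  writeBin(.png_chunk("IDAT", idat), con)
  writeBin(.png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' Write a windowed CT slice as a grayscale PNG
#'
#' Stores an integer intensity matrix (as produced by [apply_window()]) as an
#' 8- or 16-bit grayscale PNG. The round trip through [read_slice_png()] is
#' bit-exact.
#'
#' @param pixels Integer-valued matrix with values in `[0, 255]` (8-bit) or
#'   `[0, 65535]` (16-bit).
#' @param path Output file path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @seealso [read_slice_png()], [write_mask_png()]
#' @export
write_slice_png <- function(pixels, path, bit_depth = 16L) {
  if (!bit_depth %in% c(8L, 16L)) stop("unsupported bit depth: ", bit_depth, call. = FALSE)
  if (!is.matrix(pixels) || !is.numeric(pixels)) stop("`pixels` must be a numeric matrix", call. = FALSE)
  maxv <- if (bit_depth == 16L) 65535 else 255
  if (any(pixels < 0 | pixels > maxv) || any(pixels != floor(pixels)))
    stop("pixel values must be integers in [0, ", maxv, "]", call. = FALSE)
  .write_png_gray(pixels, path, as.integer(bit_depth))
}

#' Read a grayscale PNG slice
#'
#' @param path PNG file path.
#' @return A list with `pixels` (integer matrix) and `bit_depth` (8 or 16).
#' @export
read_slice_png <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (!info$bit.depth %in% c(8L, 16L))
    stop("unsupported PNG bit depth: ", info$bit.depth, call. = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L] # tolerate gray-alpha/RGB dialects
  scale <- if (info$bit.depth == 16L) 65535 else 255
  pixels <- round(img * scale)
  attributes(pixels) <- list(dim = dim(img)) # drop readPNG metadata
  list(pixels = pixels, bit_depth = as.integer(info$bit.depth))
}

#' Write a binary annotation mask as an 8-bit PNG
#'
#' Masks are stored in the `{0, 255}` dialect: foreground pixels are 255.
#'
#' @param mask Logical matrix (or 0/1 numeric matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("numeric mask must be 0/1", call. = FALSE)
    mask <- mask > 0
  }
  if (!is.logical(mask) || !is.matrix(mask)) stop("`mask` must be a logical matrix", call. = FALSE)
  .write_png_gray(ifelse(mask, 255L, 0L), path, 8L)
}

#' Read a binary annotation mask from PNG
#'
#' Accepts only the `{0, 255}` 8-bit dialect written by [write_mask_png()];
#' anything else raises a mask-dialect error.
#'
#' @param path PNG file path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- read_slice_png(path)
  vals <- unique(as.vector(img$pixels))
  scale_255 <- if (img$bit_depth == 16L) 257 else 1 # 16-bit files must use 0/65535
  if (!all(vals %in% c(0, 255 * scale_255)))
    stop("mask dialect error: pixel values outside {0, 255} in ", path, call. = FALSE)
  img$pixels > 0
}
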