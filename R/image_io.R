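# Grayscale image I/O and the package-wide pixel conventions.
#
# A gray image is an integer matrix with values in [0, 255] (0 = black,
# 255 = white). A binary image is an integer matrix over {0, 1} with
# 0 = black and 1 = white, so that stacking shares is the elementwise AND.
# Writers map bits to display intensities (0 -> 0, 1 -> 255) at the file
# boundary only; nothing inside the package works in display units.

assert_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(img) < 2L || ncol(img) < 2L) {
    stop(sprintf("`%s` must be at least 2x2", arg), call. = FALSE)
  }
  if (anyNA(img) || any(img < 0 | img > 255) || any(img != round(img))) {
    stop(sprintf("`%s` must hold integers in [0, 255]", arg), call. = FALSE)
  }
  invisible(img)
}

assert_binary_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(img) < 2L || ncol(img) < 2L) {
    stop(sprintf("`%s` must be at least 2x2", arg), call. = FALSE)
  }
  if (anyNA(img) || !all(img %in% c(0, 1))) {
    stop(sprintf("`%s` must hold bits in {0, 1} (0 = black, 1 = white)", arg),
         call. = FALSE)
  }
  invisible(img)
}

# ITU-R 601 luma weights used to collapse colour inputs to gray.
.vc_luma <- c(0.299, 0.587, 0.114)

vc_image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    return("png")
  }
  if (ext %in% c("pgm", "pnm")) {
    return("pgm")
  }
  stop(sprintf("unsupported image format '%s' (use .png or .pgm)", ext),
       call. = FALSE)
}

#' Read an 8-bit grayscale image
#'
#' Reads a PNG or PGM (binary "P5") file into an integer matrix with values
#' in \[0, 255\] where 0 is black and 255 is white. Colour PNGs are
#' accepted and collapsed to luminance with ITU-R 601 weights
#' (0.299, 0.587, 0.114), with a warning, since the whole pipeline is
#' grayscale-only. Bit depths other than 8 are rejected.
#'
#' @param path Path to a `.png` or `.pgm` file.
#' @return An integer matrix (rows x columns) of intensities in \[0, 255\].
#' @seealso [write_gray()], [binarize()]
#' @export
read_gray <- function(path) {
  fmt <- vc_image_format(path)
  if (!file.exists(path)) {
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  }
  if (fmt == "pgm") {
    return(read_pgm(path))
  }
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 25L) {
    stop(sprintf("'%s' is not a valid PNG file", path), call. = FALSE)
  }
  depth <- as.integer(hdr[25L])
  if (depth != 8L) {
    stop(sprintf("'%s' has bit depth %d; only 8-bit images are supported",
                 path, depth), call. = FALSE)
  }
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    nch <- dim(x)[3L]
    if (nch >= 3L) {
      warning(sprintf("'%s' has %d channels; converting to luminance", path, nch),
              call. = FALSE)
      x <- .vc_luma[1L] * x[, , 1L] + .vc_luma[2L] * x[, , 2L] +
        .vc_luma[3L] * x[, , 3L]
    } else {
      x <- x[, , 1L]
    }
  }
  out <- round(x * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit grayscale image
#'
#' @param img Integer matrix with values in \[0, 255\].
#' @param path Output path; the extension (`.png` or `.pgm`) selects the
#'   format. PGM files use the raw "P5" dialect with maxval 255.
#' @return Invisibly, `path`.
#' @export
write_gray <- function(img, path) {
  assert_gray_image(img)
  fmt <- vc_image_format(path)
  if (fmt == "pgm") {
    write_pgm(img, path)
  } else {
    png::writePNG(img / 255, path)
  }
  invisible(path)
}

#' Write a binary image
#'
#' Maps the in-memory bit convention (0 = black, 1 = white) to display
#' intensities: bit 0 is written as 0 and bit 1 as 255, so reading the file
#' back with [read_gray()] and thresholding with [binarize()] is the
#' identity.
#'
#' @param img Integer matrix over \{0, 1\}.
#' @param path Output path (`.png` or `.pgm`).
#' @return Invisibly, `path`.
#' @export
write_binary <- function(img, path) {
  assert_binary_image(img)
  out <- img * 255L
  storage.mode(out) <- "integer"
  write_gray(out, path)
}

#' Threshold a gray image to binary
#'
#' Pixels strictly below the threshold become black (0); pixels at or above
#' it become white (1). Raising the threshold can only turn white pixels
#' black, never the reverse.
#'
#' @param img Integer matrix with values in \[0, 255\].
#' @param threshold Intensity cut in \[0, 255\]; default 128.
#' @return A binary matrix over \{0, 1\}.
#' @export
binarize <- function(img, threshold = 128) {
  assert_gray_image(img)
  stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 255)
  out <- (img >= threshold) * 1L
  storage.mode(out) <- "integer"
  out
}

# -- PGM (P5, maxval <= 255) ------------------------------------------------
# The raw PGM dialect is a three-token ASCII header followed by one byte per
# pixel; no reader for it ships with the installed imaging packages, so the
# few lines of parsing live here.

read_pgm <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 10L || rawToChar(raw[1:2]) != "P5") {
    stop(sprintf("'%s' is not a raw (P5) PGM file", path), call. = FALSE)
  }
  pos <- 3L
  is_space <- function(b) b %in% as.raw(c(9L, 10L, 13L, 32L))
  next_int <- function() {
    repeat {
      while (pos <= length(raw) && is_space(raw[pos])) pos <<- pos + 1L
      if (pos <= length(raw) && raw[pos] == as.raw(35L)) { # '#' comment
        while (pos <= length(raw) && raw[pos] != as.raw(10L)) pos <<- pos + 1L
      } else {
        break
      }
    }
    start <- pos
    while (pos <= length(raw) && !is_space(raw[pos])) pos <<- pos + 1L
    as.integer(rawToChar(raw[start:(pos - 1L)]))
  }
  width <- next_int()
  height <- next_int()
  maxval <- next_int()
  pos <- pos + 1L # single whitespace byte after maxval
  if (is.na(maxval) || maxval > 255L) {
    stop(sprintf("'%s': maxval %s exceeds 8 bits", path, maxval), call. = FALSE)
  }
  need <- width * height
  if (length(raw) - pos + 1L < need) {
    stop(sprintf("'%s': truncated pixel data", path), call. = FALSE)
  }
  px <- as.integer(raw[pos:(pos + need - 1L)])
  matrix(px, nrow = height, ncol = width, byrow = TRUE)
}

write_pgm <- function(img, path) {
  header <- sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(as.raw(as.vector(t(img))), con)
  invisible(path)
}
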