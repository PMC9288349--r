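# Halftoning: standard Floyd-Steinberg error diffusion as the baseline, and
# block-wise halftoning restricted to a candidate set of per-block black
# levels. The restricted variant is what makes expansion-free encryption
# possible: if every secret block carries at least as many black pixels as
# any cover block can contribute, a stacking-compatible rearrangement always
# exists (see check_feasible()).

#' Halftone configuration
#'
#' Bundles the block shape and the candidate level set for block-wise
#' halftoning. A level is the number of black pixels a block may carry; with
#' 2x2 blocks the possible levels are 0 through 4, and restricting the set
#' (e.g. to \{3, 4\}) trades tonal resolution for stacking feasibility.
#'
#' @param block Integer vector `c(height, width)` of the block shape;
#'   default `c(2, 2)` (4 subpixels per block).
#' @param levels Strictly increasing integer vector of allowed black counts
#'   per block, each in \[0, block area\].
#' @return A list of class `halftone_config` with elements `block`, `levels`
#'   and `s_b` (block pixel count).
#' @export
halftone_config <- function(block = c(2, 2), levels = c(3, 4)) {
  block <- as.integer(block)
  levels <- as.integer(levels)
  stopifnot(length(block) == 2L, all(block >= 1L))
  s_b <- block[1L] * block[2L]
  if (s_b < 2L) {
    stop("block must contain at least 2 pixels", call. = FALSE)
  }
  if (length(levels) == 0L) {
    stop("`levels` must be nonempty", call. = FALSE)
  }
  if (any(diff(levels) <= 0L)) {
    stop("`levels` must be strictly increasing", call. = FALSE)
  }
  if (any(levels < 0L) || any(levels > s_b)) {
    stop(sprintf("levels must lie in [0, %d]", s_b), call. = FALSE)
  }
  structure(list(block = block, levels = levels, s_b = s_b),
            class = "halftone_config")
}

#' Floyd-Steinberg error diffusion
#'
#' Classic raster-order error diffusion: each pixel is thresholded at 128
#' and the quantization error is pushed to the unprocessed neighbours with
#' weights 7/16 (right), 3/16 (below left), 5/16 (below) and 1/16 (below
#' right). Every gray level of the input survives as local black/white
#' texture, unlike the restricted block halftoner.
#'
#' @param img Integer matrix with values in \[0, 255\].
#' @param threshold Quantization cut; default 128.
#' @return A binary matrix over \{0, 1\} of the same dimensions.
#' @export
error_diffusion <- function(img, threshold = 128) {
  assert_gray_image(img)
  nr <- nrow(img)
  nc <- ncol(img)
  x <- img + 0 # numeric working copy accumulating diffused error
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      old <- x[r, cc]
      bit <- if (old < threshold) 0L else 1L
      out[r, cc] <- bit
      e <- old - 255 * bit
      if (cc < nc) x[r, cc + 1L] <- x[r, cc + 1L] + e * 7 / 16
      if (r < nr) {
        if (cc > 1L) x[r + 1L, cc - 1L] <- x[r + 1L, cc - 1L] + e * 3 / 16
        x[r + 1L, cc] <- x[r + 1L, cc] + e * 5 / 16
        if (cc < nc) x[r + 1L, cc + 1L] <- x[r + 1L, cc + 1L] + e * 1 / 16
      }
    }
  }
  out
}

#' Quantize a block mean onto a candidate level set
#'
#' The ideal darkness of a block with mean intensity `block_mean` is
#' `s_b * (1 - block_mean / 255)` black pixels. The returned level is the
#' member of `levels` nearest to that ideal, with ties broken toward the
#' darker (larger) level; the darkest input therefore clamps to the darkest
#' allowed level and vice versa.
#'
#' @param block_mean Numeric vector of block mean intensities in \[0, 255\].
#' @param levels Strictly increasing integer vector of allowed black counts.
#' @param s_b Block pixel count.
#' @return Integer vector of levels, one per input mean; always members of
#'   `levels`.
#' @export
block_black_count <- function(block_mean, levels, s_b) {
  if (length(levels) == 0L) {
    stop("`levels` must be nonempty", call. = FALSE)
  }
  stopifnot(all(block_mean >= 0), all(block_mean <= 255),
            all(diff(levels) > 0))
  ideal <- s_b * (1 - block_mean / 255)
  d <- abs(outer(as.numeric(ideal), as.numeric(levels), "-"))
  # ties.method = "last" prefers the larger (darker) level on exact ties
  pick <- max.col(-d, ties.method = "last")
  as.integer(levels[pick])
}

# Pad bottom/right with white so dimensions become block multiples.
vc_pad_to_blocks <- function(img, block, fill = 255L) {
  bh <- block[1L]
  bw <- block[2L]
  nr <- nrow(img)
  nc <- ncol(img)
  pr <- (bh - nr %% bh) %% bh
  pc <- (bw - nc %% bw) %% bw
  if (pr == 0L && pc == 0L) {
    return(img)
  }
  out <- matrix(as.integer(fill), nr + pr, nc + pc)
  out[seq_len(nr), seq_len(nc)] <- img
  out
}

# Per-block sums of a (block-multiple) matrix, as a block-grid matrix.
vc_block_sums <- function(x, bh, bw) {
  gi <- ceiling(seq_len(nrow(x)) / bh)
  gj <- ceiling(seq_len(ncol(x)) / bw)
  s1 <- rowsum(x, group = gi, reorder = TRUE)
  out <- t(rowsum(t(s1), group = gj, reorder = TRUE))
  dimnames(out) <- NULL
  out
}

#' Per-block black-pixel counts of a binary image
#'
#' @param img Binary matrix over \{0, 1\} with block-multiple dimensions.
#' @param block Block shape `c(height, width)`.
#' @return Integer matrix of black counts, one entry per block.
#' @export
block_counts <- function(img, block = c(2, 2)) {
  assert_binary_image(img)
  bh <- block[1L]
  bw <- block[2L]
  if (nrow(img) %% bh != 0L || ncol(img) %% bw != 0L) {
    stop("image dimensions must be block multiples", call. = FALSE)
  }
  cnt <- bh * bw - vc_block_sums(img, bh, bw)
  storage.mode(cnt) <- "integer"
  cnt
}

# Deterministic part of the limited halftoner: block levels from gray input.
vc_block_levels <- function(img, config) {
  padded <- vc_pad_to_blocks(img, config$block)
  means <- vc_block_sums(padded, config$block[1L], config$block[2L]) / config$s_b
  lv <- block_black_count(as.vector(means), config$levels, config$s_b)
  matrix(lv, nrow(means), ncol(means))
}

#' Block-wise halftoning onto a restricted level set
#'
#' Divides the image into non-overlapping blocks, quantizes each block's
#' mean darkness onto the candidate level set with [block_black_count()],
#' and places that many black pixels uniformly at random within the block.
#' Every output block's black count is guaranteed to be a member of
#' `config$levels`. Images whose dimensions are not block multiples are
#' padded bottom/right with white; the original dimensions are recorded in
#' the `orig_dim` attribute.
#'
#' @param img Integer matrix with values in \[0, 255\].
#' @param config A [halftone_config()].
#' @param seed Optional integer seed for the intra-block pixel placement.
#' @return A binary matrix over \{0, 1\} with block-multiple dimensions and
#'   attribute `orig_dim`.
#' @export
limited_halftone <- function(img, config = halftone_config(), seed = NULL) {
  assert_gray_image(img)
  stopifnot(inherits(config, "halftone_config"))
  if (!is.null(seed)) set.seed(seed)
  lv <- vc_block_levels(img, config)
  bits <- vc_sample_patterns(as.vector(lv), config$s_b)
  out <- vc_assemble_blocks(bits, nrow(lv), ncol(lv),
                            config$block[1L], config$block[2L])
  attr(out, "orig_dim") <- dim(img)
  out
}

#' Draw a random block pattern with a given black count
#'
#' Samples uniformly among all `choose(s_b, black_count)` placements of
#' `black_count` black pixels in a block.
#'
#' @param black_count Number of black pixels, in \[0, block area\].
#' @param block Block shape `c(height, width)`.
#' @return A `block` shaped binary matrix with exactly `black_count` zeros.
#' @export
sample_block_pattern <- function(black_count, block = c(2, 2)) {
  block <- as.integer(block)
  s_b <- block[1L] * block[2L]
  stopifnot(length(black_count) == 1L, black_count >= 0L, black_count <= s_b)
  bits <- vc_sample_patterns(as.integer(black_count), s_b)
  matrix(bits[1L, ], block[1L], block[2L], byrow = TRUE)
}
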