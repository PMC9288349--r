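# Independent oracles and small generators used across the test files.

# Straightforward, unoptimized Floyd-Steinberg error diffusion written
# directly from the kernel definition; kept independent of the package's
# implementation so the two can cross-check each other.
oracle_floyd_steinberg <- function(img, threshold = 128) {
  x <- img + 0
  out <- matrix(0L, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    for (cc in seq_len(ncol(img))) {
      bit <- as.integer(x[r, cc] >= threshold)
      out[r, cc] <- bit
      e <- x[r, cc] - 255 * bit
      nbr <- list(c(0, 1, 7), c(1, -1, 3), c(1, 0, 5), c(1, 1, 1))
      for (n in nbr) {
        rr <- r + n[1]
        ccc <- cc + n[2]
        if (rr >= 1 && rr <= nrow(img) && ccc >= 1 && ccc <= ncol(img) &&
            (n[1] > 0 || n[2] > 0)) {
          x[rr, ccc] <- x[rr, ccc] + e * n[3] / 16
        }
      }
    }
  }
  out
}

random_gray <- function(h, w, seed) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# All 4-bit patterns with a given black count, as strings (independent
# enumeration via expand.grid rather than the package's bit arithmetic).
oracle_patterns_with_black <- function(b) {
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))[, 4:1]
  g <- g[rowSums(g == 0) == b, , drop = FALSE]
  sort(apply(g, 1, paste0, collapse = ""))
}

# Pattern string of each 2x2 block of a binary image, row-major subpixels.
block_pattern_strings <- function(img) {
  H <- nrow(img) / 2
  W <- ncol(img) / 2
  out <- character(H * W)
  k <- 1
  for (j in seq_len(W)) {
    for (i in seq_len(H)) {
      blk <- img[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
      out[k] <- paste0(blk[1, 1], blk[1, 2], blk[2, 1], blk[2, 2])
      k <- k + 1
    }
  }
  out
}
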