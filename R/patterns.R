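# Subpixel-pattern combinatorics shared by every scheme in the package.
#
# Bit convention throughout: 0 = black, 1 = white. Stacking (physical
# superposition) of two patterns is the elementwise Boolean AND: a stacked
# subpixel is white only if it is white in both shares, so black always wins.
# The black set of a stacked pattern is therefore the union of the two black
# sets, which drives all feasibility arithmetic below.

# All 2^s_b bit patterns of length s_b, one per row, in increasing binary
# value (first column is the most significant bit).
vc_patterns <- function(s_b) {
  stopifnot(s_b >= 1, s_b <= 16)
  n <- 2L^s_b
  bits <- matrix(0L, n, s_b)
  for (j in seq_len(s_b)) {
    bits[, j] <- bitwAnd(bitwShiftR(0:(n - 1L), s_b - j), 1L)
  }
  bits
}

vc_black_count <- function(bits) {
  if (is.null(dim(bits))) {
    return(sum(bits == 0L))
  }
  as.integer(rowSums(bits == 0L))
}

vc_pattern_string <- function(bits) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  apply(bits, 1L, paste0, collapse = "")
}

# All C(s_b, b) patterns with exactly b black subpixels.
vc_patterns_with_black <- function(b, s_b) {
  p <- vc_patterns(s_b)
  p[vc_black_count(p) == b, , drop = FALSE]
}

# A block triple (t, b1, b2) is realizable iff some placement of b1 and b2
# black subpixels has a union of size t.
vc_triple_feasible <- function(t, b1, b2, s_b) {
  max(b1, b2) <= t && t <= min(s_b, b1 + b2)
}

.vc_pair_cache <- new.env(parent = emptyenv())

# Every ordered pair (p1, p2) with black counts (b1, b2) whose stack has
# black count t. Cached: the tables are tiny (s_b = 4 has at most 36 pairs)
# and reused for every block of every image.
vc_valid_pairs <- function(t, b1, b2, s_b) {
  key <- paste(t, b1, b2, s_b, sep = "|")
  hit <- .vc_pair_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  p1s <- vc_patterns_with_black(b1, s_b)
  p2s <- vc_patterns_with_black(b2, s_b)
  i <- rep(seq_len(nrow(p1s)), each = nrow(p2s))
  j <- rep(seq_len(nrow(p2s)), times = nrow(p1s))
  stacked <- p1s[i, , drop = FALSE] * p2s[j, , drop = FALSE]
  keep <- vc_black_count(stacked) == t
  out <- list(
    p1 = p1s[i[keep], , drop = FALSE],
    p2 = p2s[j[keep], , drop = FALSE]
  )
  assign(key, out, envir = .vc_pair_cache)
  out
}

# All n! permutations of 1:n, one per row.
vc_perms <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- vc_perms(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    out[[i]] <- cbind(i, matrix(others[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

# Draw one uniformly random pattern with `black_count` black subpixels for
# each entry of `black_count`; returns a length(black_count) x s_b bit matrix.
vc_sample_patterns <- function(black_count, s_b) {
  bits <- matrix(1L, length(black_count), s_b)
  for (b in sort(unique(black_count))) {
    idx <- which(black_count == b)
    pm <- vc_patterns_with_black(b, s_b)
    sel <- sample.int(nrow(pm), length(idx), replace = TRUE)
    bits[idx, ] <- pm[sel, , drop = FALSE]
  }
  bits
}

# Draw one uniformly random valid pair for each block triple. The maps are
# vectors over blocks in column-major block-grid order.
vc_sample_pairs <- function(tmap, b1map, b2map, s_b) {
  n <- length(tmap)
  stopifnot(length(b1map) == n, length(b2map) == n)
  bits1 <- matrix(1L, n, s_b)
  bits2 <- matrix(1L, n, s_b)
  key <- paste(tmap, b1map, b2map, sep = "|")
  for (k in sort(unique(key))) {
    idx <- which(key == k)
    v <- as.integer(strsplit(k, "|", fixed = TRUE)[[1L]])
    if (!vc_triple_feasible(v[1L], v[2L], v[3L], s_b)) {
      stop(sprintf(
        "no arrangement of cover blocks (%d, %d black) stacks to a secret block with %d black pixels",
        v[2L], v[3L], v[1L]
      ), call. = FALSE)
    }
    tab <- vc_valid_pairs(v[1L], v[2L], v[3L], s_b)
    sel <- sample.int(nrow(tab$p1), length(idx), replace = TRUE)
    bits1[idx, ] <- tab$p1[sel, , drop = FALSE]
    bits2[idx, ] <- tab$p2[sel, , drop = FALSE]
  }
  list(bits1, bits2)
}

# Scatter per-block bit rows (column-major block order, subpixels row-major
# within the block) into a full-size image.
vc_assemble_blocks <- function(bits, blocks_h, blocks_w, bh, bw) {
  out <- matrix(1L, blocks_h * bh, blocks_w * bw)
  for (dr in seq_len(bh)) {
    for (dc in seq_len(bw)) {
      p <- (dr - 1L) * bw + dc
      out[seq(dr, by = bh, length.out = blocks_h),
          seq(dc, by = bw, length.out = blocks_w)] <-
        matrix(bits[, p], blocks_h, blocks_w)
    }
  }
  out
}

# Inverse of vc_assemble_blocks: per-block bit rows from a full-size image.
vc_extract_blocks <- function(img, bh, bw) {
  blocks_h <- nrow(img) %/% bh
  blocks_w <- ncol(img) %/% bw
  bits <- matrix(1L, blocks_h * blocks_w, bh * bw)
  for (dr in seq_len(bh)) {
    for (dc in seq_len(bw)) {
      p <- (dr - 1L) * bw + dc
      bits[, p] <- as.vector(img[seq(dr, by = bh, length.out = blocks_h),
                                 seq(dc, by = bw, length.out = blocks_w)])
    }
  }
  bits
}
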