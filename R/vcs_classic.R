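# Classic expanded (2,2) schemes, pixel-by-pixel with m = 4 subpixels.
#
# Plain VCS: both shares are noise. The white-pixel basis matrix S0 has two
# identical 2-black rows (stack keeps 2 black); the black-pixel matrix S1
# has two complementary 2-black rows (stack is all black). A single row is
# always a 2-black pattern, so one share carries no information.
#
# Extended VCS (EVCS): shares look like two cover images. A share block has
# 3 black subpixels where its cover is black and 2 where white; the stacked
# block has 4 black where the secret is black and 3 where white. The basis
# matrix for each (secret, cover1, cover2) combination is any row pair
# meeting those counts; encryption randomness is a uniform column
# permutation, equivalently a uniform draw among all valid row pairs.

# black count per share row, by cover pixel (0 = black, 1 = white)
.evcs_row_black <- function(cover_bit) ifelse(cover_bit == 0L, 3L, 2L)
# black count of the stacked block, by secret pixel
.evcs_stack_black <- function(secret_bit) ifelse(secret_bit == 0L, 4L, 3L)

#' Basis matrices of the plain (2,2)-VCS
#'
#' Returns the canonical basis pair for the 4-subpixel (2,2) scheme: `S0`
#' (white secret pixel) with two identical rows of 2 black subpixels, and
#' `S1` (black secret pixel) with two complementary rows of 2 black
#' subpixels. Stacking the rows of `S1` gives 4 black subpixels; stacking
#' the rows of `S0` gives 2.
#'
#' @return A list with 2x4 bit matrices `S0` and `S1` (0 = black).
#' @export
vcs_basis <- function() {
  p <- c(0L, 0L, 1L, 1L)
  list(S0 = rbind(p, p, deparse.level = 0),
       S1 = rbind(p, 1L - p, deparse.level = 0))
}

#' Basis matrix of the (2,2)-EVCS for one pixel combination
#'
#' Constructs a 2x4 bit matrix for a given (secret, cover1, cover2) pixel
#' combination: row i has 3 black subpixels if cover i is black and 2 if
#' white, and the AND of the rows has 4 black subpixels if the secret is
#' black and 3 if white. All 8 combinations are feasible; the returned
#' matrix is one canonical member — [permute_columns()] generates the full
#' encryption candidate set.
#'
#' @param s,c1,c2 `"black"` or `"white"`: the secret pixel and the two cover
#'   pixels.
#' @return A 2x4 bit matrix with attributes `secret` and `covers`.
#' @export
evcs_basis <- function(s = c("black", "white"),
                       c1 = c("black", "white"),
                       c2 = c("black", "white")) {
  s <- match.arg(s)
  c1 <- match.arg(c1)
  c2 <- match.arg(c2)
  t <- if (s == "black") 4L else 3L
  b1 <- if (c1 == "black") 3L else 2L
  b2 <- if (c2 == "black") 3L else 2L
  if (!vc_triple_feasible(t, b1, b2, 4L)) {
    stop(sprintf("no basis matrix exists for (%s, %s, %s)", s, c1, c2),
         call. = FALSE)
  }
  tab <- vc_valid_pairs(t, b1, b2, 4L)
  m <- rbind(tab$p1[1L, ], tab$p2[1L, ])
  attr(m, "secret") <- s
  attr(m, "covers") <- c(c1, c2)
  m
}

#' Randomly permute the columns of a basis matrix
#'
#' Column permutation is the encryption randomness of the expanded schemes:
#' it preserves each row's black count and the stacked count while
#' randomizing subpixel positions.
#'
#' @param M An n x m bit matrix.
#' @param perm Optional permutation of `seq_len(ncol(M))`; drawn uniformly
#'   at random when `NULL`.
#' @return The column-permuted matrix (attributes preserved).
#' @export
permute_columns <- function(M, perm = NULL) {
  stopifnot(is.matrix(M))
  if (is.null(perm)) {
    perm <- sample.int(ncol(M))
  }
  stopifnot(identical(sort(as.integer(perm)), seq_len(ncol(M))))
  out <- M[, perm, drop = FALSE]
  attributes(out) <- c(attributes(out),
                       attributes(M)[setdiff(names(attributes(M)), c("dim", "dimnames"))])
  out
}

# Expanded per-pixel encryption shared by VCS and EVCS: each secret pixel
# becomes a 2x2 subpixel tile at (2r-1, 2c-1), preserving aspect ratio.
vc_encrypt_expanded <- function(tmap, b1map, b2map, H, W) {
  bits <- vc_sample_pairs(as.vector(tmap), as.vector(b1map),
                          as.vector(b2map), 4L)
  lapply(bits, vc_assemble_blocks, blocks_h = H, blocks_w = W, bh = 2L, bw = 2L)
}

#' Encrypt a binary secret with the plain (2,2)-VCS
#'
#' Each secret pixel is encoded as a 2x2 subpixel tile in each of two noise
#' shares (expansion m = 4). Every share tile has exactly 2 black subpixels
#' regardless of the secret, so a single share is uniform noise; stacking
#' yields 4-black tiles where the secret is black and 2-black tiles where
#' white.
#'
#' @param secret Binary matrix over \{0, 1\} (0 = black).
#' @param seed Optional integer seed.
#' @return A `vc_shares` object with two shares of twice the secret's
#'   height and width.
#' @export
encrypt_vcs <- function(secret, seed = NULL) {
  assert_binary_image(secret, "secret")
  if (!is.null(seed)) set.seed(seed)
  t <- ifelse(secret == 0L, 4L, 2L)
  b <- matrix(2L, nrow(secret), ncol(secret))
  sh <- vc_encrypt_expanded(t, b, b, nrow(secret), ncol(secret))
  new_vc_shares(sh, scheme = "vcs", m = 4L, block = c(2L, 2L),
                secret_dim = dim(secret), seed = seed)
}

#' Encrypt a binary secret with the expanded (2,2)-EVCS
#'
#' Meaningful-share variant: each share tile carries 3 black subpixels where
#' its cover image is black and 2 where white, so each share shows its cover
#' at reduced contrast; the stacked tiles carry 4 black where the secret is
#' black and 3 where white. Expansion m = 4 (shares are 2H x 2W).
#'
#' @param secret,cover1,cover2 Binary matrices over \{0, 1\} of equal
#'   dimensions.
#' @param seed Optional integer seed.
#' @return A `vc_shares` object with two shares.
#' @export
encrypt_evcs <- function(secret, cover1, cover2, seed = NULL) {
  assert_binary_image(secret, "secret")
  assert_binary_image(cover1, "cover1")
  assert_binary_image(cover2, "cover2")
  if (!identical(dim(secret), dim(cover1)) ||
      !identical(dim(secret), dim(cover2))) {
    stop("secret and covers must have identical dimensions", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  t <- .evcs_stack_black(secret)
  b1 <- .evcs_row_black(cover1)
  b2 <- .evcs_row_black(cover2)
  sh <- vc_encrypt_expanded(t, b1, b2, nrow(secret), ncol(secret))
  new_vc_shares(sh, scheme = "evcs", m = 4L, block = c(2L, 2L),
                secret_dim = dim(secret),
                levels = list(secret = c(3L, 4L), cover = c(2L, 3L)),
                seed = seed)
}
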