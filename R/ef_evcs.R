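# Expansion-free extended visual cryptography.
#
# The expanded schemes pay a 4x area cost because every secret pixel becomes
# an m = 4 subpixel tile. The expansion-free scheme works at the block level
# instead: secret and covers are first halftoned onto restricted level sets
# (by default secret blocks carry 3 or 4 black pixels, cover blocks 2 or 3),
# then each cover block's pixels are rearranged so that the AND of the two
# share blocks has exactly the secret block's black count. Shares keep the
# covers' block counts (so they still look like the covers) and have the
# same pixel dimensions as the secret.
#
# The level restriction is what makes this always solvable: a stacked block's
# black set is the union of the two share blocks' black sets, so a triple
# (t, b1, b2) is realizable iff max(b1, b2) <= t <= min(s_b, b1 + b2). With
# unrestricted halftoning a 3-black cover block facing a 2-black secret
# block has no valid arrangement; restricting the secret to {3, 4} and the
# covers to {2, 3} makes every combination feasible.

#' Configuration of the expansion-free EVCS
#'
#' Validates a block shape and the secret/cover level sets, requiring joint
#' feasibility: every (secret level, cover level, cover level) triple must
#' admit a block arrangement. The defaults (2x2 blocks, secret \{3, 4\},
#' covers \{2, 3\}) are the unique two-level choice matching the expanded
#' EVCS subpixel counts.
#'
#' @param block Block shape `c(height, width)`; default `c(2, 2)`.
#' @param secret_levels Allowed black counts per secret block.
#' @param cover_levels Allowed black counts per cover block.
#' @return A list of class `ef_config`.
#' @export
ef_config <- function(block = c(2, 2), secret_levels = c(3, 4),
                      cover_levels = c(2, 3)) {
  sc <- halftone_config(block, secret_levels)
  cc <- halftone_config(block, cover_levels)
  if (!check_feasible(sc$levels, cc$levels, sc$s_b)) {
    stop(sprintf(
      "infeasible level sets: secret {%s} vs cover {%s} on %d-pixel blocks",
      paste(sc$levels, collapse = ","), paste(cc$levels, collapse = ","),
      sc$s_b
    ), call. = FALSE)
  }
  structure(list(block = sc$block, secret_levels = sc$levels,
                 cover_levels = cc$levels, s_b = sc$s_b,
                 secret_config = sc, cover_config = cc),
            class = "ef_config")
}

#' Check feasibility of a secret/cover level-set pair
#'
#' TRUE iff for every secret level t and every pair of cover levels (b1, b2)
#' some arrangement of the cover blocks stacks to exactly t black pixels,
#' i.e. `max(b1, b2) <= t <= min(s_b, b1 + b2)`. For example, secret \{3, 4\}
#' with covers \{2, 3\} is feasible, but covers \{1, 2\} are not (two 1-black
#' blocks can stack to at most 2 < 3).
#'
#' @param secret_levels,cover_levels Integer level sets.
#' @param s_b Block pixel count (default 4 for 2x2 blocks).
#' @return Logical scalar.
#' @export
check_feasible <- function(secret_levels, cover_levels, s_b = 4L) {
  for (t in secret_levels) {
    for (b1 in cover_levels) {
      for (b2 in cover_levels) {
        if (!vc_triple_feasible(t, b1, b2, s_b)) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Arrange one block pair for a target stacked level
#'
#' Draws uniformly among all pattern pairs (p1, p2) with black counts
#' (b1, b2) whose AND has black count t. At t = 4, b1 = b2 = 3 the two
#' white positions must differ (complementary-style pair); at t = 3,
#' b1 = b2 = 3 they must coincide (identical pair).
#'
#' @param t Target black count of the stacked block.
#' @param b1,b2 Black counts of the two share blocks.
#' @param block Block shape `c(height, width)`.
#' @return A list of class `block_assignment` with `p1`, `p2` (bit matrices
#'   of shape `block`) and the counts `t`, `b1`, `b2`.
#' @export
arrange_block <- function(t, b1, b2, block = c(2, 2)) {
  block <- as.integer(block)
  s_b <- block[1L] * block[2L]
  if (!vc_triple_feasible(t, b1, b2, s_b)) {
    stop(sprintf("infeasible block triple (t=%d, b1=%d, b2=%d) for %d-pixel blocks",
                 t, b1, b2, s_b), call. = FALSE)
  }
  tab <- vc_valid_pairs(t, b1, b2, s_b)
  k <- sample.int(nrow(tab$p1), 1L)
  structure(list(
    p1 = matrix(tab$p1[k, ], block[1L], block[2L], byrow = TRUE),
    p2 = matrix(tab$p2[k, ], block[1L], block[2L], byrow = TRUE),
    t = t, b1 = b1, b2 = b2
  ), class = "block_assignment")
}

#' Expansion-free EVCS encryption
#'
#' Halftones the gray secret and covers onto their restricted level sets
#' (independently — encryption only ever sees block counts, never the gray
#' originals), then arranges every block pair so the stacked block count
#' equals the secret block's level. The two shares have exactly the secret's
#' (padded) pixel dimensions: expansion factor 1.
#'
#' @param secret,cover1,cover2 Integer matrices with values in \[0, 255\],
#'   equal dimensions.
#' @param config An [ef_config()].
#' @param seed Optional integer seed; recorded in the result.
#' @return A `vc_shares` object with two shares; `$secret_dim` holds the
#'   original (pre-padding) dimensions.
#' @export
encrypt_ef <- function(secret, cover1, cover2, config = ef_config(),
                       seed = NULL) {
  assert_gray_image(secret, "secret")
  assert_gray_image(cover1, "cover1")
  assert_gray_image(cover2, "cover2")
  stopifnot(inherits(config, "ef_config"))
  if (!identical(dim(secret), dim(cover1)) ||
      !identical(dim(secret), dim(cover2))) {
    stop("secret and covers must have identical dimensions", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  t <- vc_block_levels(secret, config$secret_config)
  b1 <- vc_block_levels(cover1, config$cover_config)
  b2 <- vc_block_levels(cover2, config$cover_config)
  bits <- vc_sample_pairs(as.vector(t), as.vector(b1), as.vector(b2),
                          config$s_b)
  sh <- lapply(bits, vc_assemble_blocks, blocks_h = nrow(t),
               blocks_w = ncol(t), bh = config$block[1L],
               bw = config$block[2L])
  new_vc_shares(sh, scheme = "ef-evcs", m = 1L, block = config$block,
                secret_dim = dim(secret),
                levels = list(secret = config$secret_levels,
                              cover = config$cover_levels),
                seed = seed)
}

#' Interpret a block's black count as a black or white pixel
#'
#' Two-level block codes overlap across contexts: a 3-black block reads as
#' white in a recovered image (where levels are \{3, 4\}) but as black in a
#' cover/share (levels \{2, 3\}). The context selects the level set; within
#' a two-level set the darker level is black.
#'
#' @param black_count Integer vector of block black counts.
#' @param context `"recovered"` (levels 3/4) or `"cover"` (levels 2/3).
#' @param levels Optional explicit two-level set overriding the context
#'   default.
#' @return Integer vector over \{0, 1\} (0 = black, 1 = white).
#' @export
interpret_block <- function(black_count, context = c("recovered", "cover"),
                            levels = NULL) {
  context <- match.arg(context)
  if (is.null(levels)) {
    levels <- if (context == "recovered") c(3L, 4L) else c(2L, 3L)
  }
  levels <- sort(as.integer(levels))
  if (length(levels) != 2L) {
    stop("interpretation needs a two-level set", call. = FALSE)
  }
  if (!all(black_count %in% levels)) {
    stop(sprintf("block count outside the %s level set {%s}",
                 context, paste(levels, collapse = ",")), call. = FALSE)
  }
  ifelse(black_count == levels[2L], 0L, 1L)
}

#' Interpret a binary block image as a block-class map
#'
#' Convenience wrapper: computes per-block black counts and applies
#' [interpret_block()], returning one class pixel per block.
#'
#' @inheritParams interpret_block
#' @param img Binary matrix with block-multiple dimensions.
#' @param block Block shape.
#' @return Binary matrix (blocks_h x blocks_w) over \{0, 1\}.
#' @export
interpret_blocks <- function(img, block = c(2, 2),
                             context = c("recovered", "cover"),
                             levels = NULL) {
  cnt <- block_counts(img, block)
  out <- matrix(interpret_block(as.vector(cnt), context, levels),
                nrow(cnt), ncol(cnt))
  storage.mode(out) <- "integer"
  out
}

#' Render a stacked binary image as a block-gray view
#'
#' Maps each block's black count to the gray value
#' `round(255 * (1 - count / s_b))` replicated over the block — the viewing
#' surface for recovered images (a 3-black 2x2 block renders as gray 64, a
#' 2-black block as 128). Invertible back to block counts.
#'
#' @param stacked Binary matrix with block-multiple dimensions.
#' @param block Block shape `c(height, width)`.
#' @param orig_dim Optional `c(rows, cols)` to crop away halftoning padding.
#' @return Integer gray matrix.
#' @export
reconstruct_gray <- function(stacked, block = c(2, 2), orig_dim = NULL) {
  cnt <- block_counts(stacked, block)
  s_b <- block[1L] * block[2L]
  g <- matrix(as.integer(round(255 * (1 - as.vector(cnt) / s_b))),
              nrow(cnt), ncol(cnt))
  out <- g[rep(seq_len(nrow(g)), each = block[1L]),
           rep(seq_len(ncol(g)), each = block[2L]), drop = FALSE]
  if (!is.null(orig_dim)) {
    out <- out[seq_len(orig_dim[1L]), seq_len(orig_dim[2L]), drop = FALSE]
  }
  storage.mode(out) <- "integer"
  out
}
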