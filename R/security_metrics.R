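# Security and quality evaluation.
#
# The central security claim of every shipped scheme is that one share in
# isolation is worthless: the distribution of the subpixel pattern an
# adversary observes in a single share depends only on that share's cover
# (or on nothing, for plain VCS), never on the secret. leakage_posterior()
# proves this by exact enumeration — for every observable pattern the
# posterior probability of a black secret equals the 0.5 prior.

#' Pixel-expansion factor
#'
#' Ratio of share area to secret area: 4 for the expanded (2,2) schemes,
#' exactly 1 for the expansion-free scheme.
#'
#' @param secret,share Matrices, or `c(rows, cols)` dimension vectors.
#' @return Numeric scalar >= of the area ratio.
#' @export
expansion_factor <- function(secret, share) {
  d1 <- if (is.matrix(secret)) dim(secret) else as.numeric(secret)
  d2 <- if (is.matrix(share)) dim(share) else as.numeric(share)
  stopifnot(length(d1) == 2L, length(d2) == 2L, all(d1 > 0), all(d2 > 0))
  prod(d2) / prod(d1)
}

#' Build a leakage report from pattern tabulations
#'
#' Given, for every observable single-share pattern, its total probability
#' weight under a black and under a white secret (equal priors), computes
#' the posterior P(secret = black | pattern) and the maximum deviation from
#' the 0.5 prior. Used by [leakage_posterior()] and directly useful to
#' audit an arbitrary (possibly broken) sampler.
#'
#' @param weight_black,weight_white Nonnegative numeric vectors of equal
#'   length: P(pattern | secret class) up to a common factor.
#' @param patterns Optional character labels for the patterns.
#' @return An object of class `vc_leakage`: a list with `table`
#'   (data.frame of pattern, weights, posterior) and `max_deviation`.
#' @export
posterior_from_counts <- function(weight_black, weight_white,
                                  patterns = NULL) {
  stopifnot(length(weight_black) == length(weight_white),
            all(weight_black >= 0), all(weight_white >= 0))
  if (is.null(patterns)) {
    patterns <- as.character(seq_along(weight_black))
  }
  tot <- weight_black + weight_white
  keep <- tot > 0
  p_black <- weight_black[keep] / tot[keep]
  tab <- data.frame(
    pattern = patterns[keep],
    weight_black = weight_black[keep],
    weight_white = weight_white[keep],
    p_black = p_black,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, max_deviation = max(abs(p_black - 0.5))),
            class = "vc_leakage")
}

#' @export
print.vc_leakage <- function(x, ...) {
  cat(sprintf("<vc_leakage> %d observable patterns | max |posterior - 0.5| = %.3g\n",
              nrow(x$table), x$max_deviation))
  invisible(x)
}

#' Exact single-share leakage posterior
#'
#' Enumerates every encoding a scheme can emit and computes, for each
#' observable single-share subpixel pattern, the exact posterior probability
#' that the secret pixel (or block) is black, under equal priors over the
#' secret class and over the cover combinations. For the expanded schemes
#' the enumeration runs over all column permutations of the basis matrices;
#' for the expansion-free scheme it runs over all valid block-pattern pairs.
#' Every shipped scheme yields 0.5 for every pattern: a single share reveals
#' nothing.
#'
#' @param scheme `"evcs"`, `"vcs"` or `"ef-evcs"`.
#' @param secret_levels,cover_levels Level sets for `"ef-evcs"` (two levels
#'   each).
#' @param block Block shape for `"ef-evcs"`.
#' @param share Which share the adversary observes (1 or 2).
#' @return A `vc_leakage` object (see [posterior_from_counts()]), with the
#'   total enumeration size in attribute `n_enumerated`.
#' @export
leakage_posterior <- function(scheme = c("evcs", "vcs", "ef-evcs"),
                              secret_levels = c(3, 4),
                              cover_levels = c(2, 3),
                              block = c(2, 2), share = 1L) {
  scheme <- match.arg(scheme)
  share <- as.integer(share)
  stopifnot(share %in% c(1L, 2L))
  if (scheme %in% c("evcs", "vcs")) {
    s_b <- 4L
  } else {
    block <- as.integer(block)
    s_b <- block[1L] * block[2L]
  }
  pats <- vc_pattern_string(vc_patterns(s_b))
  w <- matrix(0, length(pats), 2L, dimnames = list(pats, c("black", "white")))
  n_enum <- 0L

  add <- function(pattern_bits, cls, weight) {
    key <- vc_pattern_string(pattern_bits)
    w[key, cls] <<- w[key, cls] + weight
  }

  if (scheme == "vcs") {
    basis <- vcs_basis()
    perms <- vc_perms(4L)
    for (cls in c("black", "white")) {
      B <- if (cls == "black") basis$S1 else basis$S0
      for (k in seq_len(nrow(perms))) {
        add(B[share, perms[k, ]], cls, 1 / nrow(perms))
        n_enum <- n_enum + 1L
      }
    }
  } else if (scheme == "evcs") {
    perms <- vc_perms(4L)
    covers <- expand.grid(c1 = c("black", "white"), c2 = c("black", "white"),
                          stringsAsFactors = FALSE)
    for (cls in c("black", "white")) {
      for (i in seq_len(nrow(covers))) {
        B <- evcs_basis(cls, covers$c1[i], covers$c2[i])
        for (k in seq_len(nrow(perms))) {
          add(B[share, perms[k, ]], cls, 1 / (nrow(covers) * nrow(perms)))
          n_enum <- n_enum + 1L
        }
      }
    }
  } else {
    secret_levels <- sort(as.integer(secret_levels))
    cover_levels <- sort(as.integer(cover_levels))
    if (length(secret_levels) != 2L) {
      stop("leakage report needs a two-level secret set", call. = FALSE)
    }
    if (!check_feasible(secret_levels, cover_levels, s_b)) {
      stop("infeasible level sets", call. = FALSE)
    }
    covers <- expand.grid(b1 = cover_levels, b2 = cover_levels)
    for (t in secret_levels) {
      cls <- if (t == secret_levels[2L]) "black" else "white"
      for (i in seq_len(nrow(covers))) {
        tab <- vc_valid_pairs(t, covers$b1[i], covers$b2[i], s_b)
        obs <- if (share == 1L) tab$p1 else tab$p2
        np <- nrow(obs)
        for (k in seq_len(np)) {
          add(obs[k, ], cls, 1 / (nrow(covers) * np))
          n_enum <- n_enum + 1L
        }
      }
    }
  }

  out <- posterior_from_counts(w[, "black"], w[, "white"], rownames(w))
  out$scheme <- scheme
  attr(out, "n_enumerated") <- n_enum
  out
}

#' Chi-square uniformity of share patterns within cover-level strata
#'
#' Security requires not just the right per-block black counts but a uniform
#' choice among all placements: within each stratum of blocks sharing a
#' black count b, the observed frequencies of the `choose(s_b, b)` patterns
#' are tested against the uniform distribution with Pearson's chi-square
#' (df = patterns - 1). Strata with a single possible pattern (b = 0 or
#' b = s_b) carry no information and are skipped.
#'
#' @param share Binary matrix with block-multiple dimensions.
#' @param block Block shape `c(height, width)`.
#' @param min_blocks Warn when a stratum has fewer blocks than this.
#' @return A data.frame with one row per stratum: `level`, `n_blocks`,
#'   `n_patterns`, `statistic`, `df`, `p_value`.
#' @export
share_uniformity <- function(share, block = c(2, 2), min_blocks = 50L) {
  block <- as.integer(block)
  s_b <- block[1L] * block[2L]
  bits <- vc_extract_blocks(share, block[1L], block[2L])
  assert_binary_image(share, "share")
  cnt <- vc_black_count(bits)
  key <- vc_pattern_string(bits)
  levels_seen <- sort(unique(cnt))
  rows <- list()
  for (b in levels_seen) {
    k <- choose(s_b, b)
    if (k < 2) next
    idx <- cnt == b
    n <- sum(idx)
    if (n < min_blocks) {
      warning(sprintf("stratum level %d has only %d blocks; chi-square unreliable",
                      b, n), call. = FALSE)
    }
    expected_pats <- vc_pattern_string(vc_patterns_with_black(b, s_b))
    obs <- table(factor(key[idx], levels = expected_pats))
    e <- n / k
    stat <- sum((obs - e)^2 / e)
    rows[[length(rows) + 1L]] <- data.frame(
      level = b, n_blocks = n, n_patterns = k, statistic = stat,
      df = k - 1, p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    )
  }
  do.call(rbind, rows)
}

#' Recovered-image contrast
#'
#' The visual contrast alpha of a recovered image: the difference in mean
#' white subpixels per block between blocks whose secret class is white and
#' those whose class is black, divided by the block area. The expansion-free
#' defaults give alpha = (1 - 0)/4 = 0.25; plain VCS gives (2 - 0)/4 = 0.5.
#'
#' @param recovered Binary matrix (a stacked image) with block-multiple
#'   dimensions.
#' @param secret_class Binary matrix over \{0, 1\} with one entry per block
#'   (0 = secret block black, 1 = white), e.g. from [interpret_blocks()] or
#'   the binary secret itself for the expanded schemes.
#' @param block Block shape.
#' @return Numeric scalar in \[0, 1\].
#' @export
contrast_alpha <- function(recovered, secret_class, block = c(2, 2)) {
  block <- as.integer(block)
  s_b <- block[1L] * block[2L]
  cnt <- block_counts(recovered, block)
  if (!identical(dim(cnt), dim(secret_class))) {
    stop("secret_class must have one entry per recovered block", call. = FALSE)
  }
  whites <- s_b - cnt
  is_white <- secret_class == 1L
  if (!any(is_white) || all(is_white)) {
    stop("contrast is undefined when the secret has a single class",
         call. = FALSE)
  }
  (mean(whites[is_white]) - mean(whites[!is_white])) / s_b
}

#' Peak signal-to-noise ratio between two gray images
#'
#' `10 * log10(255^2 / MSE)` in decibels; `Inf` for identical images.
#'
#' @param a,b Integer matrices with values in \[0, 255\], equal dimensions.
#' @return Numeric scalar in dB (possibly `Inf`).
#' @export
psnr <- function(a, b) {
  assert_gray_image(a, "a")
  assert_gray_image(b, "b")
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  mse <- mean((a - b)^2)
  if (mse == 0) {
    return(Inf)
  }
  10 * log10(255^2 / mse)
}

#' Evaluate a share set against its secret
#'
#' One-stop quality/security report: expansion factor, recovered contrast,
#' PSNR of the block-gray recovered view against the limited-halftone
#' secret, exact leakage deviation, and the minimum share-uniformity
#' p-value across shares and strata.
#'
#' @param shares A `vc_shares` object from [encrypt_ef()].
#' @param secret The gray secret it encrypted.
#' @param config The [ef_config()] used.
#' @return A list with elements `expansion`, `alpha` (`NA` when the secret
#'   halftones to a single class), `psnr`, `leakage_max_deviation`,
#'   `uniformity_min_p`.
#' @export
evaluate_shares <- function(shares, secret, config = ef_config()) {
  stopifnot(inherits(shares, "vc_shares"), inherits(config, "ef_config"))
  padded <- vc_pad_to_blocks(secret, config$block)
  rec <- stack_shares(shares)
  t <- vc_block_levels(secret, config$secret_config)
  cls <- matrix(interpret_block(as.vector(t), levels = config$secret_levels),
                nrow(t), ncol(t))
  g <- matrix(as.integer(round(255 * (1 - as.vector(t) / config$s_b))),
              nrow(t), ncol(t))
  halftone_view <- g[rep(seq_len(nrow(g)), each = config$block[1L]),
                     rep(seq_len(ncol(g)), each = config$block[2L]),
                     drop = FALSE]
  lk <- leakage_posterior("ef-evcs", config$secret_levels,
                          config$cover_levels, config$block)
  un <- rbind(share_uniformity(shares$shares[[1L]], config$block),
              share_uniformity(shares$shares[[2L]], config$block))
  alpha <- tryCatch(contrast_alpha(rec, cls, config$block),
                    error = function(e) NA_real_) # single-class secret
  list(
    expansion = expansion_factor(padded, shares$shares[[1L]]),
    alpha = alpha,
    psnr = psnr(reconstruct_gray(rec, config$block), halftone_view),
    leakage_max_deviation = lk$max_deviation,
    uniformity_min_p = min(un$p_value)
  )
}
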