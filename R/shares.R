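# Share containers and Boolean stacking.

new_vc_shares <- function(shares, scheme, m, block, secret_dim,
                          levels = NULL, seed = NULL) {
  stopifnot(is.list(shares), length(shares) >= 2L)
  d <- dim(shares[[1L]])
  for (s in shares) {
    if (!identical(dim(s), d)) {
      stop("all shares must have identical dimensions", call. = FALSE)
    }
  }
  structure(
    list(
      shares = shares,
      scheme = scheme,
      m = m,
      block = as.integer(block),
      secret_dim = as.integer(secret_dim),
      share_dim = as.integer(d),
      levels = levels,
      seed = seed
    ),
    class = "vc_shares"
  )
}

#' @export
print.vc_shares <- function(x, ...) {
  cat(sprintf(
    "<vc_shares> scheme: %s | %d shares of %dx%d | secret %dx%d | expansion m = %s\n",
    x$scheme, length(x$shares), x$share_dim[1L], x$share_dim[2L],
    x$secret_dim[1L], x$secret_dim[2L], format(x$m)
  ))
  if (!is.null(x$levels)) {
    cat(sprintf("  levels: secret {%s}, cover {%s}\n",
                paste(x$levels$secret, collapse = ","),
                paste(x$levels$cover, collapse = ",")))
  }
  invisible(x)
}

#' Stack shares by Boolean superposition
#'
#' Superimposes two or more shares: under the 0 = black convention a stacked
#' pixel is white only where every share is white, i.e. the pixelwise AND.
#' This is the decryption operation of every scheme in the package — no key,
#' no arithmetic beyond AND.
#'
#' @param x A `vc_shares` object or a list of binary matrices of equal
#'   dimensions (at least two).
#' @return A binary matrix over \{0, 1\}.
#' @export
stack_shares <- function(x) {
  shares <- if (inherits(x, "vc_shares")) x$shares else x
  if (!is.list(shares) || length(shares) < 2L) {
    stop("need at least two shares to stack", call. = FALSE)
  }
  d <- dim(shares[[1L]])
  out <- shares[[1L]]
  assert_binary_image(out, "shares[[1]]")
  for (i in seq_along(shares)[-1L]) {
    s <- shares[[i]]
    assert_binary_image(s, sprintf("shares[[%d]]", i))
    if (!identical(dim(s), d)) {
      stop("shares must have identical dimensions", call. = FALSE)
    }
    out <- out * s
  }
  storage.mode(out) <- "integer"
  out
}

#' Write a share set to disk with a JSON sidecar
#'
#' Writes each share as `share1`, `share2`, ... plus a `<stem>_meta.json`
#' sidecar recording the scheme, expansion, block shape, original secret
#' dimensions, level sets and seed, so an encryption is replayable and a
#' recovered view can be cropped back to the secret's size.
#'
#' @param x A `vc_shares` object.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem; default `"share"`.
#' @param format `"png"` or `"pgm"`.
#' @return Invisibly, the sidecar path.
#' @export
write_shares <- function(x, dir, stem = "share", format = c("png", "pgm")) {
  stopifnot(inherits(x, "vc_shares"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(x$shares))
  for (i in seq_along(x$shares)) {
    paths[i] <- file.path(dir, sprintf("%s%d.%s", stem, i, format))
    write_binary(x$shares[[i]], paths[i])
  }
  meta <- list(
    scheme = x$scheme, m = x$m, block = x$block,
    secret_dim = x$secret_dim, share_dim = x$share_dim,
    levels = x$levels, seed = x$seed, shares = basename(paths)
  )
  sidecar <- file.path(dir, sprintf("%s_meta.json", stem))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, null = "null")
  invisible(sidecar)
}
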