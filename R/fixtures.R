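# Deterministic synthetic images and the batch share-split pipeline.
#
# The fixtures stand in for real image collections so the whole pipeline is
# testable offline: smooth gradients exercise every gray level, checkerboards
# exercise block alignment, text-like strokes give high-frequency structure,
# and the blob generator emulates nucleus-like dark clusters on a bright
# tissue background. They are statistical stand-ins, not renderings of any
# real dataset.

#' Generate a deterministic synthetic gray image
#'
#' @param kind `"gradient"` (each row runs linearly 0..255 left to right),
#'   `"checkerboard"` (alternating 0/255 cells), `"text"` (dark strokes on a
#'   white page) or `"blobs"` (dark elliptical clusters on a bright, lightly
#'   textured background).
#' @param height,width Output dimensions in pixels.
#' @param seed Integer seed; the same spec and seed give a byte-identical
#'   image.
#' @param cell Checkerboard cell size in pixels.
#' @param n_blobs Number of elliptical clusters for `"blobs"`.
#' @param radius Length-2 range of blob semi-axes in pixels.
#' @param intensity Length-2 range of blob core intensities.
#' @param background Background intensity for `"blobs"`.
#' @return An integer matrix with values in \[0, 255\].
#' @export
make_fixture <- function(kind = c("gradient", "checkerboard", "text", "blobs"),
                         height = 64, width = 64, seed = 1,
                         cell = 8, n_blobs = 12, radius = c(3, 10),
                         intensity = c(0, 120), background = 230) {
  kind <- match.arg(kind)
  stopifnot(height >= 2, width >= 2)
  set.seed(seed)
  img <- switch(kind,
    gradient = {
      row <- round(seq(0, 255, length.out = width))
      matrix(rep(row, each = height), height, width)
    },
    checkerboard = {
      ri <- ceiling(seq_len(height) / cell)
      ci <- ceiling(seq_len(width) / cell)
      255L * outer(ri, ci, function(a, b) (a + b) %% 2L)
    },
    text = {
      x <- matrix(255L, height, width)
      n_strokes <- max(6L, round(height * width / 300))
      for (i in seq_len(n_strokes)) {
        horizontal <- stats::runif(1) < 0.5
        len <- sample(3:max(4L, round(width / 4)), 1L)
        thick <- sample(1:2, 1L)
        r0 <- sample(seq_len(max(1L, height - thick)), 1L)
        c0 <- sample(seq_len(max(1L, width - 3L)), 1L)
        if (horizontal) {
          rr <- r0:min(height, r0 + thick - 1L)
          cc <- c0:min(width, c0 + len - 1L)
        } else {
          rr <- r0:min(height, r0 + len - 1L)
          cc <- c0:min(width, c0 + thick - 1L)
        }
        x[rr, cc] <- sample(0:40, 1L)
      }
      x
    },
    blobs = {
      noise <- matrix(stats::rnorm(height * width, 0, 6), height, width)
      x <- background + noise
      rows <- matrix(seq_len(height), height, width)
      cols <- matrix(seq_len(width), height, width, byrow = TRUE)
      for (i in seq_len(n_blobs)) {
        cy <- stats::runif(1, 1, height)
        cx <- stats::runif(1, 1, width)
        a <- stats::runif(1, radius[1L], radius[2L])
        b <- stats::runif(1, radius[1L], radius[2L])
        th <- stats::runif(1, 0, pi)
        core <- stats::runif(1, intensity[1L], intensity[2L])
        dy <- rows - cy
        dx <- cols - cx
        u <- (cos(th) * dx + sin(th) * dy) / a
        v <- (-sin(th) * dx + cos(th) * dy) / b
        d2 <- u^2 + v^2
        inside <- d2 <= 1
        # soft edge: blend toward the core over the inner 70% of the radius
        wgt <- pmin(1, pmax(0, (1 - sqrt(pmin(d2, 1))) / 0.3))
        x[inside] <- x[inside] * (1 - wgt[inside]) + core * wgt[inside]
      }
      x
    }
  )
  out <- round(pmax(pmin(img, 255), 0))
  storage.mode(out) <- "integer"
  out
}

# Stable 31-polynomial hash of a string, kept in [0, 2^31 - 2]; combined
# with the master seed so adding files to a folder never perturbs the
# per-image seeds of existing files.
vc_path_seed <- function(relpath, master) {
  h <- 0
  for (code in utf8ToInt(relpath)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((h + master) %% 2147483647)
}

# Fit an image to target dimensions by center cropping then padding with
# the edge intensity (white for typical bright-background covers).
vc_fit_dims <- function(img, dims, fill = 255L) {
  nr <- nrow(img)
  nc <- ncol(img)
  tr <- dims[1L]
  tc <- dims[2L]
  if (nr > tr) {
    off <- (nr - tr) %/% 2L
    img <- img[(off + 1L):(off + tr), , drop = FALSE]
  }
  if (nc > tc) {
    off <- (nc - tc) %/% 2L
    img <- img[, (off + 1L):(off + tc), drop = FALSE]
  }
  if (nrow(img) < tr || ncol(img) < tc) {
    out <- matrix(as.integer(fill), tr, tc)
    r0 <- (tr - nrow(img)) %/% 2L
    c0 <- (tc - ncol(img)) %/% 2L
    out[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))] <- img
    img <- out
  }
  img
}

#' Split an image folder into shares and recovered views
#'
#' Batch pipeline for building a "share-split" dataset: every readable PNG
#' or PGM in `in_dir` is halftoned onto the secret level set, encrypted into
#' two meaningful shares, stacked, and rendered as a block-gray recovered
#' view. Four artifacts per input are written to `out_dir`
#' (`<name>_share1`, `<name>_share2`, `<name>_recovered`,
#' `<name>_recovered_gray`); the original image is never copied — the point
#' of the exercise is that the originals can be discarded once the shares
#' are stored separately. A JSON-lines manifest (`manifest.jsonl`) records
#' the per-image seed and configuration for bit-exact replay.
#'
#' @param in_dir Folder of input images (`.png`/`.pgm`).
#' @param out_dir Output folder, created if missing.
#' @param config An [ef_config()].
#' @param cover_policy `"fixed"` (two fixed blob covers, fitted to each
#'   secret's size) or `"generated"` (fresh per-image covers from the
#'   per-image seed).
#' @param seed Master integer seed; per-image seeds are derived from it and
#'   the file's relative path.
#' @param format Output format, `"png"` or `"pgm"`.
#' @return Invisibly, a data.frame with one row per processed image
#'   (`input`, `seed`, `share1`, `share2`, `recovered`, `recovered_gray`).
#' @export
degrade_dataset <- function(in_dir, out_dir, config = ef_config(),
                            cover_policy = c("fixed", "generated"),
                            seed = 1, format = c("png", "pgm")) {
  cover_policy <- match.arg(cover_policy)
  format <- match.arg(format)
  stopifnot(inherits(config, "ef_config"), dir.exists(in_dir))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- sort(list.files(in_dir, pattern = "\\.(png|pgm)$",
                           ignore.case = TRUE))
  records <- list()
  for (f in files) {
    path <- file.path(in_dir, f)
    secret <- tryCatch(read_gray(path), error = function(e) {
      warning(sprintf("skipping '%s': %s", f, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(secret)) next
    img_seed <- vc_path_seed(f, seed)
    if (cover_policy == "fixed") {
      c1 <- vc_fit_dims(make_fixture("blobs", 64, 64, seed = seed + 101),
                        dim(secret))
      c2 <- vc_fit_dims(make_fixture("blobs", 64, 64, seed = seed + 202),
                        dim(secret))
    } else {
      c1 <- make_fixture("blobs", nrow(secret), ncol(secret),
                         seed = img_seed + 1L)
      c2 <- make_fixture("blobs", nrow(secret), ncol(secret),
                         seed = img_seed + 2L)
    }
    shares <- encrypt_ef(secret, c1, c2, config, seed = img_seed)
    rec <- stack_shares(shares)
    rec_gray <- reconstruct_gray(rec, config$block, orig_dim = dim(secret))
    stem <- tools::file_path_sans_ext(f)
    out <- c(
      share1 = sprintf("%s_share1.%s", stem, format),
      share2 = sprintf("%s_share2.%s", stem, format),
      recovered = sprintf("%s_recovered.%s", stem, format),
      recovered_gray = sprintf("%s_recovered_gray.%s", stem, format)
    )
    write_binary(shares$shares[[1L]], file.path(out_dir, out["share1"]))
    write_binary(shares$shares[[2L]], file.path(out_dir, out["share2"]))
    write_binary(rec, file.path(out_dir, out["recovered"]))
    write_gray(rec_gray, file.path(out_dir, out["recovered_gray"]))
    # the originals must be discardable: refuse to emit a byte copy of one
    in_bytes <- readBin(path, "raw", file.info(path)$size)
    for (o in out) {
      op <- file.path(out_dir, o)
      ob <- readBin(op, "raw", file.info(op)$size)
      if (length(ob) == length(in_bytes) && all(ob == in_bytes)) {
        stop(sprintf("output '%s' is a byte copy of the input '%s'", o, f),
             call. = FALSE)
      }
    }
    records[[length(records) + 1L]] <- data.frame(
      input = f, seed = img_seed, cover_policy = cover_policy,
      share1 = out[["share1"]], share2 = out[["share2"]],
      recovered = out[["recovered"]],
      recovered_gray = out[["recovered_gray"]],
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, records)
  if (!is.null(manifest)) {
    lines <- vapply(seq_len(nrow(manifest)), function(i) {
      rec <- as.list(manifest[i, ])
      rec$config <- list(block = config$block,
                         secret_levels = config$secret_levels,
                         cover_levels = config$cover_levels)
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, file.path(out_dir, "manifest.jsonl"))
  }
  invisible(manifest)
}

#' Read a degradation manifest
#'
#' @param path Path to a `manifest.jsonl` written by [degrade_dataset()].
#' @return A data.frame with one row per record.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  do.call(rbind, lapply(recs, function(r) {
    data.frame(input = r$input, seed = r$seed, cover_policy = r$cover_policy,
               share1 = r$share1, share2 = r$share2, recovered = r$recovered,
               recovered_gray = r$recovered_gray, stringsAsFactors = FALSE)
  }))
}
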