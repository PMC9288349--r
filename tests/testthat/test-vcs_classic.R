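# Classic expanded (2,2) schemes: basis matrices, permutation, encryption.

stack_bits <- function(a, b) a * b

test_that("plain VCS basis matrices satisfy the count invariants", {
  basis <- vcs_basis()
  expect_identical(rowSums(basis$S0 == 0), c(2, 2))
  expect_identical(rowSums(basis$S1 == 0), c(2, 2))
  expect_identical(sum(stack_bits(basis$S1[1, ], basis$S1[2, ]) == 0), 4L)
  expect_identical(stack_bits(basis$S0[1, ], basis$S0[2, ]), basis$S0[1, ])
})

test_that("single VCS rows are marginally indistinguishable across secrets", {
  basis <- vcs_basis()
  perms <- vcshare:::vc_perms(4)
  dist_for <- function(M) {
    sort(table(apply(perms, 1, function(p) paste0(M[1, p], collapse = ""))))
  }
  expect_identical(dist_for(basis$S0), dist_for(basis$S1))
})

test_that("EVCS basis matrices exist for all 8 combinations with the right counts", {
  for (s in c("black", "white")) {
    for (c1 in c("black", "white")) {
      for (c2 in c("black", "white")) {
        M <- evcs_basis(s, c1, c2)
        expect_identical(sum(M[1, ] == 0), if (c1 == "black") 3L else 2L)
        expect_identical(sum(M[2, ] == 0), if (c2 == "black") 3L else 2L)
        expect_identical(sum(stack_bits(M[1, ], M[2, ]) == 0),
                         if (s == "black") 4L else 3L)
      }
    }
  }
})

test_that("EVCS basis matches the published structures up to column permutation", {
  # black secret, black covers: rows like [0 1 0 0] and [1 0 0 0] --
  # single white subpixels at distinct positions
  M <- evcs_basis("black", "black", "black")
  expect_identical(which(M[1, ] == 1) == which(M[2, ] == 1), FALSE)
  # white secret, black covers: identical rows, white positions coincide
  M <- evcs_basis("white", "black", "black")
  expect_identical(M[1, ], M[2, ])
  # black secret, white covers: 2-black rows with disjoint white positions
  M <- evcs_basis("black", "white", "white")
  expect_identical(sum(M[1, ] == 0), 2L)
  expect_length(intersect(which(M[1, ] == 1), which(M[2, ] == 1)), 0)
})

test_that("uniform pair sampling spans exactly the column-permutation orbit", {
  # each published basis matrix's permutation orbit equals the full set of
  # valid row pairs for its counts, so the two sampling views coincide
  perms <- vcshare:::vc_perms(4)
  for (s in c("black", "white")) {
    for (c1 in c("black", "white")) {
      for (c2 in c("black", "white")) {
        M <- evcs_basis(s, c1, c2)
        orbit <- unique(apply(perms, 1, function(p) {
          paste0(c(M[1, p], M[2, p]), collapse = "")
        }))
        t <- if (s == "black") 4L else 3L
        b1 <- if (c1 == "black") 3L else 2L
        b2 <- if (c2 == "black") 3L else 2L
        tab <- vcshare:::vc_valid_pairs(t, b1, b2, 4L)
        pairs <- vapply(seq_len(nrow(tab$p1)), function(k) {
          paste0(c(tab$p1[k, ], tab$p2[k, ]), collapse = "")
        }, character(1))
        expect_setequal(orbit, pairs)
      }
    }
  }
})

test_that("permute_columns preserves rows as multisets and orbits deduplicate", {
  M <- evcs_basis("white", "black", "black")
  expect_identical(permute_columns(M, perm = 1:4)[, 1:4], M[, 1:4])
  set.seed(9)
  for (i in 1:10) {
    P <- permute_columns(M)
    expect_identical(sort(P[1, ]), sort(M[1, ]))
    expect_identical(sort(P[2, ]), sort(M[2, ]))
  }
  # S for (white, black, black) has three identical columns: 4!/3! = 4
  # distinct permuted matrices
  perms <- vcshare:::vc_perms(4)
  mats <- unique(apply(perms, 1, function(p) {
    paste0(M[, p], collapse = "")
  }))
  expect_length(mats, 4)
})

test_that("plain VCS encryption recovers the secret at block level", {
  black <- matrix(0L, 2, 2)
  white <- matrix(1L, 2, 2)
  sh_b <- encrypt_vcs(black, seed = 1)
  sh_w <- encrypt_vcs(white, seed = 2)
  expect_identical(dim(sh_b$shares[[1]]), c(4L, 4L))
  expect_true(all(stack_shares(sh_b) == 0L))
  expect_true(all(block_counts(stack_shares(sh_w)) == 2L))
  # share blocks always carry exactly 2 black subpixels, secret-independent
  for (sh in c(sh_b$shares, sh_w$shares)) {
    expect_true(all(block_counts(sh) == 2L))
  }
})

test_that("expanded EVCS shares show the covers and stack to the secret", {
  secret <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  cover1 <- matrix(0L, 2, 2)
  cover2 <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  sh <- encrypt_evcs(secret, cover1, cover2, seed = 3)
  expect_identical(expansion_factor(secret, sh$shares[[1]]), 4)
  expect_identical(block_counts(sh$shares[[1]]),
                   matrix(ifelse(cover1 == 0L, 3L, 2L), 2, 2))
  expect_identical(block_counts(sh$shares[[2]]),
                   matrix(ifelse(cover2 == 0L, 3L, 2L), 2, 2))
  expect_identical(block_counts(stack_shares(sh)),
                   matrix(ifelse(secret == 0L, 4L, 3L), 2, 2))
  expect_error(encrypt_evcs(secret, cover1, matrix(1L, 2, 4)),
               "identical dimensions")
})

test_that("stacking reproduces the worked subpixel examples exactly", {
  c1 <- matrix(c(0L, 1L, 0L, 0L), 2, 2, byrow = TRUE)
  c2 <- matrix(c(1L, 0L, 0L, 0L), 2, 2, byrow = TRUE)
  expect_identical(stack_shares(list(c1, c2)), matrix(0L, 2, 2)) # black
  expect_identical(stack_shares(list(c1, c1)), c1)               # white
  # idempotence and identity
  set.seed(8)
  x <- matrix(sample(0:1, 16, replace = TRUE), 4, 4)
  expect_identical(stack_shares(list(x, x)), x)
  expect_identical(stack_shares(list(x, matrix(1L, 4, 4))), x)
  expect_error(stack_shares(list(x)), "at least two")
})

test_that("a single EVCS share's patterns are independent of the secret", {
  # homogeneity chi-square across secret strata, same cover everywhere
  set.seed(101)
  n <- 100 # 100x100 pixels = 10000 blocks
  secret <- matrix(sample(0:1, n * n, replace = TRUE), n, n)
  cover <- matrix(0L, n, n)
  sh <- encrypt_evcs(secret, cover, cover)
  pats <- block_pattern_strings(sh$shares[[1]])
  strata <- as.vector(secret) # block order matches column-major pixels
  tab <- table(strata, pats)
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})
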