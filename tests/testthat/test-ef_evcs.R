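# Expansion-free EVCS: feasibility, block arrangement, round trip.

test_that("feasibility captures exactly the union bound on stacked blocks", {
  expect_true(check_feasible(c(3, 4), c(2, 3), 4))
  expect_false(check_feasible(c(3, 4), c(1, 2), 4)) # two 1-black blocks stack to <= 2
  expect_true(check_feasible(4, 4, 4))
  # an unrestricted halftone can leave a 3-black cover facing a 2-black
  # secret block, which no arrangement can stack to
  expect_false(check_feasible(2, 3, 4))
  # exhaustive cross-check against brute-force pattern search
  for (t in 0:4) {
    for (b1 in 0:4) {
      for (b2 in 0:4) {
        tab <- vcshare:::vc_valid_pairs(t, b1, b2, 4L)
        expect_identical(nrow(tab$p1) > 0,
                         vcshare:::vc_triple_feasible(t, b1, b2, 4L))
      }
    }
  }
})

test_that("arrange_block realizes the published pair structures", {
  set.seed(5)
  for (i in 1:20) {
    ab <- arrange_block(4, 3, 3)
    expect_false(which(ab$p1 == 1) == which(ab$p2 == 1)) # whites differ
    expect_true(all(ab$p1 * ab$p2 == 0L))                # stack all black
    ab <- arrange_block(3, 3, 3)
    expect_identical(ab$p1, ab$p2)                        # whites coincide
  }
  expect_error(arrange_block(4, 1, 1), "infeasible")
})

test_that("at (t=4, b1=b2=2) the partner block is always the complement and p1 is uniform", {
  set.seed(6)
  n <- 60000
  pats <- character(n)
  for (i in seq_len(n)) {
    ab <- arrange_block(4, 2, 2)
    expect_true(all(ab$p2 == 1L - ab$p1))
    pats[i] <- paste0(ab$p1[1, 1], ab$p1[1, 2], ab$p1[2, 1], ab$p1[2, 2])
  }
  freq <- table(factor(pats, levels = oracle_patterns_with_black(2)))
  expect_true(all(abs(freq / n - 1 / 6) < 0.01))
})

test_that("encryption is expansion-free and round trips block counts exactly", {
  secret <- make_fixture("gradient", 64, 64)
  c1 <- make_fixture("blobs", 64, 64, seed = 2)
  c2 <- make_fixture("blobs", 64, 64, seed = 3)
  cfg <- ef_config()
  sh <- encrypt_ef(secret, c1, c2, cfg, seed = 7)

  expect_identical(expansion_factor(secret, sh$shares[[1]]), 1)
  expect_identical(dim(sh$shares[[2]]), dim(secret))

  # stacked block counts equal the secret's limited-halftone levels --
  # recomputed independently via the halftoner (counts are deterministic)
  want <- block_counts(limited_halftone(secret, halftone_config(levels = c(3, 4)),
                                        seed = 99))
  expect_identical(block_counts(stack_shares(sh)), want)

  # each share's block counts equal its cover's limited-halftone levels
  cover_cfg <- halftone_config(levels = c(2, 3))
  expect_identical(block_counts(sh$shares[[1]]),
                   block_counts(limited_halftone(c1, cover_cfg, seed = 1)))
  expect_identical(block_counts(sh$shares[[2]]),
                   block_counts(limited_halftone(c2, cover_cfg, seed = 1)))
})

test_that("odd-sized secrets are padded and the crop box restores them", {
  secret <- random_gray(31, 33, seed = 8)
  covers <- list(random_gray(31, 33, seed = 9), random_gray(31, 33, seed = 10))
  sh <- encrypt_ef(secret, covers[[1]], covers[[2]], seed = 11)
  expect_identical(dim(sh$shares[[1]]), c(32L, 34L))
  expect_identical(sh$secret_dim, c(31L, 33L))
  rec <- reconstruct_gray(stack_shares(sh), orig_dim = sh$secret_dim)
  expect_identical(dim(rec), c(31L, 33L))
})

test_that("infeasible configurations are rejected up front", {
  expect_error(ef_config(secret_levels = 4, cover_levels = 1), "infeasible")
  expect_error(ef_config(secret_levels = c(3, 4), cover_levels = c(1, 2)),
               "infeasible")
  expect_silent(ef_config())
})

test_that("block interpretation resolves the overlapping 3-black code by context", {
  expect_identical(interpret_block(4, "recovered"), 0L) # black
  expect_identical(interpret_block(3, "recovered"), 1L) # white
  expect_identical(interpret_block(3, "cover"), 0L)     # black
  expect_identical(interpret_block(2, "cover"), 1L)     # white
  expect_error(interpret_block(2, "recovered"), "level set")
  expect_error(interpret_block(4, "cover"), "level set")
})

test_that("reconstruct_gray maps counts to block grays and is invertible", {
  expect_true(all(reconstruct_gray(matrix(0L, 4, 4)) == 0L))
  one_white <- matrix(c(0L, 1L, 0L, 0L), 2, 2)
  expect_true(all(reconstruct_gray(one_white) == 64L))   # round(255 * 1/4)
  two_white <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_true(all(reconstruct_gray(two_white) == 128L))  # round(255 * 1/2)

  set.seed(12)
  bits <- matrix(sample(0:1, 8 * 8, replace = TRUE), 8, 8)
  g <- reconstruct_gray(bits)
  back <- round(4 * (1 - g[seq(1, 8, 2), seq(1, 8, 2)] / 255))
  expect_identical(back, block_counts(bits) + 0)
})

test_that("round trip holds for every block across seeds and random secrets", {
  cfg <- ef_config()
  for (s in 1:5) {
    secret <- random_gray(32, 32, seed = 300 + s)
    c1 <- random_gray(32, 32, seed = 400 + s)
    c2 <- random_gray(32, 32, seed = 500 + s)
    sh <- encrypt_ef(secret, c1, c2, cfg, seed = s)
    want <- block_counts(limited_halftone(secret,
                                          halftone_config(levels = c(3, 4)),
                                          seed = 1))
    expect_identical(block_counts(stack_shares(sh)), want)
  }
})
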