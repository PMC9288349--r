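# vcshare

Visual cryptography for grayscale images, aimed at privacy-preserving
storage and transmission of sensitive images (medical scans, biometric
templates) on devices too weak for conventional encryption. A secret image
is split into two *shares* that individually reveal nothing; superimposing
them — a pixelwise Boolean AND, feasible even on printed transparencies —
reveals the secret. No keys, no modular arithmetic.

The package implements three (2,2) schemes:

* **`encrypt_vcs()`** — classic visual secret sharing. Each secret pixel
  becomes an m = 4 subpixel tile in two noise-like shares (4× pixel
  expansion). A white pixel is encoded by two identical 2-black tiles
  (stack: 2 black), a black pixel by complementary tiles (stack: 4 black).
* **`encrypt_evcs()`** — extended VCS with *meaningful* shares: each share
  tile carries 3 black subpixels where its cover image is black and 2 where
  white, so the shares look like two innocuous cover images instead of
  noise. Still 4× expansion.
* **`encrypt_ef()`** — the expansion-free extended scheme. Secret and cover
  images are first halftoned block-wise onto restricted level sets
  (`limited_halftone()`: secret blocks carry 3 or 4 black pixels, cover
  blocks 2 or 3), then each cover block's pixels are rearranged so that the
  AND of the two share blocks has exactly the secret block's black count.
  Shares keep their covers' block statistics *and* have exactly the
  secret's pixel dimensions — expansion factor 1.

The level restriction is the load-bearing idea. A stacked block's black set
is the union of the share blocks' black sets, so a secret level t is
reachable from cover levels (b1, b2) iff
`max(b1, b2) <= t <= min(s_b, b1 + b2)` (block area s_b = 4). With
unrestricted halftoning a 3-black cover block facing a 2-black secret block
is unsolvable; with secret ∈ {3,4} and covers ∈ {2,3} every combination is
feasible (`check_feasible()`), at the price of a darker, lower-contrast
recovery (contrast α = 1/4).

Security is auditable, not asserted: `leakage_posterior()` enumerates every
encoding a scheme can emit and verifies that the posterior probability of a
black secret given any single-share pattern equals the 0.5 prior, and
`share_uniformity()` chi-square-tests that emitted patterns are uniform
within each cover-level stratum.

## Worked example

```r
library(vcshare)

secret <- make_fixture("blobs", 64, 64, seed = 1)        # tissue-like image
cover1 <- make_fixture("gradient", 64, 64)
cover2 <- make_fixture("checkerboard", 64, 64, cell = 16)

shares <- encrypt_ef(secret, cover1, cover2, ef_config(), seed = 2026)
shares
#> <vc_shares> scheme: ef-evcs | 2 shares of 64x64 | secret 64x64 | expansion m = 1
#>   levels: secret {3,4}, cover {2,3}

recovered <- stack_shares(shares)                         # pixelwise AND
table(block_counts(recovered))                            # secret levels only
#>    3    4
#> 1019    5
table(block_counts(shares$shares[[1]]))                   # cover levels only
#>   2   3
#> 640 384

str(evaluate_shares(shares, secret, ef_config()))
#> List of 5
#>  $ expansion            : num 1
#>  $ alpha                : num 0.25
#>  $ psnr                 : num Inf
#>  $ leakage_max_deviation: num 5.55e-17
#>  $ uniformity_min_p     : num 0.318
```

Reading the report: the shares are exactly the secret's size
(`expansion = 1`); the recovered image separates secret-white from
secret-black blocks by one white subpixel per block (`alpha = 0.25`, enough
for the eye); block-level recovery is exact (`psnr = Inf` against the
halftoned secret, since every stacked block count equals the secret's
halftone level); no single-share pattern shifts the posterior off 0.5
(`leakage_max_deviation ~ 1e-17`, i.e. floating-point zero); and the
pattern-uniformity chi-square does not reject (`uniformity_min_p = 0.32`).
`reconstruct_gray(recovered)` renders the stack as a viewable gray image,
and `write_shares(shares, "out/")` stores the shares with a JSON sidecar
for replay.

For batch use, `degrade_dataset(in_dir, out_dir, seed = ...)` runs
halftone → encrypt → stack → render over an image folder, writing two
shares and two recovered views per input plus a JSON-lines manifest — the
originals are never copied, mirroring a deployment where only the shares
are retained on separate servers.

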