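---
title: "Expansion-free extended visual cryptography: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expansion-free extended visual cryptography: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcshare)
```

## The problem

Sensitive grayscale images — medical scans, biometric templates — must
sometimes be stored or transmitted through infrastructure that cannot be
trusted and on devices too weak for conventional cryptography. Visual
cryptography addresses this with secret sharing: the image is split into
two shares held by different parties (or databases), each share is
individually uninformative, and the secret reappears under plain Boolean
superposition of the shares. Decryption needs no key and no arithmetic
beyond AND, and survives printing.

Two classical defects motivate the scheme this package centres on. First,
*pixel expansion*: the standard (2,2) construction encodes each secret
pixel as m = 4 subpixels, quadrupling share area. Second, *suspicious
shares*: noise-like shares advertise that something is hidden. Extended
schemes fix the second problem by making each share resemble an innocuous
cover image; the expansion-free extended scheme here fixes both at once.

## Conventions and the stacking model

Throughout the package a binary pixel is `0 = black`, `1 = white`, and
stacking k shares is the pixelwise AND: a stacked pixel is white only where
every share is white, exactly as physical superposition of transparencies
behaves (ink wins). Under this convention the black set of a stacked block
is the **union** of the share blocks' black sets — the single fact from
which all feasibility arithmetic follows. Gray images are integer matrices
in [0, 255]; file writers map bits to display intensities (0/255) at the
boundary only.

## Classic expanded (2,2) schemes

`encrypt_vcs()` encodes each secret pixel as one row of a 2×4 basis matrix
per share, laid out as a 2×2 subpixel tile (preserving aspect ratio). The
white-pixel matrix has two identical rows with 2 black subpixels each
(stack: 2 black); the black-pixel matrix has complementary rows (stack: 4
black). Encryption randomness is a uniformly random column permutation per
pixel. Since a single row is always "2 black out of 4", one share is
exactly uniform noise.

`encrypt_evcs()` is the meaningful-share variant: row i of the basis matrix
carries 3 black subpixels where cover i is black and 2 where it is white,
while the AND of the rows carries 4 black for a black secret pixel and 3
for a white one. All eight (secret, cover1, cover2) combinations admit such
a matrix; the package constructs the full family once by exhaustive search
over 4-bit pattern pairs subject to those count constraints. A test
verifies that the column-permutation orbit of each canonical matrix equals
the full set of valid pairs, so sampling uniformly among valid pairs (what
the implementation does, per block, from cached tables) is distributionally
identical to uniform column permutation.

## Limited-level halftoning

Gray inputs must become binary before encryption. `error_diffusion()`
provides the standard Floyd–Steinberg baseline (raster scan, threshold 128,
weights 7/16, 3/16, 5/16, 1/16), which uses every local density and is the
visually faithful reference.

`limited_halftone()` is the block-wise variant the expansion-free scheme
requires. The image is tiled into non-overlapping blocks (default 2×2,
s_b = 4 pixels); each block's ideal darkness is

    d = s_b * (1 - mean(block) / 255)

black pixels, and d is quantized to the nearest member of a *candidate
level set*, with ties broken toward the darker level; that many black
pixels are then placed uniformly at random within the block. The nearest-
level quantization with a darker tie-break is the package's design choice
for mapping tone onto a restricted palette: it is monotone (darker blocks
never get lighter levels), clamps extremes to the extreme allowed levels,
and with the full level set {0..s_b} never errs by more than half a level.
The darker tie-break matches the scheme's overall bias — restricted-level
recoveries are darker than the source.

Images whose dimensions are not block multiples are padded bottom/right
with white; the original dimensions travel in metadata and the viewing
functions crop them back.

## The expansion-free scheme

`encrypt_ef()` operates entirely at block level:

1. Halftone the secret onto `secret_levels` (default {3, 4}) and each cover
   onto `cover_levels` (default {2, 3}) — *independently*: encryption sees
   only block counts, never the gray originals, so preprocessing cannot
   leak the secret into a share.
2. For every block, draw uniformly among all pattern pairs (p1, p2) with
   the covers' black counts whose AND has the secret's black count, from
   exhaustively enumerated (and cached) valid-pair tables.
3. Emit p1 into share 1 and p2 into share 2.

Shares therefore have the secret's (padded) pixel dimensions — expansion
factor exactly 1 — and their block counts are exactly their covers'
halftone levels, so each share still shows its cover. Stacking returns
exactly the secret's halftone levels on every block, every time; the
recovery guarantee is combinatorial, not statistical.

**Why {3,4} / {2,3}?** Feasibility of a triple (t, b1, b2) is
`max(b1, b2) <= t <= min(s_b, b1 + b2)`. Requiring *every* combination of a
two-level secret set and two-level cover set to be feasible on 2×2 blocks
forces `max(cover) <= min(secret)` and `2 * min(cover) >= max(secret)`;
{3,4} with {2,3} is the unique two-level pair satisfying both while keeping
both sets contiguous and non-degenerate, and it coincides with the subpixel
counts of the expanded extended scheme. Other feasible sets (e.g. {4} with
{3}) are accepted by `ef_config()`, which validates feasibility up front
and rejects, for instance, covers {1, 2} (two 1-black blocks can stack to
at most 2 < 3).

**Interpretation of overlapping codes.** A 3-black block is *white* in a
recovered image (whose levels are {3, 4}) but *black* in a share/cover
(levels {2, 3}). `interpret_block()` makes the context explicit rather than
guessing; within a two-level set the darker level is black. The recovered
contrast is α = (1 − 0)/4 = 0.25: one white subpixel per secret-white
block, none per secret-black block — half the classic VCS contrast of 0.5,
the price of meaningful, unexpanded shares.

## Security: exact enumeration, then sampling checks

A scheme leaks if the pattern an adversary sees in one share shifts the
posterior over the secret class. Because every scheme here has a finite
encoding set, the posterior is computed *exactly*: `leakage_posterior()`
enumerates all column permutations of the basis family (expanded schemes)
or all valid pairs (expansion-free), under equal priors over secret class
and cover combination, and reports P(secret = black | pattern) for every
observable pattern. For all shipped schemes every posterior is 0.5 to
floating-point precision; the intuition for the expansion-free case is that
given the observed block's own count b1, the number of valid completions by
the partner share depends only on b1, never on the secret level t, so the
observed pattern is uniform on its count class under both secret classes.

The implementation could still be broken (a biased sampler would not change
the enumerated posterior), so `share_uniformity()` tests emitted shares:
within each stratum of blocks sharing a black count b, observed pattern
frequencies are compared to the uniform distribution over `choose(4, b)`
patterns with Pearson's chi-square (df = patterns − 1). The shipped tests
use α = 0.01 at 10 000 blocks under fixed seeds — large enough that a
uniform sampler essentially never trips it and a degenerate one (a single
repeated pattern) is rejected below 10⁻⁶. Strata with fewer than 50 blocks
warn rather than silently producing an unstable statistic.

`posterior_from_counts()` exposes the posterior computation for arbitrary
tabulations, so a deliberately secret-dependent sampler can be audited the
same way.

## Quality metrics

`expansion_factor()` is the share/secret area ratio (4 for the expanded
schemes, 1 for the expansion-free one). `contrast_alpha()` is the
difference in mean white subpixels per block between secret-white and
secret-black blocks, over the block area; it errors when the secret has a
single class, where contrast is undefined. `psnr()` is the usual
10·log10(255²/MSE) with `Inf` as the identical-image sentinel.
`evaluate_shares()` reports PSNR of the recovered block-gray view against
the *halftoned* secret's block-gray view — block-level recovery is the
scheme's fidelity target, and that PSNR is infinite exactly when the
round-trip guarantee holds. Fidelity against the original gray image is
limited by the two-level halftone itself, not by encryption, and is
deliberately not folded into the report.

## Synthetic fixtures and the batch pipeline

`make_fixture()` generates deterministic images: gradients (every gray
level, smooth tone ramps), checkerboards (block-aligned hard edges),
text-like strokes (high-frequency structure), and "blobs" — dark,
soft-edged elliptical clusters on a bright, lightly textured background,
emulating nucleus-like statistics of stained tissue at a coarse level. They
exercise tone range, alignment, and structure, but none reproduces the
texture spectra, staining variability, or resolution of real microscopy or
radiology; passing tests demonstrate the combinatorial and statistical
contracts of the scheme, not recognition performance on clinical data.

`degrade_dataset()` mirrors a deployment in which originals are discarded
after splitting: for every image in a folder it halftones, encrypts,
stacks, and renders, writing four artifacts per input and a JSON-lines
manifest. Per-image seeds are a stable hash of the file's relative path
mixed with the master seed, so adding files never perturbs existing
outputs; the writer refuses to emit a byte copy of any input. Cover policy
is either two fixed covers fitted to each secret's size (center-crop then
pad) or per-image generated covers; both are exposed because either is a
reasonable deployment.

## Numerical choices and degenerate inputs

* Binarization boundary: `value >= threshold` is white, so threshold 128
  sends mid-gray up, matching the error-diffusion threshold.
* Nearest-level ties quantize toward the darker level (deterministic, and
  consistent with the scheme's darkening bias).
* Padding fill is white (255), the usual background; padded blocks land on
  the lightest allowed level.
* All randomness flows through R's global RNG; every encryption function
  takes an optional integer seed, recorded in the share metadata, making
  share generation bit-reproducible given (inputs, seed).
* Constant-class secrets encrypt fine but make contrast undefined;
  `contrast_alpha()` errors rather than returning 0/0.
* `ef_config()` validates level-set feasibility at construction, so
  per-block arrangement can only fail on triples that the configuration
  already proved impossible (e.g. hand-built count maps).

## Problem sizes in the shipped tests

The test suite works at desk scale, chosen so the full suite runs in a few
minutes: 64×64 to 256×256 images for round-trip and conservation checks,
100 random 64×64 secrets for the repeated round-trip property, 10 000
blocks (200×200 pixels) for chi-square uniformity, and 60 000 draws for
pattern-frequency checks (1/6 ± 0.01 per 2-black pattern). The exact
enumeration behind the leakage posterior is tiny (192 matrices for the
extended scheme) and runs in well under a second.

## Limitations

* Only (2,2) threshold schemes; no (k,n) generalization, and stacking more
  than two shares of the expansion-free scheme has no defined semantics.
* Recovery is block-level and two-level: fine gray detail is quantized away
  by the restricted halftone, and recovered images are darker than the
  source. Perfect gray recovery would require XOR-style stacking, which is
  out of scope.
* Grayscale only; colour inputs are luminance-collapsed with a warning.
  8-bit PNG and raw PGM are the only formats.
* The security guarantees are per-block and information-theoretic for a
  single share; they say nothing about an adversary who obtains both
  shares, metadata side channels, or correlations an application introduces
  by reusing covers.
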