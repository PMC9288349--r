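Package: vcshare
Title: Expansion-Free Extended Visual Cryptography for Grayscale Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Visual cryptography toolkit for privacy-preserving storage and
    transmission of grayscale (e.g. medical) images. Implements classic
    (2,2) visual secret sharing and extended visual cryptography with
    meaningful cover shares, together with an expansion-free extended
    scheme built on limited gray-level block halftoning: secret and cover
    images are halftoned onto restricted per-block black-pixel level sets
    and each cover block's pixels are rearranged so that Boolean stacking
    of the two same-size shares reproduces the secret's block levels.
    Includes exact single-share leakage enumeration, share-pattern
    uniformity tests, contrast and fidelity metrics, deterministic
    synthetic image fixtures, and a batch pipeline that splits an image
    folder into share pairs and recovered views.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    stats,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
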