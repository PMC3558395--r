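Package: inchikeystats
Title: Collision Statistics and Layout Analysis for Hashed Chemical
    Identifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the collision resistance of the InChIKey,
    the 27-character truncated-SHA-256 hash of the IUPAC International
    Chemical Identifier. Provides closed-form birthday-paradox collision
    statistics for uniform hashes, explicit codecs for the InChIKey
    triplet/doublet letter layout (16384 valid triplets, 512 valid
    doublets, exactly 2^65 first blocks and 2^37 second blocks), a
    deterministic synthetic generator of stereoisomer and skeleton
    identifier strings, truncated-SHA-256 key synthesis, Monte Carlo
    collision-counting subsampling experiments, and positional
    letter/sequence frequency analysis with an exact layout-derived
    probability calculus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, stringi, jsonlite
Suggests: testthat (>= 3.0.0), openssl, optparse, withr
SystemRequirements: OpenSSL (libcrypto)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
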