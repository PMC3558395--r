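## Truncated-SHA-256 key synthesis.
##
## Emulates key production: SHA-256 of the skeleton part, leading 65 bits,
## letter-encoded through the first-block layout; SHA-256 of the
## isomer-layer part, leading 37 bits, through the second-block layout.
## "Leading bits, big-endian" is this package's truncation convention;
## which 65/37 of the 256 digest bits the official tool retains is not
## derivable from black-box statistics, and every statistic studied here
## is invariant to that choice.

.BITS_BLOCK1 <- 65L
.BITS_BLOCK2 <- 37L
.WIDTHS_BLOCK1 <- c(14L, 14L, 14L, 14L, 9L)   # triplet,triplet,triplet,triplet,doublet
.WIDTHS_BLOCK2 <- c(14L, 14L, 9L)

#' Truncate the SHA-256 digest of strings to leading bits
#'
#' Computes the SHA-256 digest of each input and keeps the leading `bits`
#' bits, interpreted as a big-endian integer.  Deterministic and
#' referentially transparent.
#'
#' @param input character vector of input strings.
#' @param bits number of leading digest bits to retain, 1..256.
#' @return for `bits <= 53`, a numeric vector of exact integer values; for
#'   larger widths, a character vector of decimal integers.
#' @examples
#' hashToBits("SYN=1S/C2H6O/c1-2-3", 37)
#' @export
hashToBits <- function(input, bits) {
  stopifnot(is.character(input), length(bits) == 1L)
  if (is.na(bits) || bits < 1 || bits > 256 || bits != floor(bits))
    stop("'bits' must be an integer in 1..256")
  bits <- as.integer(bits)
  if (bits <= 53L)
    return(drop(.Call(C_sha256_windows, input, bits)))
  widths <- c(rep(24L, bits %/% 24L),
              if (bits %% 24L) bits %% 24L)
  win <- .Call(C_sha256_windows, input, widths)
  vapply(seq_along(input), function(i) {
    big <- .bigFromNumber(0)
    for (j in seq_along(widths))
      big <- .bigMulAdd(big, 2^widths[j], win[i, j])
    .bigToDecimal(big)
  }, character(1))
}

## 0-based unit-index matrices straight from the digest (fast paths)
.hashBlock1Indices <- function(input)
  .Call(C_sha256_windows, input, .WIDTHS_BLOCK1)

.hashBlock2Indices <- function(input)
  .Call(C_sha256_windows, input, .WIDTHS_BLOCK2)

#' Forge a single key from identifier parts
#'
#' `block1 <- encode(leading 65 bits of SHA-256(skeletonPart))`;
#' `block2 <- encode(leading 37 bits of SHA-256(isomerPart))`; flags and
#' protonation take the defaults 'S' (standard), 'A' (version), 'N'
#' (neutral).  Two isomers of one skeleton therefore share the first
#' block and (almost surely) differ in the second.
#'
#' @param skeletonPart non-empty string hashed into the first block.
#' @param isomerPart non-empty string hashed into the second block.
#' @return a [KeyRecord-class].
#' @examples
#' makeKey("SYN=1S/C2H6O/c1-2-3", "1+,2-")
#' @export
makeKey <- function(skeletonPart, isomerPart) {
  stopifnot(is.character(skeletonPart), length(skeletonPart) == 1L,
            nzchar(skeletonPart),
            is.character(isomerPart), length(isomerPart) == 1L,
            nzchar(isomerPart))
  new("KeyRecord",
      block1 = .indicesToBlocks(.hashBlock1Indices(skeletonPart),
                                block1Layout()),
      block2 = .indicesToBlocks(.hashBlock2Indices(isomerPart),
                                block2Layout()),
      flagStandard = "S", flagVersion = "A", protonation = "N")
}

#' Forge keys for vectors of identifier parts
#'
#' Vectorized [makeKey()]: returns serialized 27-character keys.  With
#' only `identifiers` given, each identifier is split on the reserved
#' `"|"` separator into skeleton and isomer parts (an identifier without
#' a separator hashes whole into both blocks' inputs is *not* assumed —
#' its skeleton part is the full string and its isomer part is empty, in
#' which case the isomer part falls back to the skeleton part).
#'
#' @param skeletonParts character vector of first-block inputs, or full
#'   identifiers when `isomerParts` is missing.
#' @param isomerParts character vector of second-block inputs, recycled
#'   to the length of `skeletonParts`.
#' @return character vector of 27-character keys.
#' @examples
#' forgeKeys(enumerateStereoisomers(skeletonSpec("demo", 2)))
#' @export
forgeKeys <- function(skeletonParts, isomerParts = NULL) {
  if (is.null(isomerParts)) {
    parts <- splitIdentifier(skeletonParts)
    skeletonParts <- parts$skeleton
    isomerParts <- ifelse(nzchar(parts$isomer), parts$isomer,
                          parts$skeleton)
  }
  if (length(isomerParts) != length(skeletonParts))
    isomerParts <- rep_len(isomerParts, length(skeletonParts))
  b1 <- .indicesToBlocks(.hashBlock1Indices(skeletonParts), block1Layout())
  b2 <- .indicesToBlocks(.hashBlock2Indices(isomerParts), block2Layout())
  paste0(b1, "-", b2, "SA-N")
}

#' Stream a stereoisomer population into packed truncated hashes
#'
#' Enumerates the 2^nStereo stereoisomers of a skeleton (or the first
#' `limit` of them) in chunks, hashes each isomer layer with SHA-256, and
#' retains only the leading `bits` bits as a packed numeric vector —
#' never materializing the full string population.  This is the
#' population that the second-block subsampling experiments draw from.
#'
#' @param spec a [skeletonSpec()].
#' @param bits truncation width (default 37, the second-block width).
#' @param limit optional cap on the number of isomers.
#' @param chunkSize strings per streaming chunk.
#' @return numeric vector of `min(2^nStereo, limit)` hash values.
#' @examples
#' h <- hashStereoPopulation(skeletonSpec("demo", 10))
#' length(h)   # 1024
#' @export
hashStereoPopulation <- function(spec, bits = 37L, limit = NULL,
                                 chunkSize = 2^18) {
  stopifnot(inherits(spec, "SkeletonSpec"), bits >= 1, bits <= 53)
  total <- 2^spec$nStereo
  n <- if (is.null(limit)) total else min(total, limit)
  out <- numeric(n)
  from <- 0
  bits <- as.integer(bits)
  while (from < n) {
    take <- min(chunkSize, n - from)
    layers <- .isomerLayers(spec, from, take)
    out[(from + 1):(from + take)] <-
      .Call(C_sha256_windows, layers, bits)
    from <- from + take
  }
  out
}
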