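## Positional letter statistics and the layout-derived sequence
## probability calculus.
##
## Because blocks are built from restricted unit tables, letters are not
## uniform across positions: 'E' never opens a triplet, only TTW..TZZ of
## the T-initial triplets exist, and no doublet starts with U..Z.  The
## probability that a letter window appears at a given block position is
## obtained by enumeration: decompose the window across the units it
## overlaps, count the valid unit strings compatible with the constrained
## letters, divide by each unit's cardinality, and multiply (units are
## independent under the uniform-hash model).  Enumeration rather than
## case analysis keeps one code path for the genuine and for miniature
## (exhaustively checkable) layouts.

## letters of each key/block at the block1 positions; input may be
## 27-char keys or bare 14-letter blocks (or blockLength(layout) letters)
.extractBlocks <- function(x, layout = block1Layout()) {
  blen <- blockLength(layout)
  n27 <- nchar(x) == 27L
  out <- ifelse(n27, substr(x, 1L, 14L), x)
  ok <- nchar(out) == blen
  list(blocks = out, ok = ok)
}

## rows: which valid unit strings carry the given letters at the given
## within-unit positions
.unitMatchCount <- function(codec, positions, letterVec) {
  keep <- rep(TRUE, cardinality(codec))
  for (j in seq_along(positions))
    keep <- keep & substr(codec@validStrings, positions[j],
                          positions[j]) == letterVec[j]
  sum(keep)
}

#' Positional letter counts over a key corpus
#'
#' Counts, for every alphabet letter and every first-block position, how
#' many keys carry that letter there.  Inputs may be 27-character keys or
#' bare block strings; inputs of the wrong length are excluded and
#' reported in the result's `nMalformed` slot.  Block strings are not
#' unit-validated here — the count matrix itself is the instrument that
#' reveals the layout (see [inferUnitBoundaries()]).
#'
#' @param keys character vector of 27-character keys or block strings.
#' @param layout a [KeyLayout-class] (defaults to the first block).
#' @param referenceLetter letter used for normalized views (default "A").
#' @return a [FrequencyMatrix-class].
#' @examples
#' keys <- forgeKeys(generateSkeletonPopulation(1000, seed = 1))
#' letterPositionFrequencies(keys)
#' @export
letterPositionFrequencies <- function(keys, layout = block1Layout(),
                                      referenceLetter = "A") {
  ex <- .extractBlocks(keys, layout)
  blocks <- ex$blocks[ex$ok]
  blen <- blockLength(layout)
  ab <- layout@alphabet
  counts <- matrix(0, nrow = length(ab), ncol = blen,
                   dimnames = list(ab, seq_len(blen)))
  for (p in seq_len(blen)) {
    tb <- table(factor(stri_sub(blocks, p, p), levels = ab))
    counts[, p] <- as.numeric(tb)
  }
  new("FrequencyMatrix", counts = counts, nKeys = length(blocks),
      nMalformed = sum(!ex$ok), referenceLetter = referenceLetter)
}

#' Normalized letter frequencies
#'
#' Two normalizations of a [FrequencyMatrix-class]:
#' * `by = "position1"` (default): every cell is divided by the reference
#'   letter's frequency at the first block position — the convention of
#'   the classic per-position table, where 'A' at position 1 reads
#'   exactly 1 and the doublet-start enrichment of 'A' reads
#'   (26/512)/(676/16384) = 1.2308.
#' * `by = "block"`: one value per letter — its whole-block frequency
#'   divided by the reference letter's whole-block frequency (the
#'   per-letter bar-chart view).
#'
#' @param x a [FrequencyMatrix-class].
#' @param by `"position1"` or `"block"`.
#' @return a numeric matrix (letters x positions) or a named vector.
#' @export
normalizedFrequencies <- function(x, by = c("position1", "block")) {
  stopifnot(is(x, "FrequencyMatrix"))
  by <- match.arg(by)
  if (by == "position1") {
    ref <- x@counts[x@referenceLetter, 1L]
    if (ref == 0) stop("reference letter never occurs at position 1")
    x@counts / ref
  } else {
    tot <- rowSums(x@counts)
    ref <- tot[x@referenceLetter]
    if (ref == 0) stop("reference letter never occurs in the block")
    tot / ref
  }
}

#' Probability of a letter sequence at a fixed block position
#'
#' Probability that a uniformly random *valid* block carries `letters`
#' starting at position `start`.  The window is decomposed across the
#' units it overlaps; for each unit the number of valid unit strings
#' matching the constrained letter positions is counted by enumeration
#' and divided by the unit cardinality; the per-unit probabilities
#' multiply.  For the genuine first block,
#' `sequenceProbabilityAt("ABCD", 1)` is
#' (1/16384) x (676/16384) = 2.5183e-6: the first triplet must be
#' exactly "ABC" and the second must be one of the 676 triplets starting
#' with 'D'.
#'
#' @param letters uppercase letter string (the window).
#' @param start 1-based start position within the block.
#' @param layout a [KeyLayout-class].
#' @return probability in `[0, 1]`.
#' @examples
#' sequenceProbabilityAt("ABCD", 1)          # 2.5183e-6
#' sequenceProbabilityAt("EZZ", 1)           # 0: no triplet starts with E
#' @export
sequenceProbabilityAt <- function(letters, start,
                                  layout = block1Layout()) {
  stopifnot(is.character(letters), length(letters) == 1L,
            nchar(letters) >= 1L, start >= 1)
  w <- nchar(letters)
  blen <- blockLength(layout)
  if (start + w - 1L > blen)
    stop(sprintf("window [%d, %d] exceeds the %d-letter block",
                 start, start + w - 1L, blen))
  lv <- strsplit(letters, "")[[1]]
  starts <- .unitStarts(layout)
  prob <- 1
  for (u in seq_along(layout@units)) {
    codec <- layout@units[[u]]
    ufrom <- starts[u]
    uto <- ufrom + codec@unitLength - 1L
    lo <- max(ufrom, start)
    hi <- min(uto, start + w - 1L)
    if (lo > hi) next
    ov <- lo:hi
    prob <- prob * .unitMatchCount(codec, ov - ufrom + 1L,
                                   lv[ov - start + 1L]) /
      cardinality(codec)
  }
  prob
}

#' Total probability of a letter sequence anywhere in the block
#'
#' Sum of [sequenceProbabilityAt()] over every start position the window
#' fits (11 positions for a 4-letter window in the 14-letter first
#' block).  By linearity of expectation this is also the expected number
#' of (possibly overlapping) occurrences per key.
#'
#' @inheritParams sequenceProbabilityAt
#' @return expected occurrences per key (a probability-scale number).
#' @examples
#' sequenceProbability("ABCD")    # 2.7530e-5
#' @export
sequenceProbability <- function(letters, layout = block1Layout()) {
  w <- nchar(letters)
  nwin <- blockLength(layout) - w + 1L
  sum(vapply(seq_len(nwin), function(s)
    sequenceProbabilityAt(letters, s, layout), numeric(1)))
}

#' Theoretically expected occurrences of a sequence in a key corpus
#'
#' `nKeys` times [sequenceProbability()]: the expected total number of
#' start positions, over all keys, at which `letters` occurs.
#' Overlapping self-occurrences within one key are counted per start
#' position, matching the linearity-of-expectation derivation; the
#' observed counterpart ([observedOccurrences()]) uses the same
#' convention.
#'
#' @inheritParams sequenceProbabilityAt
#' @param nKeys corpus size.
#' @return expected occurrence count (real; round for display).
#' @examples
#' expectedOccurrences("ABCD", 1.2002e9)    # 33041
#' @export
expectedOccurrences <- function(letters, nKeys,
                                layout = block1Layout()) {
  nKeys * sequenceProbability(letters, layout)
}

#' Observed occurrences of a sequence in a key corpus
#'
#' Total number of start positions, over all keys' first blocks, where
#' `letters` occurs (overlapping occurrences counted).
#'
#' @param keys character vector of 27-character keys or block strings.
#' @param letters the sequence to scan for.
#' @param layout a [KeyLayout-class].
#' @return integer-valued count.
#' @export
observedOccurrences <- function(keys, letters,
                                layout = block1Layout()) {
  ex <- .extractBlocks(keys, layout)
  sum(stri_count_fixed(ex$blocks[ex$ok], letters, overlap = TRUE))
}

#' Infer unit boundaries from a positional frequency matrix
#'
#' Reads the layout straight off the count matrix, the way a black-box
#' analysis of a key corpus reveals it: positions where 'E' never occurs
#' are triplet starts; the position where none of 'U'..'Z' occurs but 'E'
#' does is the doublet start.  For a corpus of forged keys this returns
#' `c(1, 4, 7, 10, 13)`.
#'
#' @param x a [FrequencyMatrix-class] from at least ~10^5 keys.
#' @return integer vector of unit start positions, with attribute
#'   `conclusive`; if the corpus is too small to show the pattern the
#'   result is flagged `conclusive = FALSE`.
#' @export
inferUnitBoundaries <- function(x) {
  stopifnot(is(x, "FrequencyMatrix"))
  cts <- x@counts
  eZero <- cts["E", ] == 0
  uzZero <- colSums(cts[c("U", "V", "W", "X", "Y", "Z"), , drop = FALSE]) == 0
  tripletStarts <- which(eZero & !uzZero)
  doubletStarts <- which(uzZero & !eZero)
  out <- sort(c(tripletStarts, doubletStarts))
  conclusive <- x@nKeys >= 1e4 && length(doubletStarts) == 1L &&
    length(tripletStarts) >= 1L
  attr(out, "conclusive") <- conclusive
  if (!conclusive)
    warning("boundary pattern inconclusive (corpus too small?)")
  out
}
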