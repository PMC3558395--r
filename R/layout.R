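## The InChIKey letter layout as explicit, enumerable codecs.
##
## Both hash blocks are written in 3-letter units ("triplets") and a
## terminal 2-letter unit ("doublet").  Not every letter string is a valid
## unit: the valid triplets are AAA..ZZZ minus the ranges EAA..EZZ and
## TAA..TTV (leaving 16384 = 2^14), and the valid doublets are AA..TR
## (512 = 2^9).  A block is then a mixed-radix number over its units:
## 16384^4 x 512 = 2^65 first blocks, 16384^2 x 512 = 2^37 second blocks.

#' Build a unit codec from a table of valid strings
#'
#' @param strings character vector of valid unit strings, all the same
#'   length, strictly increasing lexicographically, uppercase.
#' @return a [UnitCodec-class].
#' @examples
#' unitCodec(c("AA", "AB", "BA", "CA"))   # a miniature doublet codec
#' @export
unitCodec <- function(strings) {
  new("UnitCodec", unitLength = nchar(strings[1L]),
      validStrings = as.character(strings))
}

#' The 16384 valid triplets
#'
#' All 3-letter strings AAA through ZZZ (26^3 = 17576) except the 676
#' strings EAA..EZZ and the 516 strings TAA..TTV, in lexicographic order:
#' 17576 - 676 - 516 = 16384 = 2^14 valid triplets.  Consequently no
#' triplet starts with 'E', and of the T-initial triplets only TTW..TZZ
#' survive.
#'
#' @return a [UnitCodec-class] with 16384 strings.
#' @examples
#' cardinality(tripletCodec())     # 16384
#' @export
tripletCodec <- function() {
  if (is.null(.layoutCache$triplet)) {
    L <- LETTERS
    all3 <- paste0(rep(L, each = 676), rep(rep(L, each = 26), 26),
                   rep(L, 676))
    keep <- !(all3 >= "EAA" & all3 <= "EZZ") &
      !(all3 >= "TAA" & all3 <= "TTV")
    .layoutCache$triplet <- unitCodec(all3[keep])
  }
  .layoutCache$triplet
}

#' The 512 valid doublets
#'
#' All 2-letter strings AA through TR in lexicographic order: 19 full
#' initial letters (A..S) of 26 doublets each plus TA..TR, giving
#' 19 x 26 + 18 = 512 = 2^9.  No doublet starts with U..Z.
#'
#' @return a [UnitCodec-class] with 512 strings.
#' @examples
#' cardinality(doubletCodec())     # 512
#' @export
doubletCodec <- function() {
  if (is.null(.layoutCache$doublet)) {
    L <- LETTERS
    all2 <- paste0(rep(L, each = 26), rep(L, 26))
    .layoutCache$doublet <- unitCodec(all2[all2 <= "TR"])
  }
  .layoutCache$doublet
}

.layoutCache <- new.env(parent = emptyenv())

#' Assemble a block layout from unit codecs
#'
#' @param units list of [UnitCodec-class] objects in block order.
#' @param alphabet letters the units draw from (defaults to the uppercase
#'   letters actually used).
#' @param totalBits `log2` of the number of valid blocks when that number
#'   is a power of two; `NA` for miniature layouts where it is not.
#' @return a [KeyLayout-class].
#' @export
keyLayout <- function(units, alphabet = LETTERS, totalBits = NA_real_) {
  new("KeyLayout", units = units, alphabet = alphabet,
      totalBits = as.numeric(totalBits))
}

#' The genuine first-block layout: 4 triplets + 1 doublet (65 bits)
#' @return a [KeyLayout-class] with 16384^4 x 512 = 2^65 valid 14-letter
#'   blocks.
#' @examples
#' block1Layout()
#' @export
block1Layout <- function() {
  t <- tripletCodec()
  keyLayout(list(t, t, t, t, doubletCodec()), totalBits = 65)
}

#' The genuine second-block layout: 2 triplets + 1 doublet (37 bits)
#' @return a [KeyLayout-class] with 16384^2 x 512 = 2^37 valid 8-letter
#'   blocks.
#' @examples
#' block2Layout()
#' @export
block2Layout <- function() {
  t <- tripletCodec()
  keyLayout(list(t, t, doubletCodec()), totalBits = 37)
}

## 1-based start position of each unit within the block
.unitStarts <- function(layout) {
  lens <- vapply(layout@units, unitLength, integer(1))
  cumsum(c(1L, lens))[seq_along(lens)]
}

#' Encode an integer as a block letter string
#'
#' Mixed-radix decomposition of `value` over the unit cardinalities, most
#' significant unit first; each digit is mapped through its codec's
#' lexicographic index.  This bit-assignment convention (leading hash bits
#' into the leading unit) is this package's emulation convention: the
#' statistical behaviour under study is invariant to which end of the hash
#' feeds which unit.
#'
#' Values up to 2^53 may be passed as numerics; larger values (the first
#' block runs to 2^65 - 1) are passed as decimal strings.
#'
#' @param value nonnegative integer as a numeric (`< 2^53`) or a decimal
#'   character string; must be less than the number of valid blocks.
#' @param layout a [KeyLayout-class].
#' @return the block letter string.
#' @examples
#' encodeBlock(0, block2Layout())                        # "AAAAAAAA"
#' encodeBlock("36893488147419103231", block1Layout())   # 2^65 - 1
#' @export
encodeBlock <- function(value, layout) {
  stopifnot(is(layout, "KeyLayout"))
  big <- if (is.character(value)) .bigFromDecimal(value)
  else .bigFromNumber(value)
  cards <- vapply(layout@units, cardinality, integer(1))
  idx <- integer(length(cards))
  for (u in rev(seq_along(cards))) {        # least significant unit last
    dm <- .bigDivmod(big, cards[u])
    idx[u] <- dm$remainder
    big <- dm$quotient
  }
  if (!.bigIsZero(big))
    stop("'value' is out of range for this layout (must be < ",
         "the number of valid blocks)")
  paste(vapply(seq_along(idx), function(u)
    layout@units[[u]]@validStrings[idx[u] + 1L], character(1)),
    collapse = "")
}

#' Decode a block letter string to its integer value
#'
#' Inverse of [encodeBlock()].  Each unit substring is looked up in its
#' codec; an invalid unit raises an error naming the unit and its letter
#' positions.
#'
#' @param letters block letter string of the layout's block length.
#' @param layout a [KeyLayout-class].
#' @return the block value: a numeric when below 2^53, otherwise a decimal
#'   character string.
#' @examples
#' decodeBlock("AAAAAAAB", block2Layout())   # 1
#' @export
decodeBlock <- function(letters, layout) {
  idx <- .blockToIndices(letters, layout)
  cards <- vapply(layout@units, cardinality, integer(1))
  big <- .bigFromNumber(0)
  for (u in seq_along(idx))
    big <- .bigMulAdd(big, cards[u], idx[u])
  v <- .bigToNumber(big)
  if (is.na(v)) .bigToDecimal(big) else v
}

## 0-based unit indices of a block string; errors carry position info
.blockToIndices <- function(letters, layout) {
  stopifnot(is.character(letters), length(letters) == 1L)
  blen <- blockLength(layout)
  if (nchar(letters) != blen)
    stop(sprintf("block must be %d letters, got %d", blen, nchar(letters)))
  starts <- .unitStarts(layout)
  idx <- integer(length(layout@units))
  for (u in seq_along(layout@units)) {
    codec <- layout@units[[u]]
    s <- substr(letters, starts[u], starts[u] + codec@unitLength - 1L)
    i <- match(s, codec@validStrings)
    if (is.na(i))
      stop(sprintf(
        "invalid unit '%s' at letters %d-%d (unit %d): not among the %d valid %d-letter units (%s..%s)",
        s, starts[u], starts[u] + codec@unitLength - 1L, u,
        cardinality(codec), codec@unitLength,
        codec@validStrings[1], codec@validStrings[cardinality(codec)]))
    idx[u] <- i - 1L
  }
  idx
}

## block string from 0-based unit index matrix (vectorized fast path)
.indicesToBlocks <- function(idx, layout) {
  cols <- lapply(seq_along(layout@units), function(u)
    layout@units[[u]]@validStrings[idx[, u] + 1L])
  .Call(C_concat_columns, cols)
}
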