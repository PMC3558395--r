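## Parsing and serializing full 27-character keys.

#' Parse a 27-character key
#'
#' Splits the serialized form
#' `AAAAAAAAAAAAAA-BBBBBBBBSA-N` (14-letter first block, dash, 8-letter
#' second block plus two flag letters, dash, protonation letter) and
#' validates that both blocks decompose into valid layout units.  Distinct
#' errors are raised for wrong length, misplaced dashes, non-letter
#' characters, and invalid units (the latter name the offending unit and
#' positions).  Flag letters are accepted as any uppercase letter; their
#' semantics (standard-key marker, version, protonation state) are not
#' interpreted.
#'
#' @param text a single 27-character string.
#' @return a [KeyRecord-class].
#' @examples
#' rec <- parseKey("BQJCRHHNABKAKU-KBQPJGBKSA-N")
#' block1(rec)
#' serializeKey(rec)
#' @export
parseKey <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (nchar(text) != 27L)
    stop(sprintf("key must be 27 characters, got %d", nchar(text)))
  if (substr(text, 15, 15) != "-" || substr(text, 26, 26) != "-")
    stop("dashes must sit at positions 15 and 26")
  b1 <- substr(text, 1, 14)
  b2 <- substr(text, 16, 23)
  flags <- substr(text, 24, 25)
  prot <- substr(text, 27, 27)
  if (!grepl("^[A-Z]+$", paste0(b1, b2, flags, prot)))
    stop("key characters outside the dashes must be uppercase letters")
  .blockToIndices(b1, block1Layout())   # validity; errors carry positions
  .blockToIndices(b2, block2Layout())
  new("KeyRecord", block1 = b1, block2 = b2,
      flagStandard = substr(flags, 1, 1),
      flagVersion = substr(flags, 2, 2),
      protonation = prot)
}

#' @describeIn KeyRecord-class serialize back to the 27-character form.
#' @export
setMethod("serializeKey", "KeyRecord", function(x) {
  paste0(x@block1, "-", x@block2, x@flagStandard, x@flagVersion, "-",
         x@protonation)
})
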