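## S4 classes for the collision-statistics machinery.

#' BirthdayModel: a uniform hash-output space
#'
#' Models a hash (or any assignment process) with `p` equally likely output
#' values.  All birthday-paradox quantities — expected same-hash pair
#' counts, collision probabilities, half-probability and half-expectation
#' dataset-size thresholds — are pure functions of `p`.
#'
#' `p` is stored as a double.  Powers of two up to 2^1023 and ordinary
#' integers (such as 365) are represented exactly; derived statistics carry
#' 15–16 significant digits, and the integer threshold searches use exact
#' double-double arithmetic so no threshold is ever off by one.
#'
#' @slot p numeric(1), number of equally likely hash outputs (`p >= 1`).
#' @slot bits numeric(1), hash width with `p = 2^bits`, or `NA` when the
#'   space is not hash-derived (e.g. 365 birthdays).
#'
#' @seealso [birthdayModel()], [expectedCollisions()],
#'   [collisionProbability()], [halfProbabilityThreshold()],
#'   [halfExpectationThreshold()]
#' @export
setClass("BirthdayModel",
         representation(p = "numeric", bits = "numeric"),
         prototype(p = 365, bits = NA_real_))

setValidity("BirthdayModel", function(object) {
  if (length(object@p) != 1L || is.na(object@p) || object@p < 1)
    return("'p' must be a single value >= 1")
  if (object@p != floor(object@p))
    return("'p' must be an integer-valued count of hash outputs")
  if (!is.na(object@bits)) {
    if (object@bits < 0 || object@bits != floor(object@bits))
      return("'bits' must be a nonnegative integer")
    if (object@p != 2^object@bits)
      return("'p' must equal 2^bits when 'bits' is set")
  }
  TRUE
})

#' UnitCodec: an ordered table of valid fixed-length letter units
#'
#' The InChIKey blocks are concatenations of 3-letter ("triplet") and
#' 2-letter ("doublet") units drawn from restricted, lexicographically
#' ordered tables: 16384 valid triplets and 512 valid doublets.  A codec is
#' that table plus the implied bijection between unit strings and their
#' 0-based lexicographic indices.  Miniature codecs over small alphabets
#' are constructible for exhaustive-enumeration oracles.
#'
#' @slot unitLength integer(1), letters per unit.
#' @slot validStrings character, the valid units in strict lexicographic
#'   order.
#'
#' @seealso [unitCodec()], [tripletCodec()], [doubletCodec()]
#' @export
setClass("UnitCodec",
         representation(unitLength = "integer", validStrings = "character"))

setValidity("UnitCodec", function(object) {
  s <- object@validStrings
  if (length(s) == 0L) return("codec must contain at least one valid string")
  if (anyNA(s)) return("valid strings must not contain NA")
  if (any(nchar(s) != object@unitLength))
    return("all valid strings must have length 'unitLength'")
  if (is.unsorted(s, strictly = TRUE))
    return("valid strings must be strictly increasing (sorted, no duplicates)")
  if (any(s != toupper(s)))
    return("valid strings must be uppercase")
  TRUE
})

#' KeyLayout: a block as an ordered sequence of unit codecs
#'
#' A block layout is an ordered list of [UnitCodec-class] units; a block
#' value is a mixed-radix number whose digits are unit indices, written
#' most-significant unit first.  The genuine first block is four triplets
#' plus a doublet (16384^4 x 512 = 2^65 valid 14-letter strings); the
#' second block is two triplets plus a doublet (16384^2 x 512 = 2^37 valid
#' 8-letter strings).
#'
#' @slot units list of [UnitCodec-class] objects, in block order.
#' @slot alphabet character, the letters the units draw from (26 uppercase
#'   letters for the genuine layouts; smaller for miniature test layouts).
#' @slot totalBits numeric(1), `log2` of the product of unit cardinalities
#'   when that product is a power of two, otherwise `NA`.
#'
#' @seealso [keyLayout()], [block1Layout()], [block2Layout()],
#'   [encodeBlock()], [decodeBlock()]
#' @export
setClass("KeyLayout",
         representation(units = "list", alphabet = "character",
                        totalBits = "numeric"))

setValidity("KeyLayout", function(object) {
  if (length(object@units) == 0L) return("layout needs at least one unit")
  if (!all(vapply(object@units, is, logical(1), "UnitCodec")))
    return("'units' must all be UnitCodec objects")
  letters_used <- unique(strsplit(paste(unlist(lapply(object@units, slot,
                                                      "validStrings")),
                                        collapse = ""), "")[[1]])
  if (!all(letters_used %in% object@alphabet))
    return("unit strings use letters outside the layout alphabet")
  if (!is.na(object@totalBits)) {
    lb <- sum(log2(vapply(object@units, function(u)
      length(u@validStrings), numeric(1))))
    if (abs(lb - object@totalBits) > 1e-9)
      return("product of unit cardinalities must equal 2^totalBits")
  }
  TRUE
})

#' KeyRecord: a parsed 27-character key
#'
#' Holds the five fields of a key: 14-letter first (skeleton) block,
#' 8-letter second (isomer-layer) block, standard-key flag, version flag,
#' and protonation character.  The serialized form is
#' `block1 + "-" + block2 + flags + "-" + protonation`, 27 characters.
#'
#' @slot block1 character(1), 14 uppercase letters.
#' @slot block2 character(1), 8 uppercase letters.
#' @slot flagStandard character(1), one uppercase letter.
#' @slot flagVersion character(1), one uppercase letter.
#' @slot protonation character(1), one uppercase letter.
#'
#' @seealso [parseKey()], [serializeKey()], [makeKey()]
#' @export
setClass("KeyRecord",
         representation(block1 = "character", block2 = "character",
                        flagStandard = "character", flagVersion = "character",
                        protonation = "character"))

setValidity("KeyRecord", function(object) {
  one_letter <- function(x) length(x) == 1L && !is.na(x) &&
    nchar(x) == 1L && grepl("^[A-Z]$", x)
  if (length(object@block1) != 1L || !grepl("^[A-Z]{14}$", object@block1))
    return("'block1' must be 14 uppercase letters")
  if (length(object@block2) != 1L || !grepl("^[A-Z]{8}$", object@block2))
    return("'block2' must be 8 uppercase letters")
  for (f in c("flagStandard", "flagVersion", "protonation"))
    if (!one_letter(slot(object, f)))
      return(sprintf("'%s' must be a single uppercase letter", f))
  TRUE
})

#' CollisionCount: pair count and duplicate count of a hash multiset
#'
#' Two related but distinct collision statistics for a set of hash values:
#' the number of same-hash pairs \eqn{X = \sum_v \binom{n_v}{2}} (the
#' quantity the birthday expectation \eqn{k(k-1)/2p} predicts) and the
#' duplicate count \eqn{N - \#distinct} ("already seen" values).  They are
#' equal exactly when no value occurs three or more times (no composite
#' collisions).
#'
#' @slot pairCount numeric(1), number of same-hash pairs.
#' @slot duplicateCount numeric(1), inputs minus distinct values.
#'
#' @seealso [countCollisions()], [pairCount()], [duplicateCount()]
#' @export
setClass("CollisionCount",
         representation(pairCount = "numeric", duplicateCount = "numeric"))

setValidity("CollisionCount", function(object) {
  if (object@pairCount < 0 || object@duplicateCount < 0)
    return("counts must be nonnegative")
  if (object@duplicateCount > object@pairCount)
    return("duplicate count can never exceed pair count")
  TRUE
})

#' ExperimentResult: a (k, m, seed) collision subsampling experiment
#'
#' Result of drawing `m` independent uniform size-`k` subsets of a hash
#' population, counting same-hash pairs in each, and comparing the mean to
#' the birthday expectation \eqn{D(k) = k(k-1)/2p}.
#'
#' @slot k numeric(1), subset size.
#' @slot m numeric(1), number of repetitions.
#' @slot seed numeric(1), root seed of the sampling plan.
#' @slot populationSize numeric(1), size of the sampled population.
#' @slot meanCollisions numeric(1), mean pair count over the `m` subsets.
#' @slot meanDuplicates numeric(1), mean duplicate count over the subsets.
#' @slot histogram numeric, named vector: how many of the `m` datasets had
#'   0, 1, 2, ... pair collisions.
#' @slot theory numeric(1), \eqn{k(k-1)/2p} for the model the experiment
#'   was run against.
#' @slot runningMeans numeric, mean pair count after 1..m repetitions.
#'
#' @seealso [runSamplingExperiment()]
#' @export
setClass("ExperimentResult",
         representation(k = "numeric", m = "numeric", seed = "numeric",
                        populationSize = "numeric",
                        meanCollisions = "numeric", meanDuplicates = "numeric",
                        histogram = "numeric", theory = "numeric",
                        runningMeans = "numeric"))

setValidity("ExperimentResult", function(object) {
  if (sum(object@histogram) != object@m)
    return("histogram frequencies must sum to m")
  counts <- as.numeric(names(object@histogram))
  if (anyNA(counts)) return("histogram names must be collision counts")
  if (abs(sum(counts * object@histogram) / object@m -
          object@meanCollisions) > 1e-8 * max(1, object@meanCollisions))
    return("histogram mean must equal meanCollisions")
  TRUE
})

#' FrequencyMatrix: positional letter counts over a key corpus
#'
#' A letters-by-positions count matrix for the first block of a set of
#' keys: entry (L, j) is how many keys carry letter L at block position j.
#' Each column sums to the number of well-formed keys counted.
#'
#' @slot counts numeric matrix, `length(alphabet)` rows by block-length
#'   columns, dimnames letters x positions.
#' @slot nKeys numeric(1), number of keys counted.
#' @slot nMalformed numeric(1), inputs excluded because they failed to
#'   parse.
#' @slot referenceLetter character(1), the letter used by
#'   [normalizedFrequencies()] (the paper-standard choice is "A").
#'
#' @seealso [letterPositionFrequencies()], [normalizedFrequencies()],
#'   [inferUnitBoundaries()]
#' @export
setClass("FrequencyMatrix",
         representation(counts = "matrix", nKeys = "numeric",
                        nMalformed = "numeric", referenceLetter = "character"))

setValidity("FrequencyMatrix", function(object) {
  if (object@nKeys > 0 &&
      any(abs(colSums(object@counts) - object@nKeys) > 0))
    return("every column must sum to nKeys")
  if (!(object@referenceLetter %in% rownames(object@counts)))
    return("referenceLetter must be a row of the count matrix")
  TRUE
})
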