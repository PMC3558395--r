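## Generics and accessors.

#' @rdname UnitCodec-class
#' @param object,x an object.
#' @export
setGeneric("cardinality", function(x) standardGeneric("cardinality"))

#' @rdname UnitCodec-class
#' @export
setGeneric("validStrings", function(x) standardGeneric("validStrings"))

#' @rdname UnitCodec-class
#' @export
setGeneric("unitLength", function(x) standardGeneric("unitLength"))

#' @rdname KeyLayout-class
#' @export
setGeneric("layoutUnits", function(x) standardGeneric("layoutUnits"))

#' @rdname KeyLayout-class
#' @export
setGeneric("blockLength", function(x) standardGeneric("blockLength"))

#' @rdname KeyLayout-class
#' @export
setGeneric("totalBits", function(x) standardGeneric("totalBits"))

#' @rdname CollisionCount-class
#' @export
setGeneric("pairCount", function(x) standardGeneric("pairCount"))

#' @rdname CollisionCount-class
#' @export
setGeneric("duplicateCount", function(x) standardGeneric("duplicateCount"))

#' @rdname ExperimentResult-class
#' @export
setGeneric("meanCollisions", function(x) standardGeneric("meanCollisions"))

#' @rdname ExperimentResult-class
#' @export
setGeneric("collisionHistogram", function(x) standardGeneric("collisionHistogram"))

#' @rdname ExperimentResult-class
#' @export
setGeneric("theoryValue", function(x) standardGeneric("theoryValue"))

#' @rdname ExperimentResult-class
#' @export
setGeneric("runningMeans", function(x) standardGeneric("runningMeans"))

#' @rdname KeyRecord-class
#' @export
setGeneric("serializeKey", function(x) standardGeneric("serializeKey"))

#' @rdname KeyRecord-class
#' @export
setGeneric("block1", function(x) standardGeneric("block1"))

#' @rdname KeyRecord-class
#' @export
setGeneric("block2", function(x) standardGeneric("block2"))

## -- accessors ---------------------------------------------------------

#' @rdname UnitCodec-class
#' @export
setMethod("cardinality", "UnitCodec", function(x) length(x@validStrings))

#' @rdname UnitCodec-class
#' @export
setMethod("validStrings", "UnitCodec", function(x) x@validStrings)

#' @rdname UnitCodec-class
#' @export
setMethod("unitLength", "UnitCodec", function(x) x@unitLength)

#' @rdname KeyLayout-class
#' @export
setMethod("layoutUnits", "KeyLayout", function(x) x@units)

#' @rdname KeyLayout-class
#' @export
setMethod("blockLength", "KeyLayout",
          function(x) sum(vapply(x@units, unitLength, integer(1))))

#' @rdname KeyLayout-class
#' @export
setMethod("totalBits", "KeyLayout", function(x) x@totalBits)

#' @rdname CollisionCount-class
#' @export
setMethod("pairCount", "CollisionCount", function(x) x@pairCount)

#' @rdname CollisionCount-class
#' @export
setMethod("duplicateCount", "CollisionCount", function(x) x@duplicateCount)

#' @rdname ExperimentResult-class
#' @export
setMethod("meanCollisions", "ExperimentResult", function(x) x@meanCollisions)

#' @rdname ExperimentResult-class
#' @export
setMethod("collisionHistogram", "ExperimentResult", function(x) x@histogram)

#' @rdname ExperimentResult-class
#' @export
setMethod("theoryValue", "ExperimentResult", function(x) x@theory)

#' @rdname ExperimentResult-class
#' @export
setMethod("runningMeans", "ExperimentResult", function(x) x@runningMeans)

#' @rdname KeyRecord-class
#' @export
setMethod("block1", "KeyRecord", function(x) x@block1)

#' @rdname KeyRecord-class
#' @export
setMethod("block2", "KeyRecord", function(x) x@block2)

## -- show methods ------------------------------------------------------

setMethod("show", "BirthdayModel", function(object) {
  cat("BirthdayModel:", if (!is.na(object@bits))
    sprintf("p = 2^%d = %.6g", object@bits, object@p)
    else sprintf("p = %.6g", object@p), "equally likely hash outputs\n")
})

setMethod("show", "UnitCodec", function(object) {
  s <- object@validStrings
  cat(sprintf("UnitCodec: %d valid %d-letter units (%s .. %s)\n",
              length(s), object@unitLength, s[1], s[length(s)]))
})

setMethod("show", "KeyLayout", function(object) {
  cards <- vapply(object@units, cardinality, integer(1))
  cat(sprintf("KeyLayout: %d letters = %s; %s valid blocks%s\n",
              blockLength(object),
              paste(vapply(object@units, unitLength, integer(1)),
                    collapse = "+"),
              paste(cards, collapse = " x "),
              if (!is.na(object@totalBits))
                sprintf(" = 2^%d", object@totalBits) else ""))
})

setMethod("show", "KeyRecord", function(object) {
  cat("KeyRecord:", serializeKey(object), "\n")
})

setMethod("show", "CollisionCount", function(object) {
  cat(sprintf("CollisionCount: %g same-hash pairs, %g duplicates\n",
              object@pairCount, object@duplicateCount))
})

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf(
    "ExperimentResult: k = %g, m = %g (population %g)\n  mean pair collisions %.4f vs theory %.4f\n",
    object@k, object@m, object@populationSize,
    object@meanCollisions, object@theory))
  h <- object@histogram
  cat("  histogram:", paste(sprintf("%s:%g", names(h), h), collapse = " "),
      "\n")
})

setMethod("show", "FrequencyMatrix", function(object) {
  cat(sprintf(
    "FrequencyMatrix: %d letters x %d positions over %g keys (%g malformed excluded)\n",
    nrow(object@counts), ncol(object@counts), object@nKeys,
    object@nMalformed))
})
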