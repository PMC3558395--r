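## Deterministic synthetic identifier strings.
##
## The statistics under study depend only on the inputs being distinct
## canonical strings (the uniform-hash hypothesis); these generators emit
## InChI-flavoured text that is deliberately NOT claimed to be valid
## InChI.  Two populations are emulated: the full stereoisomer set of a
## skeleton with n binary stereogenic elements (2^n distinct isomer
## layers over one fixed skeleton part), and large sets of distinct
## skeletons standing in for a constitutional-isomer generator.
## Tautomer-style duplication cannot occur by construction: every string
## embeds a distinct counter or bitmask.

#' Describe a stereoisomer skeleton
#'
#' @param skeletonId label for the skeleton (free text, no "|").
#' @param nStereo number of binary stereogenic elements (tetrahedral
#'   centers plus stereogenic double bonds), 0..40.  The flagship
#'   spongistatin-like case has 24 + 2 = 26 elements and hence
#'   2^26 = 67,108,864 stereoisomers.
#' @param formulaTag free-text stand-in for a molecular formula.
#' @return a list of class `"SkeletonSpec"`.
#' @examples
#' skeletonSpec("spongistatin-like", nStereo = 26)
#' @export
skeletonSpec <- function(skeletonId = "skeleton", nStereo,
                         formulaTag = "C49H74O17") {
  stopifnot(length(nStereo) == 1L, nStereo >= 0, nStereo <= 40,
            nStereo == floor(nStereo))
  if (grepl("|", skeletonId, fixed = TRUE) ||
      grepl("|", formulaTag, fixed = TRUE))
    stop("'|' is the reserved part separator and may not appear in labels")
  structure(list(skeletonId = skeletonId, nStereo = as.integer(nStereo),
                 formulaTag = formulaTag),
            class = "SkeletonSpec")
}

## the fixed skeleton part of every isomer identifier of a spec
.skeletonPart <- function(spec) {
  paste0("SYN=1S/", spec$formulaTag, "/c", spec$skeletonId)
}

## isomer layers for bitmask values [from, from + n)
.isomerLayers <- function(spec, from, n) {
  .Call(C_stereo_layers, spec$nStereo, as.numeric(from), as.numeric(n))
}

#' Enumerate stereoisomer identifier strings
#'
#' Yields `min(2^nStereo, limit)` distinct identifier strings, ordered by
#' configuration bitmask.  Each string is the fixed skeleton part, the
#' reserved separator `"|"`, and a sign-pattern isomer layer
#' (`"1+,2-,..."`) mimicking an InChI stereo layer; bit `i` of the bitmask
#' sets the sign of element `i`, so any two strings differ.  The split
#' into skeleton part and isomer part is lossless: `"|"` never occurs
#' inside either part.
#'
#' Enumerating all 2^26 flagship isomers as strings needs several
#' gigabytes; without `limit` the function refuses counts above
#' `maxMaterialize` and reports the size.  Large populations are meant to
#' be streamed through [hashStereoPopulation()], which retains only the
#' packed truncated hashes.
#'
#' @param spec a [skeletonSpec()].
#' @param limit maximum number of isomers to yield (`NULL` for all).
#' @param from first configuration bitmask (0-based; for chunked
#'   streaming).
#' @param maxMaterialize refusal threshold for unlimited enumeration.
#' @return character vector of identifier strings.
#' @examples
#' enumerateStereoisomers(skeletonSpec("demo", 2))
#' @export
enumerateStereoisomers <- function(spec, limit = NULL, from = 0,
                                   maxMaterialize = 2^22) {
  stopifnot(inherits(spec, "SkeletonSpec"))
  total <- 2^spec$nStereo
  n <- max(0, total - from)
  if (is.null(limit)) {
    if (n > maxMaterialize)
      stop(sprintf(
        "full enumeration would materialize %.0f strings; pass 'limit' or stream via hashStereoPopulation()",
        n))
  } else {
    n <- min(n, limit)
  }
  if (n == 0) return(character(0))
  paste0(.skeletonPart(spec), "|", .isomerLayers(spec, from, n))
}

#' Generate a population of distinct skeleton identifier strings
#'
#' Stand-in for a constitutional-isomer structure generator: `count`
#' distinct skeleton identifier strings, deterministic given `seed`.  The
#' seed is embedded in the string body (not used to drive an RNG), so the
#' same `(count, seed)` always yields the identical stream and different
#' seeds yield disjoint populations; distinctness is by counter injection.
#' Downstream SHA-256 hashes of such strings are effectively uniform.
#'
#' @param count number of strings (`>= 0`).
#' @param seed integer tag making populations disjoint.
#' @param formulaTag free-text stand-in for the molecular formula fed to
#'   the generator.
#' @param from 0-based index of the first string (for chunked streaming).
#' @return character vector of `count` identifier strings.
#' @examples
#' generateSkeletonPopulation(3, seed = 1)
#' @export
generateSkeletonPopulation <- function(count, seed = 1L,
                                       formulaTag = "C8H8Cl3F5",
                                       from = 0) {
  stopifnot(length(count) == 1L, count >= 0, count == floor(count))
  if (count == 0) return(character(0))
  .Call(C_counter_strings,
        sprintf("SYN=1S/%s/s%d/c", formulaTag, as.integer(seed)),
        "", as.numeric(from), as.numeric(count))
}

#' Split an identifier into skeleton part and isomer part
#'
#' @param identifiers character vector of identifier strings.
#' @return a list with character vectors `skeleton` and `isomer` (empty
#'   string when an identifier has no isomer layer).
#' @export
splitIdentifier <- function(identifiers) {
  sep <- regexpr("|", identifiers, fixed = TRUE)
  skel <- ifelse(sep > 0, substr(identifiers, 1L, sep - 1L), identifiers)
  iso <- ifelse(sep > 0, substr(identifiers, sep + 1L,
                                nchar(identifiers)), "")
  list(skeleton = skel, isomer = iso)
}
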