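# Miniature layouts and brute-force oracles shared across tests.
#
# The miniature layout mirrors the genuine one structurally (range-excluded
# unit tables, a terminal shorter unit) but is small enough that every valid
# block can be enumerated, so probability and counting code can be checked
# exhaustively.

miniAlphabet <- c("A", "B", "C", "D")

# 48 valid mini-triplets: all AAA..DDD over {A..D} minus BAA..BDD
miniTripletCodec <- function() {
  g <- expand.grid(miniAlphabet, miniAlphabet, miniAlphabet,
                   stringsAsFactors = FALSE)
  all3 <- sort(paste0(g[, 3], g[, 2], g[, 1]))
  unitCodec(all3[!(all3 >= "BAA" & all3 <= "BDD")])
}

# 12 valid mini-doublets: AA..DD minus the D-initial ones
miniDoubletCodec <- function() {
  g <- expand.grid(miniAlphabet, miniAlphabet, stringsAsFactors = FALSE)
  all2 <- sort(paste0(g[, 2], g[, 1]))
  unitCodec(all2[all2 < "DA"])
}

# 48 x 48 x 12 = 27648 valid 8-letter blocks; pass units to vary the shape
miniLayout <- function(units = NULL) {
  if (is.null(units)) {
    t <- miniTripletCodec()
    units <- list(t, t, miniDoubletCodec())
  }
  keyLayout(units, alphabet = miniAlphabet)
}

# every valid block of a (small) layout, lexicographic by unit indices
enumerateAllBlocks <- function(layout) {
  tabs <- lapply(layoutUnits(layout), validStrings)
  g <- do.call(expand.grid,
               c(rev(tabs), list(stringsAsFactors = FALSE)))
  do.call(paste0, rev(g))
}

# O(n^2) all-pairs collision oracle
bruteForcePairCount <- function(x) {
  (sum(outer(x, x, "==")) - length(x)) / 2
}

bruteForceDuplicateCount <- function(x) length(x) - length(unique(x))
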