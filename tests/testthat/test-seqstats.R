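# Positional letter statistics and the sequence-probability calculus.

test_that("position frequencies count exactly and report malformed input", {
  one <- strrep("A", 14)
  fm <- letterPositionFrequencies(one)
  expect_identical(unname(fm@counts["A", ]), rep(1, 14))
  expect_identical(sum(fm@counts), 14)

  fm2 <- letterPositionFrequencies(c(one, "TOOSHORT"))
  expect_equal(fm2@nKeys, 1)
  expect_equal(fm2@nMalformed, 1)

  # accepts full 27-character keys too
  keys <- forgeKeys(generateSkeletonPopulation(500, seed = 2))
  fm3 <- letterPositionFrequencies(keys)
  expect_equal(fm3@nKeys, 500)
  expect_identical(unname(colSums(fm3@counts)), rep(500, 14))
})

test_that("layout exclusions show up as exact zeros in the counts", {
  keys <- forgeKeys(generateSkeletonPopulation(5e4, seed = 8))
  fm <- letterPositionFrequencies(keys)
  expect_identical(unname(fm@counts["E", c(1, 4, 7, 10)]), rep(0, 4))
  expect_identical(sum(fm@counts[c("U", "V", "W", "X", "Y", "Z"), 13]), 0)
  # but E does occur at non-start triplet positions
  expect_gt(fm@counts["E", 2], 0)
})

test_that("normalization follows the classic conventions", {
  keys <- forgeKeys(generateSkeletonPopulation(5e4, seed = 8))
  fm <- letterPositionFrequencies(keys)
  nf <- normalizedFrequencies(fm)
  expect_identical(nf["A", 1], 1)
  # doublet-start enrichment of A relative to triplet starts
  expect_equal(nf["A", 13], (26 / 512) / (676 / 16384), tolerance = 0.1)
  nb <- normalizedFrequencies(fm, by = "block")
  expect_identical(unname(nb["A"]), 1)
  expect_lt(nb["E"], 0.8)   # E is barred from 4 of 14 positions
})

test_that("the flagship window probability decomposes across units", {
  expect_equal(signif(sequenceProbabilityAt("ABCD", 1), 5), 2.5183e-6)
  expect_identical(sequenceProbabilityAt("ABCD", 1),
                   (1 / 16384) * (676 / 16384))
  expect_identical(sequenceProbabilityAt("EZZ", 1), 0)
  # any non-E/T letter opens 676 of the 16384 triplets
  for (L in c("A", "K", "Z"))
    expect_identical(sequenceProbabilityAt(L, 4), 676 / 16384)
  expect_identical(sequenceProbabilityAt("T", 1), 160 / 16384)
  expect_identical(sequenceProbabilityAt("U", 13), 0)
  expect_error(sequenceProbabilityAt("ABCD", 12), "exceeds")
})

test_that("per-position probabilities are a distribution (s = 1, 2)", {
  b1 <- block1Layout()
  for (s in 1:2) {
    qs <- do.call(paste0, rev(expand.grid(rep(list(LETTERS), s),
                                          stringsAsFactors = FALSE)))
    for (pos in c(1, 2, 3, 12, 13, 14 - s + 1)) {
      tot <- sum(vapply(qs, sequenceProbabilityAt, numeric(1),
                        start = pos, layout = b1))
      expect_equal(tot, 1)
    }
  }
})

test_that("total sequence probability reproduces the published calculus", {
  expect_equal(signif(sequenceProbability("ABCD"), 5), 2.7530e-5)
  expect_equal(signif(sequenceProbability("EDNA"), 5), 1.6876e-5)
  expect_equal(signif(sequenceProbability("TBAC"), 5), 1.6876e-5)
  expect_equal(signif(sequenceProbability("ZAMR"), 5), 2.7951e-5)
  n <- 1.2002e9
  expect_identical(round(expectedOccurrences("ABCD", n)), 33041)
  expect_identical(round(expectedOccurrences("EDNA", n)), 20254)
  expect_identical(round(expectedOccurrences("ZAMR", n)), 33547)
})

test_that("miniature-layout probabilities match exhaustive enumeration", {
  ml <- miniLayout()
  blocks <- enumerateAllBlocks(ml)
  nb <- length(blocks)
  set.seed(31)
  for (q in 1:50) {
    w <- sample(1:4, 1)
    letters <- paste(sample(miniAlphabet, w, replace = TRUE),
                     collapse = "")
    # fixed-position probability vs exact share of blocks carrying it
    s <- sample.int(blockLength(ml) - w + 1L, 1)
    exact <- mean(substr(blocks, s, s + w - 1L) == letters)
    expect_equal(sequenceProbabilityAt(letters, s, ml), exact)
    # expected occurrences vs exact overlapping-occurrence count
    exactTotal <- sum(stringi::stri_count_fixed(blocks, letters,
                                                overlap = TRUE))
    expect_equal(expectedOccurrences(letters, nb, ml), exactTotal)
  }
})

test_that("window conservation holds exhaustively on the miniature layout", {
  ml <- miniLayout()
  for (s in 1:2) {
    qs <- do.call(paste0, rev(expand.grid(rep(list(miniAlphabet), s),
                                          stringsAsFactors = FALSE)))
    tot <- sum(vapply(qs, sequenceProbability, numeric(1), layout = ml))
    expect_equal(tot, blockLength(ml) - s + 1)   # one unit mass per window
  }
})

test_that("observed occurrences use the per-start-position convention", {
  # overlapping self-occurrences count once per start position
  expect_identical(observedOccurrences("ABABABABABABAB", "ABAB"), 6L)
  keys <- forgeKeys(generateSkeletonPopulation(2e4, seed = 12))
  obs <- observedOccurrences(keys, "AB")
  exp_ <- expectedOccurrences("AB", 2e4)
  expect_lt(abs(obs - exp_), 5 * sqrt(exp_))
})

test_that("unit boundaries are recovered from forged keys", {
  keys <- forgeKeys(generateSkeletonPopulation(1e5, seed = 21))
  fm <- letterPositionFrequencies(keys)
  bounds <- inferUnitBoundaries(fm)
  expect_identical(as.integer(bounds), c(1L, 4L, 7L, 10L, 13L))
  expect_true(attr(bounds, "conclusive"))
  # a tiny corpus cannot resolve the pattern and must say so
  tiny <- letterPositionFrequencies(forgeKeys(
    generateSkeletonPopulation(20, seed = 1)))
  expect_warning(inferUnitBoundaries(tiny), "inconclusive")
})
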