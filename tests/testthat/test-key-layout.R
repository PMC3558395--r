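# Unit codecs, block layouts, mixed-radix encode/decode, key parsing.

test_that("triplet codec excludes exactly the two forbidden ranges", {
  tc <- tripletCodec()
  expect_identical(cardinality(tc), 16384L)
  expect_identical(26^3 - 676 - 516, 16384)   # EAA..EZZ and TAA..TTV
  s <- validStrings(tc)
  expect_identical(s[1], "AAA")
  expect_identical(s[16384], "ZZZ")
  expect_false(any(s >= "EAA" & s <= "EZZ"))
  expect_false(any(s >= "TAA" & s <= "TTV"))
  expect_false("EAB" %in% s)
  expect_false("TTV" %in% s)
  expect_true("TTW" %in% s)
  expect_true("DZZ" %in% s)
  # no triplet starts with E; only TTW..TZZ keep a leading T
  expect_identical(sum(startsWith(s, "E")), 0L)
  expect_identical(sum(startsWith(s, "T")), 160L)
})

test_that("doublet codec is AA..TR", {
  dc <- doubletCodec()
  expect_identical(cardinality(dc), 512L)
  expect_identical(19 * 26 + 18, 512)
  s <- validStrings(dc)
  expect_true("TR" %in% s)
  expect_false("TS" %in% s)
  expect_false("UA" %in% s)
  expect_identical(sum(substr(s, 1, 1) %in% c("U", "V", "W", "X", "Y", "Z")),
                   0L)
})

test_that("block layouts multiply out to exact powers of two", {
  b1 <- block1Layout()
  b2 <- block2Layout()
  cards1 <- sapply(layoutUnits(b1), cardinality)
  cards2 <- sapply(layoutUnits(b2), cardinality)
  expect_identical(sum(log2(cards1)), 65)      # 16384^4 * 512 = 2^65
  expect_identical(sum(log2(cards2)), 37)      # 16384^2 * 512 = 2^37
  expect_identical(blockLength(b1), 14L)
  expect_identical(blockLength(b2), 8L)
  # 26^14 > 2^65: some 14-letter strings can never be a valid first block
  expect_gt(14 * log2(26), 65)
})

test_that("encode/decode hit the range endpoints", {
  b1 <- block1Layout()
  b2 <- block2Layout()
  expect_identical(encodeBlock(0, b1), strrep("A", 14))
  expect_identical(encodeBlock(0, b2), strrep("A", 8))
  expect_identical(encodeBlock("36893488147419103231", b1),  # 2^65 - 1
                   "ZZZZZZZZZZZZTR")
  expect_identical(decodeBlock("ZZZZZZZZZZZZTR", b1),
                   "36893488147419103231")
  expect_identical(decodeBlock(paste0(strrep("A", 6), "TR"), b2), 511)
  expect_error(encodeBlock(2^37, b2), "out of range")
  expect_error(encodeBlock("36893488147419103232", b1), "out of range")
})

test_that("decode agrees with direct mixed-radix arithmetic", {
  b2 <- block2Layout()
  trip <- validStrings(tripletCodec())
  doub <- validStrings(doubletCodec())
  set.seed(7)
  for (i in 1:50) {
    i1 <- sample.int(16384, 1) - 1
    i2 <- sample.int(16384, 1) - 1
    i3 <- sample.int(512, 1) - 1
    block <- paste0(trip[i1 + 1], trip[i2 + 1], doub[i3 + 1])
    expect_identical(decodeBlock(block, b2), (i1 * 16384 + i2) * 512 + i3)
  }
})

test_that("encode and decode are mutual inverses on random values", {
  b1 <- block1Layout()
  b2 <- block2Layout()
  set.seed(11)
  v2 <- floor(runif(5000) * 2^37)
  for (v in v2) expect_identical(decodeBlock(encodeBlock(v, b2), b2), v)
  # 65-bit values survive the decimal-string route
  trip <- validStrings(tripletCodec())
  doub <- validStrings(doubletCodec())
  blocks <- paste0(trip[sample.int(16384, 5000, TRUE)],
                   trip[sample.int(16384, 5000, TRUE)],
                   trip[sample.int(16384, 5000, TRUE)],
                   trip[sample.int(16384, 5000, TRUE)],
                   doub[sample.int(512, 5000, TRUE)])
  for (b in blocks[1:200]) {
    v <- decodeBlock(b, b1)
    expect_identical(encodeBlock(v, b1), b)
  }
})

test_that("decode names the offending unit and positions", {
  expect_error(decodeBlock("AAAEAAAAAAAAAA", block1Layout()),
               "invalid unit 'EAA' at letters 4-6")
  expect_error(decodeBlock("AAAAAAUS", block2Layout()),
               "invalid unit 'US' at letters 7-8")
  expect_error(decodeBlock("AAAA", block2Layout()), "must be 8 letters")
})

test_that("miniature layouts satisfy the same structural invariants", {
  ml <- miniLayout()
  cards <- sapply(layoutUnits(ml), cardinality)
  expect_identical(cards, c(48L, 48L, 12L))
  expect_identical(blockLength(ml), 8L)
  blocks <- enumerateAllBlocks(ml)
  expect_identical(length(blocks), as.integer(prod(cards)))
  expect_false(anyDuplicated(blocks) > 0)
  # encode is a bijection onto the enumeration, in index order
  set.seed(3)
  for (v in sample(prod(cards), 100) - 1)
    expect_identical(decodeBlock(encodeBlock(v, ml), ml), v)
})

test_that("parseKey validates structure and roundtrips", {
  key <- "BQJCRHHNABKAKU-KBQPJGBKSA-N"
  rec <- parseKey(key)
  expect_s4_class(rec, "KeyRecord")
  expect_identical(serializeKey(rec), key)
  expect_identical(block1(rec), "BQJCRHHNABKAKU")
  expect_identical(block2(rec), "KBQPJGBK")
  expect_error(parseKey(substr(key, 1, 26)), "27 characters")
  expect_error(parseKey(sub("-K", "K-", key)), "dashes")
  # no valid first block starts with E
  expect_error(parseKey(sub("^B", "E", key)), "invalid unit")
  expect_error(parseKey(tolower(key)), "uppercase|dashes")
})
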