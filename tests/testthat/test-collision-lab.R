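# Exact collision counting and the subsampling experiment engine.

test_that("pair count and duplicate count are kept distinct", {
  cc <- countCollisions(c(5, 5, 9))
  expect_identical(pairCount(cc), 1)
  expect_identical(duplicateCount(cc), 1)
  # a composite collision: three inputs on one hash = 3 pairs, 2 duplicates
  cc3 <- countCollisions(c(5, 5, 5))
  expect_identical(pairCount(cc3), 3)
  expect_identical(duplicateCount(cc3), 2)
  cc0 <- countCollisions(c(1, 2, 3, 4))
  expect_identical(pairCount(cc0), 0)
  expect_identical(duplicateCount(cc0), 0)
  expect_identical(pairCount(countCollisions(numeric(0))), 0)
})

test_that("counting is exact against the all-pairs oracle", {
  set.seed(101)
  for (trial in 1:100) {
    n <- sample(2:2000, 1)
    x <- sample.int(max(2, n %/% sample(1:5, 1)), n, replace = TRUE)
    cc <- countCollisions(x)
    expect_identical(pairCount(cc), bruteForcePairCount(x))
    expect_identical(duplicateCount(cc),
                     as.numeric(bruteForceDuplicateCount(x)))
  }
})

test_that("counting is invariant under permutation", {
  set.seed(5)
  x <- sample.int(500, 1000, replace = TRUE)
  cc1 <- countCollisions(x)
  cc2 <- countCollisions(sample(x))
  expect_identical(pairCount(cc1), pairCount(cc2))
  expect_identical(duplicateCount(cc1), duplicateCount(cc2))
})

# a 2^14-isomer population in a 22-bit space: dense enough (~32 colliding
# pairs) that the experiment engine sees real collisions at small scale
popLab <- hashStereoPopulation(skeletonSpec("lab", 14), bits = 22)
m22 <- birthdayModel(bits = 22)

test_that("sampling the whole population gives a degenerate histogram", {
  res <- runSamplingExperiment(popLab, k = length(popLab), m = 20,
                               seed = 1, model = m22)
  expect_length(collisionHistogram(res), 1L)
  expect_identical(meanCollisions(res), pairCount(countCollisions(popLab)))
})

test_that("experiments are deterministic in the seed and reject bad k", {
  r1 <- runSamplingExperiment(popLab, k = 5000, m = 50, seed = 42,
                              model = m22)
  r2 <- runSamplingExperiment(popLab, k = 5000, m = 50, seed = 42,
                              model = m22)
  expect_identical(meanCollisions(r1), meanCollisions(r2))
  expect_identical(collisionHistogram(r1), collisionHistogram(r2))
  r3 <- runSamplingExperiment(popLab, k = 5000, m = 50, seed = 43,
                              model = m22)
  expect_false(identical(runningMeans(r1), runningMeans(r3)))
  expect_error(runSamplingExperiment(popLab, k = length(popLab) + 1,
                                     m = 1), "exceeds")
})

test_that("mean collisions are invariant under population permutation", {
  set.seed(2)
  shuffled <- sample(popLab)
  r1 <- runSamplingExperiment(popLab, k = length(popLab), m = 5, seed = 9,
                              model = m22)
  r2 <- runSamplingExperiment(shuffled, k = length(popLab), m = 5,
                              seed = 9, model = m22)
  expect_identical(meanCollisions(r1), meanCollisions(r2))
})

test_that("observed means track the birthday expectation", {
  N <- length(popLab)
  k <- 4000
  res <- runSamplingExperiment(popLab, k = k, m = 400, seed = 42,
                               model = m22)
  expect_equal(theoryValue(res), expectedCollisions(k, m22))
  # conditional on this finite population, the sample mean targets
  # popPairs * (k/N) * ((k-1)/(N-1)); popPairs itself is Poisson around
  # C(N,2)/p, which is what D(k) summarizes
  popPairs <- pairCount(countCollisions(popLab))
  condMean <- popPairs * (k / N) * ((k - 1) / (N - 1))
  expect_lt(abs(meanCollisions(res) - condMean),
            4 * sqrt(max(condMean, 0.01) / 400))
  expect_equal(condMean / theoryValue(res), 1, tolerance = 1)
  # running means exist and settle onto the final mean
  rm <- runningMeans(res)
  expect_length(rm, 400L)
  expect_identical(rm[400], meanCollisions(res))
})

test_that("running means converge at the 1/sqrt(m) Monte Carlo rate", {
  k <- 4000
  res <- runSamplingExperiment(popLab, k = k, m = 800, seed = 7,
                               model = m22)
  target <- meanCollisions(res)
  rm <- runningMeans(res)
  # average absolute deviation from the long-run mean shrinks ~ sqrt(8)
  # between m ~ 10-50 and m ~ 640-800; allow generous slack
  early <- mean(abs(rm[10:50] - target))
  late <- mean(abs(rm[640:800] - target))
  expect_lt(late, early)
})

test_that("the comparison table lines up k, theory, observation", {
  tab <- theoryComparisonTable(popLab, kValues = c(2000, 8000), m = 30,
                               seed = 4, model = m22)
  expect_identical(names(tab),
                   c("k", "expected", "observed_mean",
                     "observed_mean_duplicates", "m"))
  expect_identical(tab$expected,
                   sapply(c(2000, 8000), expectedCollisions, m22))
  exps <- attr(tab, "experiments")
  expect_identical(tab$observed_mean[2], meanCollisions(exps[[2]]))
  expect_true(all(tab$observed_mean_duplicates <= tab$observed_mean))
})
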