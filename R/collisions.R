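## Exact collision counting and Monte Carlo subsampling experiments.

#' Count collisions in a multiset of hash values
#'
#' Computes both collision statistics exactly, by sort-and-run-length:
#' the same-hash pair count \eqn{X = \sum_v \binom{n_v}{2}} (the quantity
#' predicted by the birthday expectation \eqn{k(k-1)/2p}) and the
#' duplicate count (inputs minus distinct values).  The two differ only
#' when some value occurs three or more times: `c(5, 5, 5)` has 3 pairs
#' but 2 duplicates.  Input order is irrelevant.
#'
#' @param hashes numeric vector of hash values.
#' @return a [CollisionCount-class].
#' @examples
#' countCollisions(c(5, 5, 9))    # 1 pair, 1 duplicate
#' countCollisions(c(5, 5, 5))    # 3 pairs, 2 duplicates
#' @export
countCollisions <- function(hashes) {
  n <- length(hashes)
  if (n < 2)
    return(new("CollisionCount", pairCount = 0, duplicateCount = 0))
  s <- sort(hashes, method = "radix")
  same <- s[-1] == s[-n]
  if (!any(same))
    return(new("CollisionCount", pairCount = 0, duplicateCount = 0))
  r <- rle(same)
  runs <- r$lengths[r$values] + 1          # sizes n_v >= 2
  new("CollisionCount",
      pairCount = sum(runs * (runs - 1) / 2),
      duplicateCount = sum(runs - 1))
}

## per-repetition RNG stream: documented counter scheme so repetitions
## are reproducible and order-independent given (seed, i)
.repSeed <- function(seed, i) as.integer((seed + i - 1) %% 2147483647)

#' Run a random-subsampling collision experiment
#'
#' Draws `m` independent uniform random subsets of size `k` (without
#' replacement) from a population of hash values, counts the same-hash
#' pairs in each subset, and summarizes: mean observed collisions, the
#' per-dataset histogram, the running mean after 1..m repetitions, and
#' the theoretical expectation \eqn{D(k) = k(k-1)/2p} for comparison.
#' Repetition `i` reseeds the RNG with `(seed + i - 1) mod (2^31 - 1)`,
#' so results are deterministic given `seed` and independent of
#' evaluation order.
#'
#' @param population numeric vector of hash values (e.g. from
#'   [hashStereoPopulation()]).
#' @param k subset size, `1 <= k <= length(population)`.
#' @param m number of repetitions (`>= 1`).
#' @param seed root seed.
#' @param model a [BirthdayModel-class] giving the hash space for the
#'   theory column (defaults to the 37-bit second-block space).
#' @return an [ExperimentResult-class].
#' @examples
#' pop <- hashStereoPopulation(skeletonSpec("demo", 14))
#' runSamplingExperiment(pop, k = 4096, m = 100, seed = 42)
#' @export
runSamplingExperiment <- function(population, k, m, seed = 42L,
                                  model = birthdayModel(bits = 37)) {
  n <- length(population)
  stopifnot(k >= 1, m >= 1, k == floor(k), m == floor(m))
  if (k > n)
    stop(sprintf("subset size k = %g exceeds population size %d", k, n))
  pairs <- numeric(m)
  dups <- numeric(m)
  for (i in seq_len(m)) {
    set.seed(.repSeed(seed, i))
    cc <- countCollisions(population[sample.int(n, k)])
    pairs[i] <- cc@pairCount
    dups[i] <- cc@duplicateCount
  }
  h <- table(pairs)
  new("ExperimentResult",
      k = as.numeric(k), m = as.numeric(m), seed = as.numeric(seed),
      populationSize = as.numeric(n),
      meanCollisions = mean(pairs), meanDuplicates = mean(dups),
      histogram = setNames(as.numeric(h), names(h)),
      theory = expectedCollisions(k, model),
      runningMeans = cumsum(pairs) / seq_len(m))
}

#' Observed-versus-theory comparison table over a grid of subset sizes
#'
#' Runs [runSamplingExperiment()] for each `k` and tabulates
#' `(k, expected, observed_mean, observed_mean_duplicates, m)` — the
#' layout of the classic comparison table for second-block collisions.
#'
#' @param population numeric vector of hash values.
#' @param kValues subset sizes.
#' @param m repetitions per subset size (recycled over `kValues`).
#' @param seed root seed (each `k` derives its stream from it).
#' @param model a [BirthdayModel-class] for the theory column.
#' @return a `data.frame` with one row per `k`, plus the per-`k`
#'   [ExperimentResult-class] objects in `attr(, "experiments")`.
#' @export
theoryComparisonTable <- function(population, kValues, m = 1000L,
                                  seed = 42L,
                                  model = birthdayModel(bits = 37)) {
  m <- rep_len(m, length(kValues))
  exps <- vector("list", length(kValues))
  for (j in seq_along(kValues)) {
    ## offset the root seed per k so the k-grid uses disjoint streams
    exps[[j]] <- runSamplingExperiment(population, kValues[j], m[j],
                                       seed = seed + (j - 1) * 1000003,
                                       model = model)
  }
  out <- data.frame(
    k = kValues,
    expected = vapply(exps, theoryValue, numeric(1)),
    observed_mean = vapply(exps, meanCollisions, numeric(1)),
    observed_mean_duplicates = vapply(exps, slot, numeric(1),
                                      "meanDuplicates"),
    m = m)
  attr(out, "experiments") <- exps
  out
}
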