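## Closed-form birthday-paradox collision statistics for a uniform hash.

#' Construct a birthday-collision model
#'
#' A [BirthdayModel-class] describes a hash with `p` equally likely output
#' values.  For hash-derived spaces pass `bits` (so `p = 2^bits`); for
#' other spaces pass `p` directly (e.g. `p = 365` for birthdays).
#'
#' @param p number of equally likely outputs; ignored when `bits` is given.
#' @param bits hash width in bits.
#' @return a [BirthdayModel-class].
#' @examples
#' birthdayModel(365)          # classic birthdays
#' birthdayModel(bits = 37)    # InChIKey second block
#' birthdayModel(bits = 65)    # InChIKey first block
#' @export
birthdayModel <- function(p = NULL, bits = NULL) {
  if (!is.null(bits)) {
    stopifnot(length(bits) == 1L, bits >= 0, bits == floor(bits))
    new("BirthdayModel", p = 2^bits, bits = as.numeric(bits))
  } else {
    stopifnot(!is.null(p))
    new("BirthdayModel", p = as.numeric(p), bits = NA_real_)
  }
}

.checkK <- function(k) {
  if (length(k) != 1L || is.na(k) || !is.numeric(k))
    stop("'k' must be a single number")
  if (k < 0) stop("'k' must be nonnegative")
  if (k != floor(k)) stop("'k' must be an integer dataset size")
  k
}

#' Expected number of same-hash pairs (birthday collisions)
#'
#' For `k` independent uniform draws from `p` values, the expected number
#' of same-value pairs is \eqn{D(k) = k(k-1)/2p}: each of the
#' \eqn{\binom{k}{2}} pairs collides with probability `1/p`, and
#' expectation is linear.  For 365 birthdays this gives the classic 0.69
#' at `k = 23` and 1.04 at `k = 28`.
#'
#' The numerator `k(k-1)` is an exact integer for any `k` up to 2^53 and
#' is divided in double precision, so the result carries full 15-16 digit
#' accuracy even at `p = 2^65` scales.
#'
#' @param k dataset size (nonnegative integer; `k = 0` or `1` gives 0).
#' @param model a [BirthdayModel-class].
#' @return expected pair-collision count (nonnegative double).
#' @examples
#' expectedCollisions(23, birthdayModel(365))            # 0.693
#' expectedCollisions(1e6, birthdayModel(bits = 37))     # 3.6380
#' expectedCollisions(1e9, birthdayModel(bits = 65))     # 0.0136
#' @export
expectedCollisions <- function(k, model) {
  k <- .checkK(k)
  stopifnot(is(model, "BirthdayModel"))
  if (k < 2) return(0)
  (k / 2) * ((k - 1) / model@p)
}

#' Probability of at least one collision
#'
#' Probability that `k` uniform draws from `p` values are not all
#' distinct.  For `k <= 10^6` the exact product
#' \eqn{1 - \prod_{i=1}^{k-1} (1 - i/p)} is evaluated (via `log1p` sums);
#' beyond that the Poisson-regime approximation
#' \eqn{1 - \exp(-k(k-1)/2p)} is used.  The branch taken is recorded in
#' the `"method"` attribute of the result.
#'
#' @inheritParams expectedCollisions
#' @return probability in `[0, 1]`, with attribute `method` equal to
#'   `"exact-product"` or `"poisson-approx"`.
#' @examples
#' collisionProbability(23, birthdayModel(365))               # > 1/2
#' collisionProbability(1e9, birthdayModel(bits = 65))        # ~ 1.3%
#' collisionProbability(366, birthdayModel(365))              # exactly 1
#' @export
collisionProbability <- function(k, model) {
  k <- .checkK(k)
  stopifnot(is(model, "BirthdayModel"))
  p <- model@p
  if (k <= 1) {
    out <- 0
    attr(out, "method") <- "exact-product"
    return(out)
  }
  if (k <= 1e6) {
    i <- seq_len(k - 1)
    if (k > p) {
      out <- 1                      # pigeonhole: some factor is zero
    } else {
      out <- -expm1(sum(log1p(-i / p)))
    }
    attr(out, "method") <- "exact-product"
  } else {
    out <- -expm1(-(k / 2) * ((k - 1) / p))
    attr(out, "method") <- "poisson-approx"
  }
  out
}

#' Smallest dataset size with collision probability at least 1/2
#'
#' The smallest integer `k` with
#' \eqn{k \ge (1 + \sqrt{1 + 8\ln 2\, p})/2}; at this size the probability
#' that all hashes are distinct has dropped to at most one half.  The
#' condition is equivalent to \eqn{k(k-1) \ge 2\ln 2\, p}, which is used
#' for an exact integer refinement of the floating-point root (via an
#' error-free two-product), so the returned threshold is never off by one.
#'
#' @param model a [BirthdayModel-class].
#' @return positive integer-valued double.
#' @examples
#' halfProbabilityThreshold(birthdayModel(365))        # 23 people
#' halfProbabilityThreshold(birthdayModel(bits = 37))  # 436499
#' halfProbabilityThreshold(birthdayModel(bits = 65))  # 7151589655
#' @export
halfProbabilityThreshold <- function(model) {
  stopifnot(is(model, "BirthdayModel"))
  .smallestKWithProductAtLeast(2 * log(2) * model@p)
}

#' Smallest dataset size with expected collisions at least 1/2
#'
#' The smallest integer `k` with \eqn{k(k-1)/2p \ge 1/2}, i.e.
#' \eqn{k(k-1) \ge p}: the dataset size at which, on average, half a
#' same-hash pair is expected.  These are the sizes quoted as the
#' collision resistance of the two key blocks (about 6.1 x 10^9 skeletons
#' for the 65-bit first block and 3.7 x 10^5 isomers for the 37-bit second
#' block).
#'
#' @param model a [BirthdayModel-class].
#' @return positive integer-valued double.
#' @examples
#' halfExpectationThreshold(birthdayModel(bits = 37))  # 370729
#' halfExpectationThreshold(birthdayModel(bits = 65))  # ~ 6.1e9
#' @export
halfExpectationThreshold <- function(model) {
  stopifnot(is(model, "BirthdayModel"))
  .smallestKWithProductAtLeast(model@p)
}

## smallest integer k >= 1 with k(k-1) >= t, exact at the boundary
.smallestKWithProductAtLeast <- function(t) {
  if (t <= 0) return(1)
  k <- ceiling((1 + sqrt(1 + 4 * t)) / 2)
  while (k > 1 && .cmpProductMinus(k - 1, t) >= 0) k <- k - 1
  while (.cmpProductMinus(k, t) < 0) k <- k + 1
  k
}
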