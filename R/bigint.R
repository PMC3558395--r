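## Exact integer helpers beyond the 2^53 double-precision range.
##
## Block values reach 2^65 - 1 and the threshold searches must compare
## k(k-1) with 2p exactly at 66-bit magnitudes.  Two small tools cover
## this without a bignum dependency:
##   * a base-1e7 limb representation (little-endian numeric vector) with
##     divmod/mul-add by small radices, for mixed-radix block codecs;
##   * Dekker's error-free two-product, for exact comparison of k(k-1)
##     against an (exactly representable) power of two.

.BIG_BASE <- 1e7

.bigFromNumber <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, !is.na(x), x >= 0,
            x == floor(x), x <= 2^53)
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% .BIG_BASE)
    x <- (x - x %% .BIG_BASE) / .BIG_BASE
    if (x == 0) break
  }
  limbs
}

.bigFromDecimal <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, grepl("^[0-9]+$", s))
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  n <- nchar(s)
  cuts <- seq(n, 1, by = -7L)
  limbs <- vapply(cuts, function(end)
    as.numeric(substr(s, max(1L, end - 6L), end)), numeric(1))
  limbs
}

.bigToDecimal <- function(limbs) {
  limbs <- .bigTrim(limbs)
  k <- length(limbs)
  paste0(format(limbs[k], scientific = FALSE),
         if (k > 1L) paste(sprintf("%07.0f", rev(limbs[-k])), collapse = "")
         else "")
}

.bigTrim <- function(limbs) {
  while (length(limbs) > 1L && limbs[length(limbs)] == 0)
    limbs <- limbs[-length(limbs)]
  limbs
}

.bigIsZero <- function(limbs) all(limbs == 0)

## quotient and remainder by a small divisor (d * 1e7 must stay < 2^53)
.bigDivmod <- function(limbs, d) {
  stopifnot(d >= 1, d <= 2^29)
  q <- numeric(length(limbs))
  carry <- 0
  for (i in rev(seq_along(limbs))) {
    cur <- carry * .BIG_BASE + limbs[i]
    q[i] <- (cur - cur %% d) / d
    carry <- cur %% d
  }
  list(quotient = .bigTrim(q), remainder = carry)
}

## limbs * mult + add, with small mult/add (mult * 1e7 + carry < 2^53)
.bigMulAdd <- function(limbs, mult, add = 0) {
  stopifnot(mult >= 0, mult <= 2^29, add >= 0)
  out <- numeric(length(limbs) + 3L)
  carry <- add
  for (i in seq_along(limbs)) {
    cur <- limbs[i] * mult + carry
    out[i] <- cur %% .BIG_BASE
    carry <- (cur - cur %% .BIG_BASE) / .BIG_BASE
  }
  i <- length(limbs)
  while (carry > 0) {
    i <- i + 1L
    out[i] <- carry %% .BIG_BASE
    carry <- (carry - carry %% .BIG_BASE) / .BIG_BASE
  }
  .bigTrim(out[seq_len(max(i, 1L))])
}

## numeric value if exactly representable (< 2^53), else NA
.bigToNumber <- function(limbs) {
  v <- 0
  for (i in rev(seq_along(limbs))) v <- v * .BIG_BASE + limbs[i]
  if (v <= 2^53) v else NA_real_
}

## -- Dekker two-product ------------------------------------------------

## exact a*b as an unevaluated hi+lo double pair (a, b < 2^53 integers)
.twoProduct <- function(a, b) {
  split <- function(x) {
    c_ <- 134217729 * x            # 2^27 + 1
    hi <- c_ - (c_ - x)
    c(hi, x - hi)
  }
  p <- a * b
  sa <- split(a); sb <- split(b)
  err <- ((sa[1] * sb[1] - p) + sa[1] * sb[2] + sa[2] * sb[1]) +
    sa[2] * sb[2]
  c(hi = p, lo = err)
}

## sign of k*(k-1) - t where t is a double (exact when t is, e.g., a power
## of two; for irrational t the double rounding of t is the only slack)
.cmpProductMinus <- function(k, t) {
  pr <- .twoProduct(k, k - 1)
  d <- pr[["hi"]] - t
  if (d != 0) return(sign(d))
  sign(pr[["lo"]])
}
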