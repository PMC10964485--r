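## Minimal exact rational arithmetic on integer numerator/denominator pairs.
## Used by the stoichiometry module so that balance residuals are exact:
## the cell-synthesis reaction carries twentieths, which are not
## representable in binary floating point.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

## reduce num/den to lowest terms, den > 0
.ratReduce <- function(num, den) {
  num <- unname(num)
  den <- unname(den)
  stopifnot(den != 0)
  if (num == 0) return(c(num = 0, den = 1))
  g <- .gcd(num, den)
  s <- sign(den)
  c(num = s * num / g, den = s * den / g)
}

.ratAdd <- function(a, b) {
  .ratReduce(a[["num"]] * b[["den"]] + b[["num"]] * a[["den"]],
             a[["den"]] * b[["den"]])
}

.ratMulInt <- function(a, k) {
  .ratReduce(a[["num"]] * k, a[["den"]])
}

## sum of num/den vectors, exactly
.ratSum <- function(num, den) {
  acc <- c(num = 0, den = 1)
  for (i in seq_along(num)) {
    acc <- .ratAdd(acc, .ratReduce(num[i], den[i]))
  }
  acc
}

.ratAsNumeric <- function(a) a[["num"]] / a[["den"]]
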