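## Independent oracle implementations used to cross-check the package.
## These deliberately share no code with the functions they verify.

## r-squared by direct tabulation of the 2x2 haplotype table
oracleR2 <- function(a, b) {
  n <- length(a)
  nAB <- sum(a == 1 & b == 1); nAb <- sum(a == 1 & b == 0)
  naB <- sum(a == 0 & b == 1); nab <- sum(a == 0 & b == 0)
  pA <- (nAB + nAb) / n; pB <- (nAB + naB) / n
  D <- nAB / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

## two-sided Fisher exact P by full enumeration of tables with fixed margins
oracleFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  aVals <- max(0, c1 - r2):min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1)
  }
  pObs <- exp(logp(a))
  ps <- exp(vapply(aVals, logp, numeric(1)))
  sum(ps[ps <= pObs * (1 + 1e-7)])
}

## affine-gap global alignment score by an independent three-state DP
## (gap of length L costs -(open + L * extend), with open/extend positive)
oracleAlignScore <- function(x, y, match = 1, mismatch = -1,
                             open = 4, extend = 1) {
  x <- strsplit(x, "")[[1]]; y <- strsplit(y, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # last column aligned x[i] to y[j]
  X <- matrix(NEG, n + 1, m + 1)   # last column a gap in y (x[i] unmatched)
  Y <- matrix(NEG, n + 1, m + 1)   # last column a gap in x
  M[1, 1] <- 0
  for (i in seq_len(n) + 1L)
    X[i, 1] <- -(open + (i - 1) * extend)
  for (j in seq_len(m) + 1L)
    Y[1, j] <- -(open + (j - 1) * extend)
  for (i in seq_len(n) + 1L) for (j in seq_len(m) + 1L) {
    s <- if (x[i - 1] == y[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend,
                   Y[i - 1, j] - open - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend,
                   X[i, j - 1] - open - extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## random short DNA sequence
randomSeq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), collapse = "")

## a tiny deterministic reference with all needed motifs
tinyReference <- function() c(chr1 = "AATCATCGACGTCCAGGTTCAA")
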