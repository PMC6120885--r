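#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-rolled BH step-up so the adjustment used throughout the pipeline can
#' be cross-checked against an independent reference in the test suite:
#' sort p ascending, q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
#' NA p-values propagate to NA q-values and do not count toward m.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order and length as \code{p}.
#' @examples
#' adjustBH(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjustBH <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  x <- p[ok]
  if (any(x < 0 | x > 1)) stop("p-values must lie in [0, 1]")
  m <- length(x)
  if (m == 0) return(q)
  o <- order(x, decreasing = TRUE)          # largest first
  qs <- pmin(1, cummin(x[o] * m / seq(m, 1)))
  tmp <- q[ok]; tmp[o] <- qs; q[ok] <- tmp
  q
}

## Rank-transform each row (gene) across samples, average ranks for ties.
## cor() of row-ranked data is the Spearman correlation.
.rowRanks <- function(m) {
  t(apply(m, 1, rank, ties.method = "average"))
}

## One-sided upper-tail hypergeometric P(X >= k) with population N, K
## successes, n draws. phyper is numerically stable for corpus-scale N.
.hyperUpper <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

## Derive a bounded child seed from a master seed and a stream index, so
## each component (expression / regulome / citations / replicate) gets an
## independent reproducible stream.
.childSeed <- function(seed, stream) {
  ## double arithmetic: products exceed 32-bit range but stay exact below 2^53
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483629
}

.upperPairs <- function(n) {
  ## fixed pair order: column-major upper triangle (1,2), (1,3), (2,3),
  ## (1,4), ... — exactly m[upper.tri(m)] on a symmetric matrix
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}
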