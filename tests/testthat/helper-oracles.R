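# Brute-force enumeration oracles, implemented independently of the package
# code paths they check.

# P(X >= k) for the hypergeometric by enumerating all size-n draws from a
# universe of N elements of which the first K are "annotated".
oracleHyperUpper <- function(N, K, n, k) {
  if (n == 0)
    return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Exact two-sample rank-sum distribution by enumerating which of the pooled
# ranks go to x; returns the two-sided p for the observed samples.
oracleWilcoxTwoSided <- function(x, y) {
  m <- length(x); s <- m + length(y)
  pooled <- rank(c(x, y))
  wObs <- sum(pooled[seq_len(m)]) - m * (m + 1) / 2
  assignments <- utils::combn(s, m)
  wAll <- colSums(matrix(seq_len(s)[assignments], nrow = m)) -
    m * (m + 1) / 2
  pLe <- mean(wAll <= wObs)
  pGe <- mean(wAll >= wObs)
  min(1, 2 * min(pLe, pGe))
}

# Textbook Pearson chi-square (no correction).
oracleChi2Plain <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Yates-corrected 2x2 chi-square from the closed formula.
oracleChi2Yates <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  N <- sum(tab)
  num <- max(0, abs(a * d - b * c_) - N / 2)
  N * num^2 / (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
}

# Full enumeration of P(|A_1 & ... & A_k| >= m) over all tuples of fixed-size
# subsets of 1:N, using bit masks.
oracleMultisetP <- function(N, sizes, m) {
  masksOf <- function(sz) {
    if (sz == 0)
      return(0L)
    apply(utils::combn(N, sz), 2L, function(ix) sum(bitwShiftL(1L, ix - 1L)))
  }
  popcount <- function(v) {
    out <- integer(length(v))
    while (any(v > 0L)) {
      out <- out + bitwAnd(v, 1L)
      v <- bitwShiftR(v, 1L)
    }
    out
  }
  tuples <- Reduce(function(acc, sz) {
    msk <- masksOf(sz)
    unlist(lapply(acc, function(a) bitwAnd(a, msk)))
  }, sizes[-1L], init = masksOf(sizes[1L]))
  mean(popcount(tuples) >= m)
}
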