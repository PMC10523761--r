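# Association statistics: disease-ortholog enrichment of selected modules
# (Wilcoxon rank-sum on per-module percentages), RIP-target prevalence
# comparisons (2x2 chi-square), and exact multi-set intersection tests built
# from a chained hypergeometric mixture (the SuperExactTest construction).

#' Percentage of disease-linked proteins in a module
#'
#' @param module a [FunctionalModule-class] or character vector of nodes.
#' @param disease data.frame (`gene`, `linked`); genes absent from the table
#'   count as not linked.
#' @return percentage in \[0, 100\].
#' @export
diseaseFraction <- function(module, disease) {
  nodes <- if (is(module, "FunctionalModule")) moduleNodes(module)
           else as.character(module)
  if (length(nodes) == 0L)
    stop("cannot score an empty module")
  linked <- disease$gene[disease$linked]
  100 * length(intersect(nodes, linked)) / length(nodes)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sample location test on ranks (midranks for ties). The p-value is
#' exact by enumeration of rank assignments when the pooled sample has at
#' most 12 observations and no ties, otherwise it uses the normal
#' approximation with tie and continuity corrections. The boundary only
#' affects p-value precision, never the direction of the comparison.
#'
#' @param x,y numeric samples, both non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   relative to `x`.
#' @return list with `statistic` (the Mann-Whitney U for `x`), `p`, and
#'   `exact` (whether the exact distribution was used).
#' @examples
#' wilcoxonRankSum(c(3, 4), c(1, 2))$p  # 1/3
#' @export
wilcoxonRankSum <- function(x, y,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 12L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  p <- ht$p.value
  if (is.nan(p))
    p <- 1  # zero rank variance (all observations tied): no evidence
  list(statistic = unname(ht$statistic), p = p, exact = exact)
}

#' Chi-square test of independence on a 2x2 table
#'
#' Pearson's chi-square with one degree of freedom; the Yates continuity
#' correction is applied by default, mirroring R's reference behaviour for
#' 2x2 tables.
#'
#' @param tab 2x2 matrix of non-negative counts (rows = group,
#'   columns = outcome), or a length-4 vector filled row-wise.
#' @param yates apply the continuity correction (default `TRUE`).
#' @return list with `chi2` and `p`.
#' @examples
#' chi2Independence(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))$chi2  # 16.2
#' @export
chi2Independence <- function(tab, yates = TRUE) {
  if (!is.matrix(tab))
    tab <- matrix(tab, nrow = 2L, byrow = TRUE)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0))
    stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test undefined for a zero margin")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(chi2 = unname(ht$statistic), p = ht$p.value)
}

#' Expected size of a random multi-set intersection
#'
#' For k independent uniform subsets of sizes n_1..n_k drawn from a universe
#' of size N, the expected size of their common intersection is
#' `N * prod(n_i / N)`.
#'
#' @param N universe size.
#' @param sizes vector of subset sizes.
#' @return expected intersection size.
#' @export
multisetExpected <- function(N, sizes) {
  if (any(sizes > N) || any(sizes < 0) || N < 1)
    stop("subset sizes must lie in [0, N]")
  N * prod(sizes / N)
}

#' Exact distribution of a multi-set intersection size
#'
#' Distribution of |A_1 & ... & A_k| when each A_i is an independent uniform
#' subset of fixed size n_i from a universe of size N, built by chained
#' hypergeometric mixing: the intersection of the first j sets, conditional
#' on having size y, intersects A_j+1 in Hypergeometric(N, y, n_j+1) elements.
#'
#' @param N universe size.
#' @param sizes vector of at least one subset size.
#' @return numeric vector of probabilities for intersection sizes
#'   `0:min(sizes)` (named).
#' @export
multisetIntersectionDist <- function(N, sizes) {
  if (length(sizes) < 1L || any(sizes > N) || any(sizes < 0) || N < 1)
    stop("require at least one subset size, each in [0, N]")
  # d[y + 1] = P(|A_1 & ... & A_j| = y); the support shrinks as sets mix in
  top <- sizes[1L]
  d <- c(rep(0, top), 1)  # point mass at n_1
  for (j in seq_along(sizes)[-1L]) {
    nj <- sizes[j]
    newTop <- min(top, nj)
    dNew <- numeric(newTop + 1L)
    for (y in which(d > 0) - 1L)
      dNew <- dNew + d[y + 1L] * stats::dhyper(0:newTop, y, N - y, nj)
    d <- dNew
    top <- newTop
  }
  names(d) <- 0:top
  d
}

#' Upper-tail multi-set intersection test
#'
#' P(|A_1 & ... & A_k| >= m) under independent uniform fixed-size subsets,
#' from the exact chained-hypergeometric distribution. Used to compare the
#' observed overlap of DE/AS gene sets across knockdowns with random
#' expectation.
#'
#' @param N universe size.
#' @param sizes vector of k >= 2 subset sizes.
#' @param m observed intersection size, `m <= min(sizes)`.
#' @return upper-tail probability.
#' @examples
#' multisetIntersectionP(4, c(2, 2), 2)      # 1/6
#' multisetIntersectionP(3, c(2, 2, 2), 1)   # 7/9
#' @export
multisetIntersectionP <- function(N, sizes, m) {
  if (length(sizes) < 2L)
    stop("at least two sets are required")
  if (m > min(sizes) || m < 0)
    stop("'m' must lie in [0, min(sizes)]")
  if (m == 0)
    return(1)
  d <- multisetIntersectionDist(N, sizes)
  sum(d[as.integer(names(d)) >= m])
}

#' Disease enrichment of selected versus non-selected modules
#'
#' Two-sided Wilcoxon rank-sum test comparing the per-module percentage of
#' disease-linked proteins between selected modules and the rest of the
#' library.
#'
#' @param lib a [ModuleLibrary-class].
#' @param selectedIds selected module term ids.
#' @param disease disease data.frame (`gene`, `linked`).
#' @return list with `statistic`, `p`, `medianSelected`, `medianRest`,
#'   `nSelected`, `nRest`.
#' @export
compareSelectedVsRest <- function(lib, selectedIds, disease) {
  ids <- names(lib)
  selectedIds <- intersect(ids, selectedIds)
  restIds <- setdiff(ids, selectedIds)
  if (length(selectedIds) == 0L || length(restIds) == 0L)
    stop("both the selected and the non-selected group must be non-empty")
  fr <- function(id) diseaseFraction(lib[[id]], disease)
  x <- vapply(selectedIds, fr, numeric(1))
  y <- vapply(restIds, fr, numeric(1))
  wt <- wilcoxonRankSum(x, y, alternative = "two.sided")
  list(statistic = wt$statistic, p = wt$p,
       medianSelected = stats::median(x), medianRest = stats::median(y),
       nSelected = length(x), nRest = length(y))
}

#' RIP-target prevalence across module membership groups
#'
#' Fraction of bound transcripts within disjoint groups of altered genes
#' (typically: in selected modules / in non-selected modules / in no module),
#' with a Yates-corrected 2x2 chi-square for every pair of non-empty groups.
#'
#' @param groups named list of disjoint character vectors of genes.
#' @param bound character vector: union of all RIP bound sets.
#' @return list with `fractions` (data.frame: group, n, n_bound,
#'   fraction_pct; `NA` fraction for an empty group) and `tests` (data.frame:
#'   group_a, group_b, chi2, p).
#' @export
ripPrevalence <- function(groups, bound) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  all_ <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_))
    stop("groups must be disjoint")
  bound <- unique(bound)
  n <- lengths(groups)
  nb <- vapply(groups, function(g) length(intersect(g, bound)), integer(1))
  fractions <- data.frame(group = names(groups), n = as.integer(n),
                          n_bound = nb,
                          fraction_pct = ifelse(n > 0, 100 * nb / n,
                                                NA_real_),
                          row.names = NULL)
  tests <- data.frame(group_a = character(0), group_b = character(0),
                      chi2 = numeric(0), p = numeric(0))
  nonEmpty <- names(groups)[n > 0]
  if (length(nonEmpty) >= 2L) {
    pairs <- utils::combn(nonEmpty, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      tab <- matrix(c(nb[[a]], n[[a]] - nb[[a]],
                      nb[[b]], n[[b]] - nb[[b]]), nrow = 2L, byrow = TRUE)
      res <- tryCatch(chi2Independence(tab, yates = TRUE),
                      error = function(e) list(chi2 = NA_real_,
                                               p = NA_real_))
      data.frame(group_a = a, group_b = b, chi2 = res$chi2, p = res$p)
    }))
  }
  list(fractions = fractions, tests = tests)
}
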