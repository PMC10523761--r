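# Term over-representation of the tissue network against the unspecific
# network: hypergeometric upper-tail test per term, with a randomization-based
# FDR estimate (random candidate sets of the same size drawn from the
# background, default 1000 draws, flagged at FDR <= 0.1).

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of at least `k`
#' annotated genes among `n` drawn without replacement from a universe of `N`
#' genes of which `K` are annotated. Evaluated through [stats::phyper()],
#' which computes in log space and is numerically stable far into the tail.
#'
#' @param N background (universe) size.
#' @param K number of annotated genes in the background.
#' @param n candidate-set size.
#' @param k observed overlap.
#' @return a probability.
#' @examples
#' hypergeomUpper(10, 4, 5, 4)  # 6/252
#' @export
hypergeomUpper <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || any(k > pmin(K, n)) || any(K > N) ||
      any(n > N))
    stop("require 0 <= k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term-wise over-representation of a candidate gene set
#'
#' One hypergeometric upper-tail test per annotation term. Annotations are
#' restricted to background genes before counting; terms with no background
#' gene are dropped.
#'
#' @param candidate character vector of candidate genes (must be a subset of
#'   `background`), typically the tissue-network node set.
#' @param background character vector of background genes, typically the
#'   unspecific-network node set.
#' @param annotations annotation data.frame (`term_id`, `term_name`, `gene`).
#' @return data.frame with one row per term: `term_id`, `term_name`, `k`
#'   (overlap), `K` (term size in background), `n`, `N`, `p`; sorted by
#'   term id.
#' @export
enrichTerms <- function(candidate, background, annotations) {
  candidate <- unique(candidate)
  background <- unique(background)
  if (!all(candidate %in% background))
    stop("candidate set must be a subset of the background")
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  ann <- unique(ann[, c("term_id", "term_name", "gene")])
  if (nrow(ann) == 0L)
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0)))
  termK <- table(ann$term_id)
  inCand <- ann$gene %in% candidate
  termk <- table(factor(ann$term_id[inCand], levels = names(termK)))
  ids <- names(termK)
  nameOf <- ann$term_name[match(ids, ann$term_id)]
  out <- data.frame(term_id = ids, term_name = nameOf,
                    k = as.integer(termk), K = as.integer(termK),
                    n = length(candidate), N = length(background),
                    p = hypergeomUpper(length(background), as.integer(termK),
                                       length(candidate), as.integer(termk)))
  out <- out[order(out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomization-based FDR for term enrichment
#'
#' For each of `nRand` randomizations a candidate set of the observed size is
#' drawn uniformly from the background and all term p-values are recomputed.
#' The FDR at an observed p-value t is the mean number of null terms with
#' p <= t across randomizations, divided by the number of observed terms with
#' p <= t (at least 1), made monotone non-decreasing in p by a cumulative
#' maximum from the smallest p and capped at 1. Terms are flagged enriched at
#' `fdr <= fdrThreshold`.
#'
#' @param results data.frame from [enrichTerms()].
#' @param candidateSize size of the observed candidate set (defaults to the
#'   `n` recorded in `results`).
#' @param background background gene identifiers.
#' @param annotations annotation data.frame.
#' @param nRand number of randomizations, default 1000.
#' @param fdrThreshold enrichment cut-off on the estimated FDR, default 0.1.
#' @param seed optional seed for the randomizations; the caller's RNG state
#'   is preserved.
#' @return `results` with extra columns `fdr` and `enriched`.
#' @export
randomizationFdr <- function(results, candidateSize = NULL, background,
                             annotations, nRand = 1000, fdrThreshold = 0.1,
                             seed = NULL) {
  stopifnot(nRand >= 1)
  if (nrow(results) == 0L) {
    results$fdr <- numeric(0)
    results$enriched <- logical(0)
    return(results)
  }
  background <- unique(background)
  if (is.null(candidateSize))
    candidateSize <- results$n[1L]
  N <- length(background)
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  ann <- unique(ann[, c("term_id", "gene")])
  ann <- ann[ann$term_id %in% results$term_id, , drop = FALSE]
  gi <- match(ann$gene, background)
  ti <- match(ann$term_id, results$term_id)
  A <- Matrix::sparseMatrix(i = gi, j = ti, x = 1,
                            dims = c(N, nrow(results)))
  Kvec <- results$K

  nullP <- withSeed(seed, {
    draws <- matrix(0, nrow = N, ncol = nRand)
    for (r in seq_len(nRand))
      draws[sample.int(N, candidateSize), r] <- 1
    kNull <- as.matrix(Matrix::crossprod(A, draws))  # terms x nRand
    stats::phyper(kNull - 1, Kvec, N - Kvec, candidateSize,
                  lower.tail = FALSE)
  })

  sortedNull <- sort(as.vector(nullP))
  sortedObs <- sort(results$p)
  nullCount <- findInterval(results$p, sortedNull) / nRand
  obsCount <- findInterval(results$p, sortedObs)
  fdr <- nullCount / pmax(1, obsCount)
  ord <- order(results$p)
  fdr[ord] <- cummax(fdr[ord])
  results$fdr <- pmin(1, fdr)
  results$enriched <- results$fdr <= fdrThreshold
  results
}

#' Run the full enrichment step
#'
#' [enrichTerms()] followed by [randomizationFdr()] with the same background
#' and annotations.
#'
#' @inheritParams enrichTerms
#' @inheritParams randomizationFdr
#' @return data.frame with per-term counts, `p`, `fdr` and `enriched`.
#' @export
runEnrichment <- function(candidate, background, annotations, nRand = 1000,
                          fdrThreshold = 0.1, seed = NULL) {
  res <- enrichTerms(candidate, background, annotations)
  randomizationFdr(res, length(unique(candidate)), background, annotations,
                   nRand = nRand, fdrThreshold = fdrThreshold, seed = seed)
}
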