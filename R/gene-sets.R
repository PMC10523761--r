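# Derivation of the analysis gene sets from DEA / splicing / RIP tables.
# All significance comparisons are strict (<): boundary values (padj = 0.05,
# FDR = 0.05, FPKM = 1) are non-significant / non-expressed.

#' Tissue expression universe
#'
#' Genes whose expression is strictly greater than `threshold` FPKM define
#' the tissue (e.g. adult brain) universe used to filter all downstream gene
#' sets and the interaction network.
#'
#' @param expr expression data.frame (`gene`, `fpkm`).
#' @param threshold FPKM cut-off; a gene is kept when `fpkm > threshold`.
#'   Default 1.
#' @return sorted character vector of gene identifiers. Warns when empty.
#' @examples
#' neuronalUniverse(data.frame(gene = c("A", "B"), fpkm = c(0.5, 7)))
#' @export
neuronalUniverse <- function(expr, threshold = 1) {
  stopifnot(is.data.frame(expr), all(c("gene", "fpkm") %in% names(expr)))
  if (nrow(expr) == 0L)
    stop("expression table is empty")
  out <- sort(unique(expr$gene[expr$fpkm > threshold]))
  if (!length(out))
    warning("no gene passes the expression threshold of ", threshold, " FPKM")
  out
}

#' Call differentially expressed genes
#'
#' Splits a DEA table into up- and down-regulated sets at adjusted
#' p < `alpha` (strict). Genes with missing `padj` are non-significant, and a
#' log2 fold change of exactly 0 belongs to neither direction.
#'
#' @param dea data.frame (`gene`, `log2fc`, `padj`).
#' @param alpha significance level, default 0.05.
#' @return list with sorted character vectors `up` and `down`.
#' @export
callDe <- function(dea, alpha = 0.05) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(dea)))
  sig <- !is.na(dea$padj) & dea$padj < alpha & !is.na(dea$log2fc)
  list(up = sort(dea$gene[sig & dea$log2fc > 0]),
       down = sort(dea$gene[sig & dea$log2fc < 0]))
}

#' Call genes with altered splicing
#'
#' Takes one splicing table or a list of them (e.g. one per event class) and
#' returns the union of genes with FDR < `alpha` (strict) in any table.
#'
#' @param splicing data.frame (`gene`, `fdr`) or a list of such data.frames.
#' @param alpha significance level, default 0.05.
#' @return sorted character vector.
#' @export
callAs <- function(splicing, alpha = 0.05) {
  if (is.data.frame(splicing))
    splicing <- list(splicing)
  hits <- lapply(splicing, function(tab) {
    stopifnot(all(c("gene", "fdr") %in% names(tab)))
    tab$gene[!is.na(tab$fdr) & tab$fdr < alpha]
  })
  sort(unique(as.character(unlist(hits, use.names = FALSE))))
}

#' Call transcripts bound in a RIP experiment
#'
#' A transcript is bound by the immunoprecipitated protein when its
#' enrichment over the control pull-down has a positive log2 fold change and
#' an adjusted p below `alpha` (strict).
#'
#' @param rip DEA-style data.frame (`gene`, `log2fc`, `padj`) of the pull-down
#'   versus control comparison.
#' @param alpha significance level, default 0.05.
#' @return sorted character vector of bound gene identifiers.
#' @export
callBound <- function(rip, alpha = 0.05) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(rip)))
  sort(rip$gene[!is.na(rip$padj) & rip$padj < alpha &
                  !is.na(rip$log2fc) & rip$log2fc > 0])
}

#' Restrict gene sets to an expression universe
#'
#' Intersects a gene set, a list of gene sets, or all three sets of a
#' [KnockdownProfile-class] with the universe. Idempotent.
#'
#' @param x character vector, list of character vectors, or
#'   `KnockdownProfile`.
#' @param universe character vector from [neuronalUniverse()].
#' @return object of the same shape as `x`.
#' @export
restrictToUniverse <- function(x, universe) {
  if (is(x, "KnockdownProfile"))
    return(knockdownProfile(x@condition,
                            deUp = intersect(x@deUp, universe),
                            deDown = intersect(x@deDown, universe),
                            asSet = intersect(x@asSet, universe)))
  if (is.list(x))
    return(lapply(x, restrictToUniverse, universe = universe))
  sort(intersect(x, universe))
}

#' Derive a knockdown profile from raw tables
#'
#' Convenience wrapper: calls DE and AS genes at the given thresholds and,
#' when a universe is supplied, restricts all sets to it.
#'
#' @param condition condition label.
#' @param dea DEA data.frame for this condition.
#' @param splicing splicing data.frame (or list of them) for this condition.
#' @param universe optional expression universe.
#' @param deAlpha,asAlpha significance levels (default 0.05).
#' @return a [KnockdownProfile-class].
#' @export
deriveProfile <- function(condition, dea, splicing, universe = NULL,
                          deAlpha = 0.05, asAlpha = 0.05) {
  de <- callDe(dea, deAlpha)
  as_ <- callAs(splicing, asAlpha)
  prof <- knockdownProfile(condition, deUp = de$up, deDown = de$down,
                           asSet = as_)
  if (!is.null(universe))
    prof <- restrictToUniverse(prof, universe)
  prof
}
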