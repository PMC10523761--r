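# Turning enriched terms into functional modules: induce the term's genes on
# the tissue network, keep the component structure, apply the isolated-cluster
# rule (discard satellites only when the largest component holds strictly more
# than 90% of the induced nodes) and the inclusive 10-100 size window.

#' Extract the functional module of one term
#'
#' Induces the subgraph of the tissue network on the term's genes and
#' computes its connected components (an induced node without any
#' within-module edge is a singleton component). If the largest component
#' covers strictly more than `keepFraction` of the induced nodes, the
#' isolated clusters are discarded and only the largest component is
#' retained; otherwise all components are kept — proteins collaborating in
#' one process need not all interact physically. A largest-component share of
#' exactly `keepFraction` does not trigger the discard.
#'
#' @param termGenes character vector of genes annotated to the term.
#' @param net tissue `igraph` network.
#' @param termId,termName term identifier and display name.
#' @param keepFraction largest-component share above which satellites are
#'   dropped; default 0.9.
#' @return a [FunctionalModule-class], or `NULL` when no term gene is a
#'   network node.
#' @examples
#' g <- buildNetwork(data.frame(p1 = c("A", "B"), p2 = c("B", "C")))
#' extractModule(c("A", "B", "C"), g, "T1")
#' @export
extractModule <- function(termGenes, net, termId = "term",
                          termName = termId, keepFraction = 0.9) {
  nodes <- intersect(igraph::V(net)$name, unique(termGenes))
  if (length(nodes) == 0L)
    return(NULL)
  sub <- igraph::induced_subgraph(net, nodes)
  comp <- igraph::components(sub)
  parts <- split(igraph::V(sub)$name, comp$membership)
  parts <- lapply(parts, sort)
  # deterministic order: by decreasing size, ties by first node name
  parts <- parts[order(-lengths(parts),
                       vapply(parts, `[`, character(1), 1L))]
  if (lengths(parts)[1L] / length(nodes) > keepFraction)
    parts <- parts[1L]
  new("FunctionalModule", termId = termId, termName = termName,
      nodes = sort(unlist(parts, use.names = FALSE)),
      components = unname(parts))
}

#' Build the module library from enriched terms
#'
#' One candidate module per enriched term via [extractModule()]; modules are
#' kept when their retained size (after the isolated-cluster rule) lies in
#' the inclusive window `[minSize, maxSize]`. The library is sorted by term
#' id.
#'
#' @param enriched enrichment data.frame with `term_id`, `term_name` and
#'   logical `enriched` (see [runEnrichment()]); only flagged terms are used.
#' @param annotations annotation data.frame (`term_id`, `term_name`, `gene`).
#' @param net tissue `igraph` network.
#' @param minSize,maxSize inclusive size bounds, defaults 10 and 100.
#' @param keepFraction passed to [extractModule()].
#' @return a [ModuleLibrary-class].
#' @export
buildLibrary <- function(enriched, annotations, net, minSize = 10,
                         maxSize = 100, keepFraction = 0.9) {
  ids <- sort(enriched$term_id[enriched$enriched])
  mods <- list()
  for (id in ids) {
    genes <- annotations$gene[annotations$term_id == id]
    nm <- enriched$term_name[match(id, enriched$term_id)]
    m <- extractModule(genes, net, termId = id, termName = nm,
                       keepFraction = keepFraction)
    if (!is.null(m) && moduleSize(m) >= minSize && moduleSize(m) <= maxSize)
      mods[[id]] <- m
  }
  new("ModuleLibrary", modules = mods,
      provenance = list(minSize = minSize, maxSize = maxSize,
                        keepFraction = keepFraction,
                        nEnriched = length(ids)))
}

#' Pairwise module redundancy
#'
#' Reports (never filters) the overlap between every pair of library modules:
#' the Jaccard index |A&B|/|A|B| and the overlap coefficient
#' |A&B|/min(|A|,|B|).
#'
#' @param lib a [ModuleLibrary-class] with at least two modules.
#' @return data.frame with `term_a`, `term_b`, `intersection`, `jaccard`,
#'   `overlap_coef`, one row per unordered pair (a < b).
#' @export
redundancyMatrix <- function(lib) {
  if (length(lib) < 2L)
    stop("redundancy requires at least two modules")
  ids <- names(lib)
  pairs <- utils::combn(ids, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    a <- moduleNodes(lib[[pr[1L]]])
    b <- moduleNodes(lib[[pr[2L]]])
    i <- length(intersect(a, b))
    c(i, i / length(union(a, b)), i / min(length(a), length(b)))
  })
  data.frame(term_a = pairs[1L, ], term_b = pairs[2L, ],
             intersection = as.integer(rows[1L, ]),
             jaccard = rows[2L, ], overlap_coef = rows[3L, ])
}
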