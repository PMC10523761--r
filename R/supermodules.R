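# Coalescing selected modules into super-modules. The overlap graph connects
# selected modules that share altered transcripts; coalescing thresholds the
# node-set Jaccard index and takes connected components, which is
# deterministic and order-free, unlike manual grouping.

#' Build the overlap graph over selected modules
#'
#' Vertices are the selected modules. An edge connects two modules sharing at
#' least one altered node (altered in any condition); it carries
#' `shared_altered` (the number of commonly altered transcripts, the display
#' weight) and `jaccard` (the Jaccard index of the full node sets, the
#' coalescing signal).
#'
#' @param lib a [ModuleLibrary-class].
#' @param selectedIds term ids of the selected modules.
#' @param profiles named list of [KnockdownProfile-class].
#' @return an undirected `igraph` graph with edge attributes
#'   `shared_altered` and `jaccard`.
#' @export
buildOverlapGraph <- function(lib, selectedIds, profiles) {
  selectedIds <- sort(unique(selectedIds))
  if (length(selectedIds) == 0L)
    stop("no selected modules")
  stopifnot(all(selectedIds %in% names(lib)))
  alteredAll <- sort(unique(unlist(lapply(profiles, alteredGenes),
                                   use.names = FALSE)))
  nodesOf <- lapply(selectedIds, function(id) moduleNodes(lib[[id]]))
  names(nodesOf) <- selectedIds
  altOf <- lapply(nodesOf, intersect, y = alteredAll)

  g <- igraph::make_empty_graph(n = length(selectedIds), directed = FALSE)
  igraph::V(g)$name <- selectedIds
  if (length(selectedIds) >= 2L) {
    pairs <- utils::combn(selectedIds, 2L)
    sharedAltered <- apply(pairs, 2L, function(pr)
      length(intersect(altOf[[pr[1L]]], altOf[[pr[2L]]])))
    jac <- apply(pairs, 2L, function(pr) {
      a <- nodesOf[[pr[1L]]]; b <- nodesOf[[pr[2L]]]
      length(intersect(a, b)) / length(union(a, b))
    })
    keep <- sharedAltered > 0
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
      igraph::E(g)$shared_altered <- sharedAltered[keep]
      igraph::E(g)$jaccard <- jac[keep]
    }
  }
  g
}

#' Coalesce selected modules into super-modules
#'
#' Keeps overlap-graph edges with node-set Jaccard at or above `minJaccard`
#' and takes connected components. Every selected module ends up in exactly
#' one super-module; singletons are allowed. Super-module ids are
#' deterministic, derived from the smallest member term id.
#'
#' @param graph overlap graph from [buildOverlapGraph()].
#' @param lib the [ModuleLibrary-class] the modules come from.
#' @param minJaccard Jaccard threshold, default 0.2.
#' @return a [SuperModuleSet-class].
#' @export
coalesceSuperModules <- function(graph, lib, minJaccard = 0.2) {
  if (igraph::ecount(graph) > 0L) {
    drop <- igraph::E(graph)[igraph::E(graph)$jaccard < minJaccard]
    graph <- igraph::delete_edges(graph, drop)
  }
  comp <- igraph::components(graph)
  members <- split(igraph::V(graph)$name, comp$membership)
  members <- lapply(members, sort)
  ids <- paste0("SM_", vapply(members, `[`, character(1), 1L))
  ord <- order(ids)
  members <- members[ord]
  ids <- ids[ord]
  names(members) <- ids
  nodes <- lapply(members, function(ms)
    sort(unique(unlist(lapply(ms, function(id) moduleNodes(lib[[id]])),
                       use.names = FALSE))))
  new("SuperModuleSet", ids = ids, members = members, nodes = nodes)
}

#' Overlap between two super-modules
#'
#' Percentage of shared nodes relative to the smaller super-module (the
#' overlap coefficient, in percent).
#'
#' @param a,b character vectors of node identifiers.
#' @return percentage in \[0, 100\].
#' @export
superModuleOverlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  100 * length(intersect(a, b)) / min(length(a), length(b))
}

#' Pairwise super-module overlap table
#'
#' @param sms a [SuperModuleSet-class].
#' @return data.frame `supermodule_a`, `supermodule_b`, `overlap_pct`; empty
#'   when there are fewer than two super-modules.
#' @export
superModuleOverlapTable <- function(sms) {
  if (length(sms) < 2L)
    return(data.frame(supermodule_a = character(0),
                      supermodule_b = character(0),
                      overlap_pct = numeric(0)))
  pairs <- utils::combn(sms@ids, 2L)
  data.frame(
    supermodule_a = pairs[1L, ], supermodule_b = pairs[2L, ],
    overlap_pct = apply(pairs, 2L, function(pr)
      superModuleOverlap(sms@nodes[[pr[1L]]], sms@nodes[[pr[2L]]])))
}

#' Per-super-module summary
#'
#' Member modules, node counts and mean per-condition impact of the member
#' modules (from an [ImpactReport-class]).
#'
#' @param sms a [SuperModuleSet-class].
#' @param report the impact report covering the member modules.
#' @return data.frame, one row per super-module.
#' @export
superModuleSummary <- function(sms, report) {
  sc <- report@scores
  impCols <- paste0("impact_", report@conditions)
  rows <- lapply(sms@ids, function(id) {
    ms <- sms@members[[id]]
    sub <- sc[sc$term_id %in% ms, , drop = FALSE]
    out <- data.frame(supermodule_id = id,
                      members = paste(ms, collapse = ","),
                      n_modules = length(ms),
                      n_nodes = length(sms@nodes[[id]]))
    for (cl in impCols)
      out[[paste0("mean_", cl)]] <- mean(sub[[cl]])
    out$mean_overall_impact <- mean(sub$overall_impact)
    out
  })
  do.call(rbind, rows)
}
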