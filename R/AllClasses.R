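#' @import methods
#' @importFrom stats median phyper runif rlnorm rexp rnorm setNames
#' @importFrom utils combn
NULL

#' Per-knockdown profile of altered genes
#'
#' Holds, for one knockdown condition, the set of up-regulated genes, the set
#' of down-regulated genes (both from a differential-expression analysis at
#' adjusted p < 0.05) and the set of genes with altered splicing (FDR < 0.05).
#' The "altered" set used throughout the impact analysis is the union of the
#' three and is obtained with [alteredGenes()].
#'
#' @slot condition single condition label, e.g. `"caz"`.
#' @slot deUp,deDown,asSet character vectors of gene identifiers. `deUp` and
#'   `deDown` must be disjoint.
#' @seealso [knockdownProfile()], [deriveProfile()]
#' @export
setClass("KnockdownProfile",
  representation(condition = "character", deUp = "character",
                 deDown = "character", asSet = "character"))

setValidity("KnockdownProfile", function(object) {
  msg <- character(0)
  if (length(object@condition) != 1L || !nzchar(object@condition))
    msg <- c(msg, "'condition' must be a single non-empty label")
  if (length(intersect(object@deUp, object@deDown)) > 0L)
    msg <- c(msg, "'deUp' and 'deDown' must be disjoint")
  if (anyDuplicated(object@deUp) || anyDuplicated(object@deDown) ||
      anyDuplicated(object@asSet))
    msg <- c(msg, "gene sets must not contain duplicates")
  if (length(msg)) msg else TRUE
})

#' A term-anchored functional module
#'
#' The subgraph of the tissue-specific interaction network induced by the
#' genes annotated to one enriched term, after the isolated-cluster rule
#' (see [extractModule()]). `components` is the partition of the retained
#' nodes into connected components, largest first.
#'
#' @slot termId,termName annotation term identifier and name.
#' @slot nodes character vector of retained gene identifiers.
#' @slot components list of character vectors partitioning `nodes`,
#'   sorted by decreasing size.
#' @export
setClass("FunctionalModule",
  representation(termId = "character", termName = "character",
                 nodes = "character", components = "list"))

setValidity("FunctionalModule", function(object) {
  msg <- character(0)
  if (length(object@termId) != 1L)
    msg <- c(msg, "'termId' must be a single string")
  comp <- unlist(object@components, use.names = FALSE)
  if (!setequal(comp, object@nodes) || length(comp) != length(object@nodes))
    msg <- c(msg, "'components' must partition 'nodes'")
  sizes <- lengths(object@components)
  if (length(sizes) > 1L && any(diff(sizes) > 0))
    msg <- c(msg, "'components' must be sorted by decreasing size")
  if (length(msg)) msg else TRUE
})

#' A library of functional modules
#'
#' An ordered collection of [FunctionalModule-class] objects with unique term
#' identifiers, plus the parameters used to build it.
#'
#' @slot modules list of `FunctionalModule`, named by term id and sorted by
#'   term id.
#' @slot provenance named list of the parameters used by [buildLibrary()].
#' @export
setClass("ModuleLibrary",
  representation(modules = "list", provenance = "list"))

setValidity("ModuleLibrary", function(object) {
  if (length(object@modules) == 0L)
    return(TRUE)
  ids <- vapply(object@modules, function(m) m@termId, character(1))
  msg <- character(0)
  if (anyDuplicated(ids))
    msg <- c(msg, "module term ids must be unique")
  if (!identical(names(object@modules), unname(ids)))
    msg <- c(msg, "'modules' must be named by term id")
  if (is.unsorted(ids))
    msg <- c(msg, "'modules' must be sorted by term id")
  if (length(msg)) msg else TRUE
})

#' Per-module impact report
#'
#' One row per library module with the per-condition impact percentages, the
#' overall impact (their minimum) and the selection flag, plus a per-node
#' annotation table.
#'
#' @slot scores data.frame with columns `term_id`, one `impact_<condition>`
#'   column per knockdown, `overall_impact` and `selected`.
#' @slot nodeAnnotations data.frame with one row per (module, gene) giving the
#'   per-condition DE state (`up`/`down`/`none`), AS flag, and optional bound
#'   and disease flags.
#' @slot conditions condition labels, in score-column order.
#' @slot threshold selection threshold on the overall impact, in percent.
#' @export
setClass("ImpactReport",
  representation(scores = "data.frame", nodeAnnotations = "data.frame",
                 conditions = "character", threshold = "numeric"))

setValidity("ImpactReport", function(object) {
  msg <- character(0)
  need <- c("term_id", paste0("impact_", object@conditions),
            "overall_impact", "selected")
  if (!all(need %in% names(object@scores)))
    msg <- c(msg, "scores is missing required columns")
  if (nrow(object@scores)) {
    imp <- as.matrix(object@scores[paste0("impact_", object@conditions)])
    if (any(abs(object@scores$overall_impact - apply(imp, 1L, min)) > 1e-9))
      msg <- c(msg, "overall_impact must equal the per-condition minimum")
    if (!identical(object@scores$selected,
                   object@scores$overall_impact >= object@threshold))
      msg <- c(msg, "selected flag inconsistent with threshold")
  }
  if (length(msg)) msg else TRUE
})

#' Super-modules: coalesced groups of selected modules
#'
#' Connected components of the module-overlap graph after thresholding on the
#' node-set Jaccard index (see [coalesceSuperModules()]).
#'
#' @slot ids super-module identifiers (derived from the smallest member term
#'   id, so deterministic).
#' @slot members named list (by id) of member module term ids.
#' @slot nodes named list (by id) of the union of member node sets.
#' @export
setClass("SuperModuleSet",
  representation(ids = "character", members = "list", nodes = "list"))

setValidity("SuperModuleSet", function(object) {
  if (length(object@ids) == 0L && length(object@members) == 0L &&
      length(object@nodes) == 0L)
    return(TRUE)
  msg <- character(0)
  if (!identical(names(object@members), object@ids) ||
      !identical(names(object@nodes), object@ids))
    msg <- c(msg, "'members' and 'nodes' must be named by 'ids'")
  mem <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(mem))
    msg <- c(msg, "each module must belong to exactly one super-module")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic benchmark generator
#'
#' All knobs of [generateBenchmark()]. Defaults describe the reference
#' benchmark used throughout the test suite: 2000 genes, 80% expressed, a
#' preferential-attachment interactome of mean degree ~6, 150 annotation
#' terms of which 12 are planted convergently-impacted modules and 15 are
#' "decoy" modules (connected, enriched, but only background-level impact),
#' per-condition planted alteration probability 0.35 against a background
#' rate of 0.08, and RIP/disease label enrichment in planted genes.
#'
#' @seealso [benchmarkConfig()] for the user constructor.
#' @export
setClass("BenchmarkConfig",
  representation(
    nGenes = "integer", fracExpressed = "numeric", meanDegree = "numeric",
    nTerms = "integer", plantedTerms = "integer", decoyTerms = "integer",
    plantedTermSize = "integer", decoyTermSize = "integer",
    plantedImpact = "numeric", backgroundAlterRate = "numeric",
    ripRateInPlanted = "numeric", ripRateBackground = "numeric",
    diseaseRateInPlanted = "numeric", diseaseRateBackground = "numeric",
    satelliteFrac = "numeric", selfLoopFrac = "numeric", seed = "integer"))

setValidity("BenchmarkConfig", function(object) {
  msg <- character(0)
  rates <- c(object@fracExpressed, object@plantedImpact,
             object@backgroundAlterRate, object@ripRateInPlanted,
             object@ripRateBackground, object@diseaseRateInPlanted,
             object@diseaseRateBackground, object@satelliteFrac,
             object@selfLoopFrac)
  if (any(rates < 0) || any(rates > 1))
    msg <- c(msg, "all rates and fractions must lie in [0, 1]")
  if (object@fracExpressed <= 0)
    msg <- c(msg, "'fracExpressed' must be in (0, 1]")
  if (object@plantedTerms + object@decoyTerms > object@nTerms)
    msg <- c(msg, "plantedTerms + decoyTerms must not exceed nTerms")
  if (object@plantedTerms > 0L &&
      object@plantedImpact <= object@backgroundAlterRate)
    msg <- c(msg, "'plantedImpact' must exceed 'backgroundAlterRate'")
  if (object@meanDegree <= 0)
    msg <- c(msg, "'meanDegree' must be positive")
  for (nm in c("plantedTermSize", "decoyTermSize")) {
    rg <- slot(object, nm)
    if (length(rg) != 2L || rg[1L] > rg[2L] || rg[1L] < 1L)
      msg <- c(msg, sprintf("'%s' must be an increasing pair of counts", nm))
  }
  if (length(msg)) msg else TRUE
})

#' A complete synthetic input bundle with ground truth
#'
#' Everything the pipeline consumes — edge list, expression table, flat
#' annotation table, per-condition DEA and splicing tables, per-(protein,
#' compartment) RIP tables and a disease-label table — plus a `truth` list
#' recording the planted structure, so recovery can be scored.
#'
#' @slot edges data.frame (`p1`, `p2`), duplicates and self-loops included on
#'   purpose so the network-cleaning step is exercised.
#' @slot expression data.frame (`gene`, `fpkm`).
#' @slot annotations data.frame (`term_id`, `term_name`, `gene`).
#' @slot dea,splicing named lists (by condition) of data.frames.
#' @slot rip named list (by `<protein>_<compartment>`) of DEA-style tables.
#' @slot disease data.frame (`gene`, `linked`).
#' @slot truth list: planted/decoy/background term ids, planted gene sets
#'   (core and with satellites), per-condition altered sets, bound set,
#'   disease-linked set, expressed set.
#' @slot config the [BenchmarkConfig-class] that produced the bundle.
#' @export
setClass("BenchmarkBundle",
  representation(edges = "data.frame", expression = "data.frame",
                 annotations = "data.frame", dea = "list", splicing = "list",
                 rip = "list", disease = "data.frame", truth = "list",
                 config = "BenchmarkConfig"))

setValidity("BenchmarkBundle", function(object) {
  msg <- character(0)
  universe <- object@expression$gene
  if (!all(object@annotations$gene %in% universe))
    msg <- c(msg, "every annotated gene must exist in the gene universe")
  if (!all(object@truth$plantedTermIds %in% object@annotations$term_id))
    msg <- c(msg, "planted term ids must be annotation term ids")
  if (length(msg)) msg else TRUE
})
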