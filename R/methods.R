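# Constructors, accessors and show methods for the core classes.

#' Construct a knockdown profile
#'
#' @param condition condition label (e.g. `"caz"`, `"Smn"`, `"TBPH"`).
#' @param deUp,deDown,asSet character vectors of gene identifiers: up- and
#'   down-regulated DE genes and genes with altered splicing.
#' @return A [KnockdownProfile-class].
#' @examples
#' p <- knockdownProfile("caz", deUp = "G1", deDown = "G2", asSet = c("G2", "G3"))
#' alteredGenes(p)
#' @export
knockdownProfile <- function(condition, deUp = character(0),
                             deDown = character(0), asSet = character(0)) {
  new("KnockdownProfile", condition = as.character(condition),
      deUp = sort(unique(as.character(deUp))),
      deDown = sort(unique(as.character(deDown))),
      asSet = sort(unique(as.character(asSet))))
}

#' @rdname knockdownProfile
#' @param x a `KnockdownProfile`.
#' @export
setGeneric("alteredGenes", function(x) standardGeneric("alteredGenes"))

#' @describeIn knockdownProfile the altered set: `deUp` union `deDown` union
#'   `asSet` (each gene counted once).
#' @export
setMethod("alteredGenes", "KnockdownProfile", function(x)
  sort(unique(c(x@deUp, x@deDown, x@asSet))))

#' @describeIn knockdownProfile accessors for the component gene sets.
#' @export
deUp <- function(x) x@deUp
#' @rdname knockdownProfile
#' @export
deDown <- function(x) x@deDown
#' @rdname knockdownProfile
#' @export
asSet <- function(x) x@asSet

setMethod("show", "KnockdownProfile", function(object) {
  cat(sprintf("KnockdownProfile '%s': %d up, %d down, %d AS (%d altered)\n",
              object@condition, length(object@deUp), length(object@deDown),
              length(object@asSet), length(alteredGenes(object))))
})

#' Accessors for functional modules
#'
#' @param x a [FunctionalModule-class].
#' @return `termId`/`termName` return the term identifier and name;
#'   `moduleNodes` the retained nodes; `moduleComponents` the connected
#'   components (largest first); `moduleSize` the number of retained nodes.
#' @export
termId <- function(x) x@termId
#' @rdname termId
#' @export
termName <- function(x) x@termName
#' @rdname termId
#' @export
moduleNodes <- function(x) x@nodes
#' @rdname termId
#' @export
moduleComponents <- function(x) x@components
#' @rdname termId
#' @export
moduleSize <- function(x) length(x@nodes)

setMethod("show", "FunctionalModule", function(object) {
  cat(sprintf("FunctionalModule %s ('%s'): %d nodes in %d component(s)\n",
              object@termId, object@termName, length(object@nodes),
              length(object@components)))
})

#' Accessors for a module library
#'
#' A [ModuleLibrary-class] behaves like a named list of modules: `length()`,
#' `names()` and `[[` (by position or term id) are supported.
#'
#' @param x a `ModuleLibrary`.
#' @export
modules <- function(x) x@modules

#' @rdname modules
#' @export
moduleSizes <- function(x)
  vapply(x@modules, moduleSize, integer(1))

#' @rdname modules
#' @export
libraryProvenance <- function(x) x@provenance

setMethod("length", "ModuleLibrary", function(x) length(x@modules))
setMethod("names", "ModuleLibrary", function(x) {
  nm <- names(x@modules)
  if (is.null(nm)) character(0) else nm
})
setMethod("[[", "ModuleLibrary", function(x, i) x@modules[[i]])

setMethod("show", "ModuleLibrary", function(object) {
  sz <- moduleSizes(object)
  cat(sprintf("ModuleLibrary with %d modules", length(object)))
  if (length(object))
    cat(sprintf(" (sizes %d-%d, median %g)", min(sz), max(sz),
                stats::median(sz)))
  cat("\n")
})

#' Accessors for an impact report
#'
#' @param x an [ImpactReport-class].
#' @return `impactScores` returns the per-module score table,
#'   `nodeAnnotations` the per-(module, gene) annotation table.
#' @seealso [impactReport()], [selectModules()]
#' @export
impactScores <- function(x) x@scores

#' @rdname impactScores
#' @export
nodeAnnotations <- function(x) x@nodeAnnotations

setMethod("show", "ImpactReport", function(object) {
  cat(sprintf(
    "ImpactReport: %d modules, %d selected at overall impact >= %g%%\n",
    nrow(object@scores), sum(object@scores$selected), object@threshold))
})

#' Accessors for super-module sets
#'
#' @param x a [SuperModuleSet-class].
#' @export
superModuleIds <- function(x) x@ids
#' @rdname superModuleIds
#' @export
superModuleMembers <- function(x) x@members
#' @rdname superModuleIds
#' @export
superModuleNodes <- function(x) x@nodes

setMethod("length", "SuperModuleSet", function(x) length(x@ids))

setMethod("show", "SuperModuleSet", function(object) {
  cat(sprintf("SuperModuleSet: %d super-modules (%s modules; %s nodes)\n",
              length(object@ids),
              paste(lengths(object@members), collapse = "/"),
              paste(lengths(object@nodes), collapse = "/")))
})
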