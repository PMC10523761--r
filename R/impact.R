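# Module impact scoring. The impact of one knockdown on one module is the
# percentage of module nodes whose transcript is altered (DE in either
# direction, or AS) in that condition; the overall impact is the minimum over
# conditions — a module with overall impact X% has at least X% of its nodes
# affected in every knockdown. Selection is inclusive at >= 20%.

#' Impact of one knockdown on one module
#'
#' @param module a [FunctionalModule-class] (or a character vector of nodes).
#' @param profile a [KnockdownProfile-class].
#' @return percentage in \[0, 100\]: `100 * |nodes & altered| / |nodes|`.
#' @export
moduleImpact <- function(module, profile) {
  nodes <- if (is(module, "FunctionalModule")) moduleNodes(module)
           else as.character(module)
  if (length(nodes) == 0L)
    stop("cannot score an empty module")
  100 * length(intersect(nodes, alteredGenes(profile))) / length(nodes)
}

#' Overall impact: the weakest-condition impact
#'
#' @param impacts numeric vector of per-condition impact percentages.
#' @return the minimum impact.
#' @export
overallImpact <- function(impacts) {
  if (length(impacts) == 0L)
    stop("at least one condition is required")
  min(impacts)
}

#' Score a module library against all knockdowns
#'
#' Computes every module's per-condition impact, overall impact and selection
#' flag, plus a per-node annotation table recording each node's DE direction
#' and AS status per condition and, when supplied, whether it is bound in any
#' RIP experiment or linked to disease.
#'
#' @param lib a [ModuleLibrary-class].
#' @param profiles named list of [KnockdownProfile-class], one per condition.
#' @param threshold selection threshold on the overall impact, in percent;
#'   inclusive, default 20.
#' @param boundSets optional list of bound gene sets (pooled by union for the
#'   `bound` flag).
#' @param disease optional disease data.frame (`gene`, `linked`); genes
#'   absent from it count as not linked.
#' @return an [ImpactReport-class].
#' @export
impactReport <- function(lib, profiles, threshold = 20, boundSets = NULL,
                         disease = NULL) {
  stopifnot(is(lib, "ModuleLibrary"), length(profiles) >= 1L)
  conds <- vapply(profiles, function(p) p@condition, character(1))
  names(profiles) <- conds
  ids <- names(lib)

  imp <- matrix(NA_real_, nrow = length(ids), ncol = length(conds),
                dimnames = list(ids, paste0("impact_", conds)))
  for (j in seq_along(profiles))
    imp[, j] <- vapply(ids, function(id)
      moduleImpact(lib[[id]], profiles[[j]]), numeric(1))
  overall <- if (length(ids)) apply(imp, 1L, min) else numeric(0)

  scores <- data.frame(term_id = ids, imp, overall_impact = overall,
                       selected = overall >= threshold,
                       row.names = NULL, check.names = FALSE)

  ann <- do.call(rbind, lapply(ids, function(id) {
    nodes <- moduleNodes(lib[[id]])
    df <- data.frame(term_id = id, gene = nodes)
    for (cn in conds) {
      p <- profiles[[cn]]
      state <- rep("none", length(nodes))
      state[nodes %in% p@deUp] <- "up"
      state[nodes %in% p@deDown] <- "down"
      df[[paste0("de_", cn)]] <- state
      df[[paste0("as_", cn)]] <- nodes %in% p@asSet
    }
    df$n_conditions_altered <- rowSums(
      vapply(conds, function(cn) nodes %in% alteredGenes(profiles[[cn]]),
             logical(length(nodes))))
    if (!is.null(boundSets))
      df$bound <- nodes %in% unique(unlist(boundSets, use.names = FALSE))
    if (!is.null(disease))
      df$linked <- nodes %in% disease$gene[disease$linked]
    df
  }))
  if (is.null(ann))
    ann <- data.frame(term_id = character(0), gene = character(0))

  new("ImpactReport", scores = scores, nodeAnnotations = ann,
      conditions = unname(conds), threshold = threshold)
}

#' Select modules by overall impact
#'
#' @param report an [ImpactReport-class].
#' @param threshold overrides the report's threshold when given; selection is
#'   inclusive (`overall_impact >= threshold`).
#' @return character vector of selected module term ids.
#' @export
selectModules <- function(report, threshold = NULL) {
  if (is.null(threshold))
    threshold <- report@threshold
  report@scores$term_id[report@scores$overall_impact >= threshold]
}
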