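# End-to-end orchestration: read every input table from a directory, run the
# stages in order (gene sets -> networks -> enrichment -> module library ->
# impact -> super-modules -> association statistics) and write deterministic
# TSV outputs. All thresholds default to the analysis' reference values and
# every run is self-describing through its summary table.

#' Pipeline configuration
#'
#' @param fpkmThreshold expression universe cut-off (FPKM, strict), default 1.
#' @param deAlpha,asAlpha,ripAlpha significance levels for DE, AS and RIP
#'   calls (strict), default 0.05.
#' @param nRand enrichment randomizations, default 1000.
#' @param enrichFdr enrichment FDR threshold, default 0.1.
#' @param minSize,maxSize inclusive module size window, defaults 10 and 100.
#' @param keepFraction isolated-cluster rule threshold, default 0.9.
#' @param impactThreshold overall-impact selection threshold in percent
#'   (inclusive), default 20.
#' @param minJaccard super-module coalescing threshold, default 0.2.
#' @param seed seed for the enrichment randomizations, default 1.
#' @return a named list of validated parameters.
#' @export
pipelineConfig <- function(fpkmThreshold = 1, deAlpha = 0.05,
                           asAlpha = 0.05, ripAlpha = 0.05, nRand = 1000,
                           enrichFdr = 0.1, minSize = 10, maxSize = 100,
                           keepFraction = 0.9, impactThreshold = 20,
                           minJaccard = 0.2, seed = 1) {
  cfg <- list(fpkmThreshold = fpkmThreshold, deAlpha = deAlpha,
              asAlpha = asAlpha, ripAlpha = ripAlpha, nRand = nRand,
              enrichFdr = enrichFdr, minSize = minSize, maxSize = maxSize,
              keepFraction = keepFraction,
              impactThreshold = impactThreshold, minJaccard = minJaccard,
              seed = seed)
  stopifnot(all(vapply(cfg, is.numeric, logical(1))),
            all(c(deAlpha, asAlpha, ripAlpha, enrichFdr) > 0),
            all(c(deAlpha, asAlpha, ripAlpha, enrichFdr) <= 1),
            keepFraction > 0, keepFraction <= 1, minSize <= maxSize,
            nRand >= 1, minJaccard >= 0, minJaccard <= 1)
  cfg
}

pipelineInputs <- function(inputDir) {
  all_ <- list.files(inputDir)
  need <- c("edges.tsv", "expression.tsv", "annotation.tsv", "disease.tsv")
  miss <- setdiff(need, all_)
  if (length(miss))
    stop("missing pipeline input file(s): ", paste(miss, collapse = ", "))
  deaFiles <- sort(grep("^dea_.*\\.tsv$", all_, value = TRUE))
  if (!length(deaFiles))
    stop("no dea_<condition>.tsv files found in ", inputDir)
  conds <- sub("^dea_(.*)\\.tsv$", "\\1", deaFiles)
  spliceFiles <- sprintf("splicing_%s.tsv", conds)
  miss <- setdiff(spliceFiles, all_)
  if (length(miss))
    stop("missing splicing table(s): ", paste(miss, collapse = ", "))
  list(conditions = conds,
       ripFiles = sort(grep("^rip_.*\\.tsv$", all_, value = TRUE)))
}

#' Run the full analysis pipeline on a directory of input tables
#'
#' Expects the file layout written by [writeBenchmark()]: `edges.tsv`,
#' `expression.tsv`, `annotation.tsv`, `disease.tsv`, one `dea_<cond>.tsv` +
#' `splicing_<cond>.tsv` pair per knockdown and any number of
#' `rip_<label>.tsv` tables. Stages run in order; a failing stage aborts the
#' run with its name, and partial outputs are removed. Outputs (all TSV,
#' byte-deterministic given config and seed): `summary.tsv`,
#' `enrichment.tsv`, `modules.tsv`, `redundancy.tsv`, `impact.tsv`,
#' `node_annotations.tsv`, `supermodules.tsv`, `supermodule_overlap.tsv`,
#' `stats.tsv`, `intersections.tsv`.
#'
#' The association stage computes the disease-ortholog Wilcoxon comparison of
#' selected versus non-selected modules, the RIP-target prevalence chi-square
#' comparisons across module-membership groups, and exact multi-set
#' intersection tests of the per-condition altered sets over the expression
#' universe. Comparisons whose groups are empty are reported as skipped
#' rather than computed.
#'
#' @param inputDir directory with the input tables.
#' @param outDir output directory, created if needed.
#' @param config list from [pipelineConfig()].
#' @return (invisibly) a list with every intermediate object: `universe`,
#'   `profiles`, `network`, `tissueNetwork`, `enrichment`, `library`,
#'   `report`, `superModules`, `stats`, `summary`.
#' @export
runPipeline <- function(inputDir, outDir, config = pipelineConfig()) {
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  stage <- "setup"
  res <- tryCatch(
    runPipelineImpl(inputDir, outDir, config,
                    note = function(s) stage <<- s,
                    track = function(f) written <<- c(written, f)),
    error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  ok <- TRUE
  invisible(res)
}

runPipelineImpl <- function(inputDir, outDir, config, note, track) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outDir, x)
  log <- list()
  say <- function(stageName, key, value)
    log[[length(log) + 1L]] <<- data.frame(stage = stageName, key = key,
                                           value = as.character(value))

  note("read_inputs")
  layout <- pipelineInputs(inputDir)
  conds <- layout$conditions
  edges <- readEdgeList(file.path(inputDir, "edges.tsv"))
  expr <- readTable(file.path(inputDir, "expression.tsv"), "expression")
  ann <- readTable(file.path(inputDir, "annotation.tsv"), "annotation")
  disease <- readTable(file.path(inputDir, "disease.tsv"), "disease")
  dea <- lapply(conds, function(cond)
    readTable(file.path(inputDir, sprintf("dea_%s.tsv", cond)), "dea"))
  names(dea) <- conds
  splicing <- lapply(conds, function(cond)
    readTable(file.path(inputDir, sprintf("splicing_%s.tsv", cond)),
              "splicing"))
  names(splicing) <- conds
  rip <- lapply(layout$ripFiles, function(f)
    readTable(file.path(inputDir, f), "dea"))
  names(rip) <- sub("^rip_(.*)\\.tsv$", "\\1", layout$ripFiles)
  say("read_inputs", "conditions", paste(conds, collapse = ","))
  say("read_inputs", "edge_rows", nrow(edges))
  say("read_inputs", "genes", nrow(expr))
  say("read_inputs", "annotation_terms", length(unique(ann$term_id)))
  for (p in names(config))
    say("config", p, config[[p]])

  note("gene_sets")
  universe <- neuronalUniverse(expr, config$fpkmThreshold)
  profiles <- lapply(conds, function(cond)
    deriveProfile(cond, dea[[cond]], splicing[[cond]], universe,
                  deAlpha = config$deAlpha, asAlpha = config$asAlpha))
  names(profiles) <- conds
  boundSets <- lapply(rip, function(tab)
    restrictToUniverse(callBound(tab, config$ripAlpha), universe))
  boundAll <- sort(unique(unlist(boundSets, use.names = FALSE)))
  say("gene_sets", "universe_size", length(universe))
  for (cond in conds)
    say("gene_sets", paste0("altered_", cond),
        length(alteredGenes(profiles[[cond]])))
  say("gene_sets", "bound_union", length(boundAll))

  note("network_builder")
  net <- buildNetwork(edges, label = "unspecific")
  tissueNet <- filterByUniverse(net, universe, label = "tissue")
  for (nm in c("unspecific", "tissue")) {
    s <- networkSummary(if (nm == "unspecific") net else tissueNet)
    for (k in c("n_nodes", "n_edges", "n_components"))
      say("network_builder", paste(nm, k, sep = "_"), s[[k]])
  }

  note("enrichment")
  enr <- runEnrichment(candidate = igraph::V(tissueNet)$name,
                       background = igraph::V(net)$name,
                       annotations = ann, nRand = config$nRand,
                       fdrThreshold = config$enrichFdr, seed = config$seed)
  say("enrichment", "terms_tested", nrow(enr))
  say("enrichment", "terms_enriched", sum(enr$enriched))

  note("module_library")
  lib <- buildLibrary(enr, ann, tissueNet, minSize = config$minSize,
                      maxSize = config$maxSize,
                      keepFraction = config$keepFraction)
  say("module_library", "modules", length(lib))

  note("impact")
  report <- impactReport(lib, profiles, threshold = config$impactThreshold,
                         boundSets = boundSets, disease = disease)
  selected <- selectModules(report)
  say("impact", "selected_modules", length(selected))

  note("supermodules")
  if (length(selected)) {
    og <- buildOverlapGraph(lib, selected, profiles)
    sms <- coalesceSuperModules(og, lib, minJaccard = config$minJaccard)
    smSummary <- superModuleSummary(sms, report)
    smOverlap <- superModuleOverlapTable(sms)
  } else {
    sms <- new("SuperModuleSet", ids = character(0), members = list(),
               nodes = list())
    smSummary <- data.frame(supermodule_id = character(0),
                            members = character(0), n_modules = integer(0),
                            n_nodes = integer(0))
    smOverlap <- superModuleOverlapTable(sms)
  }
  say("supermodules", "supermodules", length(sms))

  note("assoc_stats")
  statsRows <- list()
  addStat <- function(test, groups, statistic, p, noteTxt = "") {
    statsRows[[length(statsRows) + 1L]] <<- data.frame(
      test = test, groups = groups, statistic = statistic, p = p,
      note = noteTxt)
  }
  rest <- setdiff(names(lib), selected)
  if (length(selected) && length(rest)) {
    wt <- compareSelectedVsRest(lib, selected, disease)
    addStat("wilcoxon_disease_fraction", "selected_vs_nonselected",
            wt$statistic, wt$p)
  } else {
    addStat("wilcoxon_disease_fraction", "selected_vs_nonselected",
            NA_real_, NA_real_, "skipped: empty group")
  }

  alteredAll <- sort(unique(unlist(lapply(profiles, alteredGenes),
                                   use.names = FALSE)))
  selNodes <- sort(unique(unlist(lapply(selected, function(id)
    moduleNodes(lib[[id]])), use.names = FALSE)))
  restNodes <- setdiff(
    sort(unique(unlist(lapply(rest, function(id) moduleNodes(lib[[id]])),
                       use.names = FALSE))), selNodes)
  groups <- list(
    selected_modules = intersect(alteredAll, selNodes),
    nonselected_modules = intersect(alteredAll, restNodes),
    no_module = setdiff(alteredAll, union(selNodes, restNodes)))
  prevalence <- ripPrevalence(groups, boundAll)
  for (i in seq_len(nrow(prevalence$fractions))) {
    fr <- prevalence$fractions[i, ]
    addStat("rip_bound_fraction", fr$group, fr$fraction_pct, NA_real_,
            if (fr$n == 0) "skipped: empty group" else
              sprintf("n=%d bound=%d", fr$n, fr$n_bound))
  }
  for (i in seq_len(nrow(prevalence$tests))) {
    ts <- prevalence$tests[i, ]
    addStat("chi2_rip_prevalence", paste(ts$group_a, ts$group_b, sep = "_vs_"),
            ts$chi2, ts$p)
  }

  interRows <- list()
  if (length(conds) >= 2L) {
    sets <- lapply(profiles, alteredGenes)
    combos <- unlist(lapply(2:length(conds), function(k)
      utils::combn(conds, k, simplify = FALSE)), recursive = FALSE)
    for (cmb in combos) {
      obs <- length(Reduce(intersect, sets[cmb]))
      sizes <- lengths(sets[cmb])
      Nuniv <- length(universe)
      expct <- multisetExpected(Nuniv, sizes)
      pval <- multisetIntersectionP(Nuniv, sizes, obs)
      interRows[[length(interRows) + 1L]] <- data.frame(
        sets = paste(cmb, collapse = "&"),
        universe = Nuniv, observed = obs, expected = expct,
        fold = if (expct > 0) obs / expct else NA_real_, p_upper = pval)
    }
  }
  intersections <- if (length(interRows)) do.call(rbind, interRows) else
    data.frame(sets = character(0), universe = integer(0),
               observed = integer(0), expected = numeric(0),
               fold = numeric(0), p_upper = numeric(0))
  statsTab <- do.call(rbind, statsRows)

  note("write_outputs")
  out <- list(
    summary.tsv = do.call(rbind, log),
    enrichment.tsv = enr,
    modules.tsv = lib,
    impact.tsv = report,
    node_annotations.tsv = report@nodeAnnotations,
    supermodules.tsv = smSummary,
    supermodule_overlap.tsv = smOverlap,
    stats.tsv = statsTab,
    intersections.tsv = intersections)
  if (length(lib) >= 2L)
    out$redundancy.tsv <- redundancyMatrix(lib)
  for (nm in names(out)) {
    track(fp(nm))
    if (identical(nm, "summary.tsv") || identical(nm, "stats.tsv") ||
        identical(nm, "intersections.tsv"))
      writeTable(out[[nm]], fp(nm), sortBy = NULL)
    else
      writeReport(out[[nm]], fp(nm))
  }

  invisible(list(universe = universe, profiles = profiles,
                 boundSets = boundSets, network = net,
                 tissueNetwork = tissueNet, enrichment = enr, library = lib,
                 report = report, selected = selected, superModules = sms,
                 superModuleSummary = smSummary,
                 superModuleOverlap = smOverlap, stats = statsTab,
                 intersections = intersections,
                 summary = do.call(rbind, log), disease = disease))
}

#' Extract the altered-node subnetwork of a super-module
#'
#' Induces the tissue network on the super-module nodes altered in at least
#' one condition and drops nodes without any edge to another altered node, so
#' only proteins directly interacting with other DE/AS-encoded proteins
#' remain. Each kept node is annotated with the number of conditions in which
#' it is altered, its per-condition DE direction (kept separate across
#' knockdowns, so discordant changes stay visible) and AS flag, and optional
#' bound/disease flags.
#'
#' @param nodes character vector of super-module nodes (one element of
#'   [superModuleNodes()]).
#' @param net tissue `igraph` network.
#' @param profiles named list of [KnockdownProfile-class].
#' @param boundSets optional list of bound sets (pooled by union).
#' @param disease optional disease data.frame.
#' @return list with `edges` (data.frame `p1`, `p2`) and `nodes` (annotation
#'   data.frame); both empty when no altered node has an altered neighbour.
#' @export
extractAlteredSubnetwork <- function(nodes, net, profiles, boundSets = NULL,
                                     disease = NULL) {
  alteredAll <- unique(unlist(lapply(profiles, alteredGenes),
                              use.names = FALSE))
  keep <- intersect(intersect(nodes, alteredAll), igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, keep)
  sub <- igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
  vn <- igraph::V(sub)$name
  el <- igraph::as_edgelist(sub)
  edges <- if (nrow(el)) data.frame(p1 = pmin(el[, 1L], el[, 2L]),
                                    p2 = pmax(el[, 1L], el[, 2L]))
           else data.frame(p1 = character(0), p2 = character(0))
  edges <- edges[order(edges$p1, edges$p2), , drop = FALSE]
  rownames(edges) <- NULL

  vn <- sort(vn)
  df <- data.frame(gene = vn)
  for (cond in names(profiles)) {
    p <- profiles[[cond]]
    state <- rep("none", length(vn))
    state[vn %in% p@deUp] <- "up"
    state[vn %in% p@deDown] <- "down"
    df[[paste0("de_", cond)]] <- state
    df[[paste0("as_", cond)]] <- vn %in% p@asSet
  }
  df$n_conditions_altered <- if (length(vn)) rowSums(vapply(
    names(profiles), function(cond)
      vn %in% alteredGenes(profiles[[cond]]), logical(length(vn))))
    else integer(0)
  if (!is.null(boundSets))
    df$bound <- vn %in% unique(unlist(boundSets, use.names = FALSE))
  if (!is.null(disease))
    df$linked <- vn %in% disease$gene[disease$linked]
  list(edges = edges, nodes = df)
}
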