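# Seeded synthetic benchmark with planted structure. The generator emulates
# the study conditions the pipeline targets: a heavy-tailed interactome over
# mostly-expressed genes, a flat term-annotation table in which some terms are
# planted as connected, convergently impacted modules, three knockdown
# profiles, per-(protein, compartment) RIP tables and disease labels enriched
# in planted genes. Everything is drawn from a single seeded generator, and
# the `truth` slot records what was planted so recovery can be scored.

#' Construct a benchmark configuration
#'
#' Defaults define the reference benchmark (see
#' [BenchmarkConfig-class]). Term classes: `plantedTerms` connected expressed
#' subgraphs with per-condition alteration probability `plantedImpact` plus
#' elevated RIP/disease rates; `decoyTerms` connected expressed subgraphs
#' (hence enriched in the tissue network) left at background rates, which
#' populate the non-selected side of the library; the remaining terms are
#' random gene sets with sizes log-uniform in \[5, 150\].
#'
#' @param nGenes number of genes in the universe.
#' @param fracExpressed fraction of genes expressed above 1 FPKM.
#' @param meanDegree target mean degree of the expressed interactome.
#' @param nTerms total number of annotation terms.
#' @param plantedTerms,decoyTerms counts of planted / decoy terms.
#' @param plantedTermSize,decoyTermSize inclusive size ranges (length-2).
#' @param plantedImpact per-condition alteration probability of a
#'   planted-term gene; must exceed `backgroundAlterRate` by a margin above
#'   the 20% selection threshold.
#' @param backgroundAlterRate per-condition alteration probability of any
#'   other gene.
#' @param ripRateInPlanted,ripRateBackground binding probability of an
#'   altered planted gene / any other gene.
#' @param diseaseRateInPlanted,diseaseRateBackground disease-link probability
#'   of a planted-term gene / any other gene.
#' @param satelliteFrac fraction of planted terms receiving one disconnected
#'   satellite gene, to exercise the isolated-cluster rule.
#' @param selfLoopFrac fraction of genes given a self-loop in the raw edge
#'   list, to exercise network cleaning.
#' @param seed integer seed; identical configurations generate identical
#'   bundles.
#' @return a validated [BenchmarkConfig-class].
#' @export
benchmarkConfig <- function(nGenes = 2000, fracExpressed = 0.8,
                            meanDegree = 6, nTerms = 150, plantedTerms = 12,
                            decoyTerms = 15, plantedTermSize = c(40, 80),
                            decoyTermSize = c(25, 50), plantedImpact = 0.35,
                            backgroundAlterRate = 0.08,
                            ripRateInPlanted = 0.35,
                            ripRateBackground = 0.15,
                            diseaseRateInPlanted = 0.30,
                            diseaseRateBackground = 0.05,
                            satelliteFrac = 0.25, selfLoopFrac = 0.05,
                            seed = 1) {
  new("BenchmarkConfig", nGenes = as.integer(nGenes),
      fracExpressed = fracExpressed, meanDegree = meanDegree,
      nTerms = as.integer(nTerms), plantedTerms = as.integer(plantedTerms),
      decoyTerms = as.integer(decoyTerms),
      plantedTermSize = as.integer(plantedTermSize),
      decoyTermSize = as.integer(decoyTermSize),
      plantedImpact = plantedImpact,
      backgroundAlterRate = backgroundAlterRate,
      ripRateInPlanted = ripRateInPlanted,
      ripRateBackground = ripRateBackground,
      diseaseRateInPlanted = diseaseRateInPlanted,
      diseaseRateBackground = diseaseRateBackground,
      satelliteFrac = satelliteFrac, selfLoopFrac = selfLoopFrac,
      seed = as.integer(seed))
}

benchmarkConditions <- c("caz", "Smn", "TBPH")
benchmarkCompartments <- c("nuclear", "cytoplasmic")

# Breadth-first growth of a connected gene set of the requested size within
# the subgraph induced on `available`; NULL when no component is big enough.
growConnectedSet <- function(gExpr, available, size) {
  sub <- igraph::induced_subgraph(gExpr, available)
  comp <- igraph::components(sub)
  big <- which(comp$csize >= size)
  if (length(big) == 0L)
    return(NULL)
  cand <- which(comp$membership %in% big)
  start <- cand[sample.int(length(cand), 1L)]
  al <- igraph::as_adj_list(sub)
  seen <- logical(length(al))
  seen[start] <- TRUE
  queue <- start
  ordv <- integer(0)
  while (length(queue) && length(ordv) < size) {
    v <- queue[1L]
    queue <- queue[-1L]
    ordv <- c(ordv, v)
    nb <- as.integer(al[[v]])
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  igraph::V(sub)$name[ordv]
}

#' Generate a synthetic benchmark bundle
#'
#' See [benchmarkConfig()] for the planted structure. Generation order (all
#' draws from one seeded generator): expressed set and FPKM values; the
#' expressed preferential-attachment interactome plus wired-in non-expressed
#' genes, self-loops and duplicated reversed pairs; planted, decoy and
#' background terms; per-condition alteration calls and DEA/splicing values;
#' RIP binding and tables; disease labels. Planted (and decoy) terms are
#' grown breadth-first so that they induce connected subgraphs of the
#' expressed network; planted terms are mutually disjoint and decoys avoid
#' planted genes, while decoys may overlap each other.
#'
#' @param config a [BenchmarkConfig-class].
#' @return a [BenchmarkBundle-class].
#' @examples
#' b <- generateBenchmark(benchmarkConfig(nGenes = 300, nTerms = 20,
#'   plantedTerms = 2, decoyTerms = 2, plantedTermSize = c(10, 15),
#'   decoyTermSize = c(10, 15), seed = 7))
#' length(bundleTruth(b)$plantedTermIds)
#' @export
generateBenchmark <- function(config) {
  stopifnot(is(config, "BenchmarkConfig"))
  validObject(config)
  withSeed(config@seed, generateBenchmarkImpl(config))
}

generateBenchmarkImpl <- function(config) {
  n <- config@nGenes
  genes <- sprintf("G%05d", seq_len(n))
  nExpr <- round(config@fracExpressed * n)
  expressed <- sort(sample(genes, nExpr))
  nonExpressed <- setdiff(genes, expressed)

  # expression: expressed genes log-normal (median ~ e^3 = 20 FPKM),
  # truncated to > 1 so the expressed set and the FPKM > 1 universe coincide;
  # non-expressed genes uniform in (0, 1].
  fpkm <- stats::setNames(numeric(n), genes)
  v <- stats::rlnorm(nExpr, meanlog = 3, sdlog = 1)
  while (any(v <= 1))
    v[v <= 1] <- stats::rlnorm(sum(v <= 1), meanlog = 3, sdlog = 1)
  fpkm[expressed] <- v
  fpkm[nonExpressed] <- stats::runif(length(nonExpressed))
  expression <- data.frame(gene = genes, fpkm = unname(fpkm[genes]))

  # interactome: preferential attachment over expressed genes, then wire in
  # the non-expressed genes with 1-2 degree-weighted edges each
  m <- max(1L, round(config@meanDegree / 2))
  gPa <- igraph::sample_pa(nExpr, m = m, directed = FALSE)
  el <- igraph::as_edgelist(gPa, names = FALSE)
  exprEdges <- data.frame(p1 = expressed[el[, 1L]], p2 = expressed[el[, 2L]])
  gExpr <- igraph::graph_from_data_frame(exprEdges, directed = FALSE,
                                         vertices = expressed)
  edges <- exprEdges
  if (length(nonExpressed)) {
    deg <- igraph::degree(gPa)
    kAttach <- sample(1:2, length(nonExpressed), replace = TRUE)
    targets <- sample(expressed, sum(kAttach), replace = TRUE, prob = deg)
    edges <- rbind(edges, data.frame(p1 = rep(nonExpressed, kAttach),
                                     p2 = targets))
  }
  nLoop <- round(config@selfLoopFrac * n)
  if (nLoop > 0) {
    loops <- sample(genes, nLoop)
    edges <- rbind(edges, data.frame(p1 = loops, p2 = loops))
  }
  nDup <- max(1L, round(0.02 * nrow(edges)))
  dupIdx <- sample.int(nrow(edges), nDup)
  edges <- rbind(edges, data.frame(p1 = edges$p2[dupIdx],
                                   p2 = edges$p1[dupIdx]))

  # terms
  nBackground <- config@nTerms - config@plantedTerms - config@decoyTerms
  termIds <- sprintf("T%04d", seq_len(config@nTerms))
  plantedIds <- termIds[seq_len(config@plantedTerms)]
  decoyIds <- termIds[config@plantedTerms + seq_len(config@decoyTerms)]
  backgroundIds <- setdiff(termIds, c(plantedIds, decoyIds))

  available <- expressed
  plantedCore <- list()
  plantedGenesByTerm <- list()
  nSat <- ceiling(config@satelliteFrac * config@plantedTerms)
  satTerms <- if (config@plantedTerms)
    sample(plantedIds, nSat) else character(0)
  for (id in plantedIds) {
    size <- sample(seq(config@plantedTermSize[1L], config@plantedTermSize[2L]),
                   1L)
    core <- growConnectedSet(gExpr, available, size)
    if (is.null(core))
      stop("generation error: no connected component of size ", size,
           " left for a planted term; increase meanDegree or nGenes, or ",
           "reduce planted term sizes/counts")
    available <- setdiff(available, core)
    members <- core
    if (id %in% satTerms) {
      # satellite: expressed, unused, and not adjacent to the core, so it is
      # an isolated singleton in the induced module subgraph
      nbh <- igraph::V(gExpr)$name[unique(as.integer(unlist(
        igraph::adjacent_vertices(gExpr, core))))]
      cand <- setdiff(available, nbh)
      if (length(cand)) {
        sat <- cand[sample.int(length(cand), 1L)]
        available <- setdiff(available, sat)
        members <- c(members, sat)
      }
    }
    plantedCore[[id]] <- sort(core)
    plantedGenesByTerm[[id]] <- sort(members)
  }
  plantedGenes <- sort(unique(unlist(plantedGenesByTerm, use.names = FALSE)))

  decoyPool <- setdiff(expressed, plantedGenes)
  decoyGenesByTerm <- list()
  for (id in decoyIds) {
    size <- sample(seq(config@decoyTermSize[1L], config@decoyTermSize[2L]),
                   1L)
    memb <- growConnectedSet(gExpr, decoyPool, size)
    if (is.null(memb))
      stop("generation error: no connected component of size ", size,
           " left for a decoy term; increase meanDegree or nGenes")
    decoyGenesByTerm[[id]] <- sort(memb)
  }

  backgroundGenesByTerm <- list()
  for (id in backgroundIds) {
    size <- round(exp(stats::runif(1, log(5), log(150))))
    backgroundGenesByTerm[[id]] <- sort(sample(genes, size))
  }

  allTerms <- c(plantedGenesByTerm, decoyGenesByTerm, backgroundGenesByTerm)
  allTerms <- allTerms[termIds[termIds %in% names(allTerms)]]
  annotations <- data.frame(
    term_id = rep(names(allTerms), lengths(allTerms)),
    term_name = rep(sprintf("biological process %s",
                            sub("^T", "", names(allTerms))),
                    lengths(allTerms)),
    gene = unlist(allTerms, use.names = FALSE))
  annotations <- annotations[order(annotations$term_id, annotations$gene), ]
  rownames(annotations) <- NULL

  # knockdowns: per condition, planted genes altered with plantedImpact,
  # others with backgroundAlterRate; altered genes are DE-up / DE-down /
  # AS-only with probabilities 0.4 / 0.4 / 0.2
  pAlter <- ifelse(genes %in% plantedGenes, config@plantedImpact,
                   config@backgroundAlterRate)
  dea <- list()
  splicing <- list()
  truthAltered <- list()
  truthType <- list()
  for (cond in benchmarkConditions) {
    altered <- stats::runif(n) < pAlter
    type <- rep("none", n)
    type[altered] <- sample(c("up", "down", "as"), sum(altered),
                            replace = TRUE, prob = c(0.4, 0.4, 0.2))
    lfc <- stats::rnorm(n, 0, 0.2)
    padj <- stats::runif(n, 0.05, 1)
    fdr <- stats::runif(n, 0.05, 1)
    isUp <- type == "up"
    isDown <- type == "down"
    isAs <- type == "as"
    lfc[isUp] <- stats::rexp(sum(isUp)) + 0.1
    lfc[isDown] <- -(stats::rexp(sum(isDown)) + 0.1)
    padj[isUp | isDown] <- stats::runif(sum(isUp | isDown), 0, 0.05)
    fdr[isAs] <- stats::runif(sum(isAs), 0, 0.05)
    dea[[cond]] <- data.frame(gene = genes, log2fc = lfc, padj = padj)
    splicing[[cond]] <- data.frame(gene = genes, fdr = fdr)
    truthAltered[[cond]] <- genes[altered]
    truthType[[cond]] <- type
  }

  # RIP: altered planted genes bound with ripRateInPlanted, everything else
  # with ripRateBackground; a bound gene shows positive enrichment in one
  # randomly chosen (protein, compartment) table
  alteredAny <- sort(unique(unlist(truthAltered, use.names = FALSE)))
  pBound <- ifelse(genes %in% intersect(plantedGenes, alteredAny),
                   config@ripRateInPlanted, config@ripRateBackground)
  boundFlag <- stats::runif(n) < pBound
  ripNames <- as.vector(outer(benchmarkConditions, benchmarkCompartments,
                              paste, sep = "_"))
  ripAssign <- sample(ripNames, n, replace = TRUE)
  rip <- list()
  for (nm in ripNames) {
    lfc <- stats::rnorm(n, 0, 0.5)
    padj <- stats::runif(n, 0.05, 1)
    hit <- boundFlag & ripAssign == nm
    lfc[hit] <- stats::rexp(sum(hit)) + 0.1
    padj[hit] <- stats::runif(sum(hit), 0, 0.05)
    rip[[nm]] <- data.frame(gene = genes, log2fc = lfc, padj = padj)
  }

  pLinked <- ifelse(genes %in% plantedGenes, config@diseaseRateInPlanted,
                    config@diseaseRateBackground)
  linkedFlag <- stats::runif(n) < pLinked
  disease <- data.frame(gene = genes, linked = linkedFlag)

  truth <- list(
    plantedTermIds = plantedIds, decoyTermIds = decoyIds,
    backgroundTermIds = backgroundIds,
    plantedCore = plantedCore, plantedGenes = plantedGenesByTerm,
    altered = truthAltered, alterType = truthType,
    bound = genes[boundFlag], linked = genes[linkedFlag],
    expressed = expressed)

  new("BenchmarkBundle", edges = edges, expression = expression,
      annotations = annotations, dea = dea, splicing = splicing, rip = rip,
      disease = disease, truth = truth, config = config)
}

#' Access the ground truth of a benchmark bundle
#'
#' @param bundle a [BenchmarkBundle-class].
#' @return the `truth` list (see [BenchmarkBundle-class]).
#' @export
bundleTruth <- function(bundle) bundle@truth

#' Write a benchmark bundle to a directory
#'
#' Writes every input table under its pipeline file name (`edges.tsv`,
#' `expression.tsv`, `annotation.tsv`, `dea_<condition>.tsv`,
#' `splicing_<condition>.tsv`, `rip_<protein>_<compartment>.tsv`,
#' `disease.tsv`) plus `truth.tsv` (term id, class). The edge list is written
#' unsorted and uncollapsed, duplicates and self-loops included, as an
#' APID-style export would be.
#'
#' @param bundle a [BenchmarkBundle-class].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeBenchmark <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  con <- file(fp("edges.tsv"), open = "wb")
  writeLines(c("#p1\tp2",
               paste(bundle@edges$p1, bundle@edges$p2, sep = "\t")),
             con, sep = "\n")
  close(con)
  writeTable(bundle@expression, fp("expression.tsv"))
  writeTable(bundle@annotations, fp("annotation.tsv"))
  for (cond in names(bundle@dea))
    writeTable(bundle@dea[[cond]], fp(sprintf("dea_%s.tsv", cond)))
  for (cond in names(bundle@splicing))
    writeTable(bundle@splicing[[cond]], fp(sprintf("splicing_%s.tsv", cond)))
  for (nm in names(bundle@rip))
    writeTable(bundle@rip[[nm]], fp(sprintf("rip_%s.tsv", nm)))
  disease <- bundle@disease
  disease$linked <- as.integer(disease$linked)
  writeTable(disease, fp("disease.tsv"))
  truth <- bundle@truth
  cls <- data.frame(
    term_id = c(truth$plantedTermIds, truth$decoyTermIds,
                truth$backgroundTermIds),
    class = c(rep("planted", length(truth$plantedTermIds)),
              rep("decoy", length(truth$decoyTermIds)),
              rep("background", length(truth$backgroundTermIds))))
  writeTable(cls, fp("truth.tsv"))
  invisible(dir)
}

#' Score recovery of the planted modules
#'
#' @param truth truth list from [bundleTruth()] (or any list with a
#'   `plantedTermIds` element), or a character vector of planted term ids.
#' @param selected character vector of selected module term ids.
#' @return list with `recall` (fraction of planted terms selected; 1 by
#'   convention when nothing was planted) and `falsePositives` (number of
#'   selected modules not matching any planted term).
#' @examples
#' truthRecoveryScore(c("T1", "T2"), c("T1", "T9"))
#' @export
truthRecoveryScore <- function(truth, selected) {
  planted <- if (is.list(truth)) truth$plantedTermIds else truth
  selected <- unique(selected)
  recall <- if (length(planted) == 0L) 1 else mean(planted %in% selected)
  list(recall = recall,
       falsePositives = sum(!selected %in% planted))
}
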