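test_that("generation is deterministic given the seed", {
  cfg <- smallBenchConfig(seed = 4)
  b1 <- generateBenchmark(cfg)
  b2 <- generateBenchmark(cfg)
  expect_identical(b1@edges, b2@edges)
  expect_identical(b1@expression, b2@expression)
  expect_identical(b1@annotations, b2@annotations)
  expect_identical(b1@dea, b2@dea)
  expect_identical(b1@rip, b2@rip)
  expect_identical(b1@truth, b2@truth)
  b3 <- generateBenchmark(smallBenchConfig(seed = 5))
  expect_false(identical(b1@edges, b3@edges))
})

test_that("an unplanted zero-background config yields empty DE/AS sets", {
  cfg <- smallBenchConfig(seed = 2, plantedTerms = 0,
                          backgroundAlterRate = 0)
  b <- generateBenchmark(cfg)
  for (cond in names(b@dea)) {
    de <- callDe(b@dea[[cond]])
    expect_length(de$up, 0)
    expect_length(de$down, 0)
    expect_length(callAs(b@splicing[[cond]]), 0)
  }
})

test_that("planted structure obeys its construction invariants", {
  b <- generateBenchmark(smallBenchConfig(seed = 6))
  tr <- bundleTruth(b)
  universe <- b@expression$gene

  # no gene outside the universe appears anywhere
  expect_true(all(b@annotations$gene %in% universe))
  expect_true(all(c(b@edges$p1, b@edges$p2) %in% universe))
  expect_true(all(unlist(tr$altered) %in% universe))

  # planted cores induce connected subgraphs of the expressed network
  net <- buildNetwork(b@edges)
  tissue <- filterByUniverse(net, tr$expressed)
  for (id in tr$plantedTermIds) {
    core <- tr$plantedCore[[id]]
    sub <- igraph::induced_subgraph(tissue, core)
    expect_equal(igraph::components(sub)$no, 1L)
  }

  # planted terms are mutually disjoint
  all_ <- unlist(tr$plantedGenes, use.names = FALSE)
  expect_equal(anyDuplicated(all_), 0L)

  # truth term ids partition the annotation term universe
  expect_setequal(c(tr$plantedTermIds, tr$decoyTermIds, tr$backgroundTermIds),
                  unique(b@annotations$term_id))
})

test_that("realized rates converge to configured rates", {
  cfg <- benchmarkConfig(seed = 1)  # n_genes = 2000 reference conditions
  b <- generateBenchmark(cfg)
  tr <- bundleTruth(b)
  planted <- unique(unlist(tr$plantedGenes, use.names = FALSE))
  nP <- length(planted)
  for (cond in names(tr$altered)) {
    rate <- length(intersect(tr$altered[[cond]], planted)) / nP
    se <- sqrt(0.35 * 0.65 / nP)
    expect_lt(abs(rate - 0.35), 3 * se)
  }
  bgGenes <- setdiff(b@expression$gene, planted)
  for (cond in names(tr$altered)) {
    rate <- length(intersect(tr$altered[[cond]], bgGenes)) / length(bgGenes)
    se <- sqrt(0.08 * 0.92 / length(bgGenes))
    expect_lt(abs(rate - 0.08), 3 * se)
  }
  linkedRate <- length(intersect(tr$linked, planted)) / nP
  expect_lt(abs(linkedRate - 0.30), 3 * sqrt(0.3 * 0.7 / nP))
})

test_that("recovery scoring follows its conventions", {
  expect_equal(truthRecoveryScore(c("T1", "T2"), c("T1", "T2")),
               list(recall = 1.0, falsePositives = 0L))
  expect_equal(truthRecoveryScore(c("T1", "T2"), c("T1", "T9")),
               list(recall = 0.5, falsePositives = 1L))
  expect_equal(truthRecoveryScore(character(0), character(0)),
               list(recall = 1.0, falsePositives = 0L))
  expect_equal(
    truthRecoveryScore(list(plantedTermIds = c("T1", "T2")), "T2")$recall,
    0.5)
})

test_that("infeasible planted sizes raise a generation error", {
  cfg <- smallBenchConfig(seed = 1, nGenes = 60, plantedTerms = 4,
                          plantedTermSize = c(50, 55), nTerms = 10)
  expect_error(generateBenchmark(cfg), "generation error")
})
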