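mkModule <- function(id, nodes)
  new("FunctionalModule", termId = id, termName = id, nodes = sort(nodes),
      components = list(sort(nodes)))

mkLib <- function(...) {
  mods <- list(...)
  names(mods) <- vapply(mods, termId, character(1))
  new("ModuleLibrary", modules = mods[order(names(mods))],
      provenance = list())
}

test_that("module impact is the percentage of altered nodes", {
  m <- mkModule("M", sprintf("G%02d", 1:10))
  p <- knockdownProfile("caz", deUp = c("G01", "G02"), asSet = "G03")
  expect_equal(moduleImpact(m, p), 30.0)
  expect_equal(moduleImpact(m, knockdownProfile("caz")), 0.0)
  pAll <- knockdownProfile("caz", deUp = sprintf("G%02d", 1:10))
  expect_equal(moduleImpact(m, pAll), 100.0)
  expect_error(moduleImpact(character(0), p), "empty")
})

test_that("overall impact is the minimum across conditions", {
  expect_equal(overallImpact(c(caz = 30, Smn = 20, TBPH = 50)), 20.0)
  expect_equal(overallImpact(c(caz = 42)), 42.0)
  expect_equal(overallImpact(c(caz = 0, Smn = 90, TBPH = 90)), 0.0)
  expect_error(overallImpact(numeric(0)), "condition")
})

test_that("selection is inclusive at the threshold", {
  lib <- mkLib(mkModule("M1", sprintf("A%02d", 1:10)),
               mkModule("M2", sprintf("B%03d", 1:1000)))
  # M1: exactly 2/10 = 20% in every condition; M2: 199/1000 = 19.9%
  profs <- lapply(c("caz", "Smn", "TBPH"), function(cn)
    knockdownProfile(cn, deUp = c(sprintf("A%02d", 1:2),
                                  sprintf("B%03d", 1:199))))
  rep_ <- impactReport(lib, profs, threshold = 20)
  expect_equal(selectModules(rep_), "M1")
  sc <- impactScores(rep_)
  expect_equal(sc$overall_impact, c(20.0, 19.9))
  expect_equal(selectModules(rep_, threshold = 19), c("M1", "M2"))
  expect_length(selectModules(rep_, threshold = 101), 0L)
})

test_that("overall impact is monotone in the altered sets and bounded by each condition", {
  set.seed(13)
  for (i in 1:20) {
    nodes <- sprintf("N%03d", 1:30)
    m <- mkModule("M", nodes)
    profs <- lapply(c("c1", "c2", "c3"), function(cn)
      knockdownProfile(cn, deUp = sample(nodes, sample(0:20, 1)),
                       asSet = sample(nodes, sample(0:10, 1))))
    imps <- vapply(profs, function(p) moduleImpact(m, p), numeric(1))
    expect_true(overallImpact(imps) <= min(imps) + 1e-12)

    # enlarge one condition's altered set: overall never decreases
    j <- sample(3, 1)
    enlarged <- profs
    enlarged[[j]] <- knockdownProfile(
      "cx", deUp = union(deUp(profs[[j]]), sample(nodes, 5)),
      asSet = asSet(profs[[j]]))
    imps2 <- vapply(enlarged, function(p) moduleImpact(m, p), numeric(1))
    expect_gte(overallImpact(imps2), overallImpact(imps))
  }
})

test_that("node annotations record DE direction, AS, bound and disease flags", {
  lib <- mkLib(mkModule("M1", c("G1", "G2", "G3")))
  p <- knockdownProfile("caz", deUp = "G1", deDown = "G2", asSet = "G2")
  rep_ <- impactReport(lib, list(p), threshold = 20,
                       boundSets = list(x = "G2"),
                       disease = data.frame(gene = c("G3", "G9"),
                                            linked = c(TRUE, TRUE)))
  ann <- nodeAnnotations(rep_)
  expect_equal(ann$de_caz, c("up", "down", "none"))
  expect_equal(ann$as_caz, c(FALSE, TRUE, FALSE))
  expect_equal(ann$n_conditions_altered, c(1, 1, 0))
  expect_equal(ann$bound, c(FALSE, TRUE, FALSE))
  expect_equal(ann$linked, c(FALSE, FALSE, TRUE))
})
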