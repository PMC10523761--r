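smFixture <- function() {
  mk <- function(id, nodes)
    new("FunctionalModule", termId = id, termName = id, nodes = sort(nodes),
        components = list(sort(nodes)))
  mods <- list(
    A = mk("A", sprintf("N%02d", 1:10)),
    B = mk("B", sprintf("N%02d", 6:15)),   # Jaccard(A,B) = 5/15
    C = mk("C", sprintf("Z%02d", 1:10)))   # disjoint
  lib <- new("ModuleLibrary", modules = mods, provenance = list())
  profs <- list(knockdownProfile("caz", deUp = c(sprintf("N%02d", 1:15),
                                                 sprintf("Z%02d", 1:10))))
  list(lib = lib, profs = profs)
}

test_that("the overlap graph carries shared-altered weights and omits empty overlaps", {
  fx <- smFixture()
  g <- buildOverlapGraph(fx$lib, c("A", "B", "C"), fx$profs)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 1L)  # only A-B share altered nodes
  expect_equal(igraph::E(g)$shared_altered, 5)
  expect_equal(igraph::E(g)$jaccard, 5 / 15)
  expect_error(buildOverlapGraph(fx$lib, character(0), fx$profs), "selected")
})

test_that("coalescing takes Jaccard-thresholded components with deterministic ids", {
  fx <- smFixture()
  g <- buildOverlapGraph(fx$lib, c("A", "B", "C"), fx$profs)
  sms <- coalesceSuperModules(g, fx$lib, minJaccard = 0.2)
  expect_equal(length(sms), 2L)
  expect_equal(superModuleMembers(sms)[["SM_A"]], c("A", "B"))
  expect_equal(superModuleMembers(sms)[["SM_C"]], "C")
  expect_setequal(superModuleNodes(sms)[["SM_A"]], sprintf("N%02d", 1:15))

  # every selected module lands in exactly one super-module
  expect_setequal(unlist(superModuleMembers(sms)), c("A", "B", "C"))

  # degenerate threshold: all singletons
  sms1 <- coalesceSuperModules(g, fx$lib, minJaccard = 1.0)
  expect_equal(length(sms1), 3L)

  # raising the threshold only refines the partition
  smsLo <- coalesceSuperModules(g, fx$lib, minJaccard = 0.1)
  for (idHi in superModuleIds(sms1)) {
    hi <- superModuleMembers(sms1)[[idHi]]
    inLo <- vapply(superModuleMembers(smsLo), function(ms)
      all(hi %in% ms), logical(1))
    expect_equal(sum(inLo), 1L)
  }
})

test_that("chains coalesce transitively through components", {
  mk <- function(id, nodes)
    new("FunctionalModule", termId = id, termName = id, nodes = sort(nodes),
        components = list(sort(nodes)))
  # A~B and B~C overlap, A and C do not
  mods <- list(A = mk("A", sprintf("N%02d", 1:10)),
               B = mk("B", sprintf("N%02d", 7:16)),
               C = mk("C", sprintf("N%02d", 13:22)))
  lib <- new("ModuleLibrary", modules = mods, provenance = list())
  profs <- list(knockdownProfile("c1", deUp = sprintf("N%02d", 1:22)))
  g <- buildOverlapGraph(lib, names(lib), profs)
  sms <- coalesceSuperModules(g, lib, minJaccard = 0.2)
  expect_equal(length(sms), 1L)
  expect_equal(superModuleMembers(sms)[[1L]], c("A", "B", "C"))
})

test_that("super-module overlap percentages use the smaller set", {
  expect_equal(superModuleOverlap(letters[1:10], LETTERS[1:10]), 0.0)
  expect_equal(superModuleOverlap(letters[1:5], letters[1:20]), 100.0)
  expect_equal(superModuleOverlap(sprintf("x%d", 1:10),
                                  c(sprintf("x%d", 1:2),
                                    sprintf("y%d", 1:18))), 20.0)
})
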