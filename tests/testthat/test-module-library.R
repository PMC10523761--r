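test_that("the isolated-cluster rule discards satellites only above 90%", {
  # 11 + 1 nodes: 11/12 > 0.9 -> keep the largest component only
  fx <- componentFixture(11, 1)
  m <- extractModule(fx$termGenes, fx$net, "T1")
  expect_equal(moduleSize(m), 11L)
  expect_length(moduleComponents(m), 1L)

  # 6 + 6: 0.5 <= 0.9 -> keep both
  e <- rbind(data.frame(p1 = sprintf("A%d", 1:5), p2 = sprintf("A%d", 2:6)),
             data.frame(p1 = sprintf("B%d", 1:5), p2 = sprintf("B%d", 2:6)))
  net <- buildNetwork(e)
  m <- extractModule(c(sprintf("A%d", 1:6), sprintf("B%d", 1:6)), net, "T2")
  expect_equal(moduleSize(m), 12L)
  expect_length(moduleComponents(m), 2L)

  # 9 + 1: exactly 0.9 is NOT > 0.9 -> keep both, size 10
  fx <- componentFixture(9, 1)
  m <- extractModule(fx$termGenes, fx$net, "T3")
  expect_equal(moduleSize(m), 10L)
  expect_length(moduleComponents(m), 2L)

  # no induced node -> NULL
  expect_null(extractModule(c("ZZ1", "ZZ2"), fx$net, "T4"))
})

test_that("module extraction is invariant to input gene order and keeps the rule's postcondition", {
  set.seed(8)
  fx <- componentFixture(14, 3)
  g1 <- fx$termGenes
  m1 <- extractModule(g1, fx$net, "T")
  m2 <- extractModule(sample(g1), fx$net, "T")
  expect_equal(moduleNodes(m1), moduleNodes(m2))
  expect_equal(moduleComponents(m1), moduleComponents(m2))
  # after the rule: one component left, or largest covers <= 90% of retained
  for (small in 0:4) {
    fx <- componentFixture(12, small)
    m <- extractModule(fx$termGenes, fx$net, "T")
    shares <- lengths(moduleComponents(m)) / moduleSize(m)
    expect_true(length(moduleComponents(m)) == 1L || shares[1L] <= 0.9)
  }
})

test_that("the library applies the inclusive 10-100 size window after the rule", {
  # construct terms inducing sizes 9, 10, 100, 101 on a long path network
  nodes <- sprintf("P%03d", 1:130)
  net <- buildNetwork(data.frame(p1 = nodes[-130], p2 = nodes[-1]))
  sizes <- c(9, 10, 100, 101)
  ann <- do.call(rbind, lapply(seq_along(sizes), function(i)
    data.frame(term_id = sprintf("T%d", i), term_name = "t",
               gene = nodes[seq_len(sizes[i])])))
  enr <- data.frame(term_id = sprintf("T%d", 1:4), term_name = "t",
                    enriched = TRUE)
  lib <- buildLibrary(enr, ann, net)
  expect_setequal(names(lib), c("T2", "T3"))
  expect_equal(unname(moduleSizes(lib)), c(10L, 100L))

  # no enriched term -> empty library
  enr$enriched <- FALSE
  expect_length(buildLibrary(enr, ann, net), 0L)
})

test_that("genes may appear in several modules, and redundancy is reported not filtered", {
  nodes <- sprintf("P%03d", 1:40)
  net <- buildNetwork(data.frame(p1 = nodes[-40], p2 = nodes[-1]))
  ann <- rbind(
    data.frame(term_id = "TA", term_name = "a", gene = nodes[1:20]),
    data.frame(term_id = "TB", term_name = "b", gene = nodes[11:30]))
  enr <- data.frame(term_id = c("TA", "TB"), term_name = c("a", "b"),
                    enriched = TRUE)
  lib <- buildLibrary(enr, ann, net)
  expect_equal(length(lib), 2L)
  shared <- intersect(moduleNodes(lib[["TA"]]), moduleNodes(lib[["TB"]]))
  expect_length(shared, 10L)

  red <- redundancyMatrix(lib)
  expect_equal(red$jaccard, 10 / 30)
  expect_equal(red$overlap_coef, 0.5)

  # arithmetic cases
  libIdent <- new("ModuleLibrary", modules = list(
    X = new("FunctionalModule", termId = "X", termName = "x",
            nodes = c("a", "b"), components = list(c("a", "b"))),
    Y = new("FunctionalModule", termId = "Y", termName = "y",
            nodes = c("a", "b"), components = list(c("a", "b")))),
    provenance = list())
  expect_equal(redundancyMatrix(libIdent)$jaccard, 1.0)
  expect_error(redundancyMatrix(new("ModuleLibrary", modules = list(),
                                    provenance = list())), "two")
})
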