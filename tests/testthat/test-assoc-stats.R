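test_that("disease fractions are percentages over all module nodes", {
  dis <- data.frame(gene = c("G1", "G2", "X9"), linked = c(TRUE, TRUE, TRUE))
  expect_equal(diseaseFraction(sprintf("G%d", 1:10), dis), 20.0)
  expect_equal(diseaseFraction(sprintf("H%d", 1:5), dis), 0.0)
  expect_equal(diseaseFraction(c("G1", "G2"), dis), 100.0)
})

test_that("the rank-sum test matches enumeration and handles degenerate inputs", {
  expect_equal(wilcoxonRankSum(c(3, 4), c(1, 2))$p, 1 / 3, tolerance = 1e-12)
  expect_true(wilcoxonRankSum(c(3, 4), c(1, 2))$exact)
  # identical samples: no shift
  expect_gte(wilcoxonRankSum(c(10, 20, 30), c(10, 20, 30), "greater")$p, 0.5)
  expect_equal(wilcoxonRankSum(c(1, 2, 7), c(1, 2, 7))$p, 1, tolerance = 0.05)
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")
})

test_that("chi-square handles Yates, plain, and zero margins", {
  t1 <- matrix(c(10, 10, 10, 10), 2)
  r <- chi2Independence(t1, yates = FALSE)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_equal(chi2Independence(matrix(c(10, 0, 0, 10), 2))$chi2, 16.2,
               tolerance = 1e-9)
  expect_equal(chi2Independence(matrix(c(10, 0, 0, 10), 2),
                                yates = FALSE)$chi2, 20,
               tolerance = 1e-9)
  expect_error(chi2Independence(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
})

test_that("the chained hypergeometric distribution normalizes and matches expectation", {
  set.seed(7)
  for (i in 1:12) {
    N <- sample(20:200, 1)
    k <- sample(2:4, 1)
    sizes <- sample.int(N, k, replace = TRUE)
    d <- multisetIntersectionDist(N, sizes)
    expect_equal(sum(d), 1, tolerance = 1e-9)
    meanD <- sum(as.integer(names(d)) * d)
    expect_equal(meanD, multisetExpected(N, sizes), tolerance = 1e-6)
  }
  expect_equal(multisetExpected(100, c(50, 50, 50)), 12.5)
  expect_equal(multisetExpected(40, c(10, 0, 9)), 0)
  expect_equal(multisetExpected(40, 17), 17)
})

test_that("multi-set intersection p-values match enumeration and Monte-Carlo", {
  expect_equal(multisetIntersectionP(4, c(2, 2), 2), 1 / 6,
               tolerance = 1e-12)
  expect_equal(multisetIntersectionP(3, c(2, 2, 2), 1), 7 / 9,
               tolerance = 1e-12)
  expect_equal(multisetIntersectionP(50, c(20, 30), 0), 1.0)

  # Monte-Carlo cross-check at N = 100, k = 3
  set.seed(21)
  N <- 100; sizes <- c(40, 55, 30); m <- 8
  draws <- replicate(1e5, {
    length(Reduce(intersect, lapply(sizes, function(s) sample.int(N, s))))
  })
  pHat <- mean(draws >= m)
  se <- sqrt(pHat * (1 - pHat) / length(draws))
  expect_lt(abs(multisetIntersectionP(N, sizes, m) - pHat), 3 * se)
})

test_that("selected-vs-rest disease comparison behaves on constructed libraries", {
  mk <- function(id, nodes)
    new("FunctionalModule", termId = id, termName = id, nodes = sort(nodes),
        components = list(sort(nodes)))
  mods <- lapply(1:8, function(i)
    mk(sprintf("M%d", i), sprintf("g%d_%d", i, 1:10)))
  names(mods) <- sprintf("M%d", 1:8)
  lib <- new("ModuleLibrary", modules = mods, provenance = list())
  # identical fractions everywhere -> p ~ 1
  disNone <- data.frame(gene = "none", linked = TRUE)
  r <- compareSelectedVsRest(lib, c("M1", "M2"), disNone)
  expect_equal(r$p, 1, tolerance = 0.05)
  expect_error(compareSelectedVsRest(lib, names(lib), disNone), "non-empty")

  # planted difference: selected modules fully linked
  dis <- data.frame(gene = c(sprintf("g1_%d", 1:10), sprintf("g2_%d", 1:10),
                             sprintf("g3_%d", 1:10)),
                    linked = TRUE)
  r2 <- compareSelectedVsRest(lib, c("M1", "M2", "M3"), dis)
  expect_lt(r2$p, 0.05)
  expect_gt(r2$medianSelected, r2$medianRest)
})

test_that("RIP prevalence reports per-group fractions and pairwise tests", {
  groups <- list(a = sprintf("A%d", 1:4), b = sprintf("B%d", 1:4),
                 c = character(0))
  bound <- c("A1", "B1")
  r <- ripPrevalence(groups, bound)
  expect_equal(r$fractions$fraction_pct, c(25.0, 25.0, NA))
  # identical fractions, equal sizes -> chi2 = 0 (without correction it would
  # be exactly 0; with Yates it stays 0 because |ad - bc| < N/2 clips)
  expect_equal(r$tests$chi2[r$tests$group_a == "a" &
                            r$tests$group_b == "b"], 0)
  expect_equal(nrow(r$tests), 1L)  # empty group excluded from tests
  expect_error(ripPrevalence(list(a = "G1", b = "G1"), "G1"), "disjoint")
})
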