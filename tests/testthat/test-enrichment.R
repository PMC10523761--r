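test_that("hypergeometric upper tail matches exact values and guards its domain", {
  expect_equal(hypergeomUpper(10, 4, 5, 4), 6 / 252, tolerance = 1e-12)
  expect_equal(hypergeomUpper(6, 3, 3, 3), 1 / 20, tolerance = 1e-12)
  expect_equal(hypergeomUpper(50, 10, 20, 0), 1.0)
  expect_error(hypergeomUpper(10, 4, 5, 6), "min")
  expect_error(hypergeomUpper(10, 12, 5, 2), "N")
})

test_that("term enrichment counts overlaps within the background", {
  ann <- data.frame(term_id = c(rep("TA", 4), rep("TB", 3)),
                    term_name = "x",
                    gene = c("G1", "G2", "G3", "G4", "G8", "G9", "Z1"))
  bg <- sprintf("G%d", 1:10)
  res <- enrichTerms(sprintf("G%d", 1:5), bg, ann)
  # Z1 outside background: K(TB) = 2
  expect_equal(res$K[res$term_id == "TB"], 2L)
  expect_equal(res$p[res$term_id == "TA"], 6 / 252, tolerance = 1e-12)

  # candidate == background -> every p is 1
  resAll <- enrichTerms(bg, bg, ann)
  expect_true(all(resAll$p == 1))

  expect_error(enrichTerms(c("G1", "QQ"), bg, ann), "subset")
})

test_that("randomization FDR flags extreme terms, is seed-reproducible and order-invariant", {
  set.seed(1)
  bg <- sprintf("G%03d", 1:120)
  cand <- bg[1:40]
  # one term fully inside the candidate set, several random terms
  ann <- data.frame(term_id = "T01", term_name = "planted", gene = bg[1:15])
  for (i in 2:12)
    ann <- rbind(ann, data.frame(term_id = sprintf("T%02d", i),
                                 term_name = "bg",
                                 gene = sample(bg, 12)))
  res <- enrichTerms(cand, bg, ann)
  r1 <- randomizationFdr(res, length(cand), bg, ann, nRand = 300, seed = 9)
  r2 <- randomizationFdr(res, length(cand), bg, ann, nRand = 300, seed = 9)
  expect_identical(r1$fdr, r2$fdr)
  expect_true(r1$enriched[r1$term_id == "T01"])

  # permuting the rows changes nothing
  resPerm <- res[sample(nrow(res)), ]
  r3 <- randomizationFdr(resPerm, length(cand), bg, ann, nRand = 300,
                         seed = 9)
  expect_equal(r3$fdr[match(r1$term_id, r3$term_id)], r1$fdr)

  # fdr is monotone in p
  ord <- order(r1$p)
  expect_true(all(diff(r1$fdr[ord]) >= 0))
})

test_that("a term beating every randomization gets fdr 0; all-null p=1 flags nothing", {
  bg <- sprintf("G%03d", 1:60)
  ann <- data.frame(term_id = "T1", term_name = "t", gene = bg[1:10])
  res <- enrichTerms(bg[1:12], bg, ann)  # k = 10 of 12: essentially minimal p
  r <- randomizationFdr(res, 12, bg, ann, nRand = 200, seed = 2)
  expect_equal(r$fdr[1], 0)
  expect_true(r$enriched[1])

  resNull <- res
  resNull$p <- 1
  rNull <- randomizationFdr(resNull, 12, bg, ann, nRand = 50, seed = 2)
  expect_false(any(rNull$enriched))
})
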