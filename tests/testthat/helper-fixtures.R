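# Shared fixtures built in code.

# A small, fast benchmark for unit tests (the reference benchmark with
# defaults is exercised in the acceptance tests).
smallBenchConfig <- function(seed = 11, ...) {
  args <- list(nGenes = 400, fracExpressed = 0.7, meanDegree = 6,
               nTerms = 30, plantedTerms = 3, decoyTerms = 3,
               plantedTermSize = c(20, 30), decoyTermSize = c(12, 18),
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(benchmarkConfig, args)
}

# Toy tissue network: a path A-B-C-D plus an edge E-F and isolated pair G-H.
toyNet <- function() {
  buildNetwork(data.frame(
    p1 = c("A", "B", "C", "E", "G"),
    p2 = c("B", "C", "D", "F", "H")), label = "toy")
}

# A graph with one large component of `big` nodes (a path) and `small`
# isolated singletons, used for the isolated-cluster rule fixtures. Node
# names: big component N01.., satellites S01..
componentFixture <- function(big, small) {
  bigNodes <- sprintf("N%02d", seq_len(big))
  edges <- data.frame(p1 = bigNodes[-big], p2 = bigNodes[-1L])
  sats <- if (small > 0) sprintf("S%02d", seq_len(small)) else character(0)
  # satellites get edges to each other or to a dummy so they stay in the
  # network, but never to the big component
  if (small > 0) {
    dummy <- sprintf("D%02d", seq_len(small))
    edges <- rbind(edges, data.frame(p1 = sats, p2 = dummy))
  }
  list(net = buildNetwork(edges),
       termGenes = c(bigNodes, sats))
}

writeTempTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
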