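# ModuleImpact

Convergent knockdown impact on tissue-specific protein functional modules.

## The problem

When several disease genes are knocked down and each alters a different set
of transcripts, gene-level overlap analysis can miss what the perturbations
have in common: a protein complex can be disrupted through *distinct*
subunits. `ModuleImpact` implements a network-based procedure for detecting
protein functional modules convergently impacted by multiple gene
knockdowns. It is aimed at systems-biology analyses that start from
gene-level tables (differential expression, altered splicing, RIP-seq
enrichment, tissue expression, disease annotations) downstream of standard
RNA-seq processing.

The procedure:

1. **Tissue network.** An unspecific protein–protein interaction edge list
   is cleaned into a simple graph (duplicates collapsed, self-loops and
   isolated proteins removed) and filtered to interactions whose *both*
   proteins pass a tissue expression threshold (FPKM > 1).
2. **Module library.** Annotation terms over-represented in the tissue
   network versus the unspecific network are found with a hypergeometric
   upper-tail test, `P(X ≥ k)` for `X ~ Hypergeom(N, K, n)`, with a
   randomization FDR: random candidate sets of the observed size are redrawn
   from the background (1000 times), and `FDR(t) = E[#null p ≤ t] / #obs p ≤ t`,
   monotonized; terms pass at FDR ≤ 0.1. Each enriched term induces a module
   on the tissue network; isolated clusters are discarded only when the
   largest connected component holds > 90% of the module, and modules of
   10–100 proteins (inclusive) are kept.
3. **Impact scoring.** For each module and knockdown condition, the impact
   is the percentage of module nodes whose transcript is DE (adjusted
   p < 0.05, either direction) or AS (FDR < 0.05). The **overall impact** is
   the minimum across conditions — a module at X% is hit at ≥ X% in *every*
   knockdown — and modules with overall impact ≥ 20% are selected.
4. **Super-modules.** Selected modules are coalesced by thresholding their
   node-set Jaccard overlap (≥ 0.2) and taking connected components of the
   overlap graph.
5. **Association statistics.** Disease-ortholog enrichment of selected
   versus non-selected modules (Wilcoxon rank-sum), RIP-target prevalence
   across module membership groups (Yates-corrected chi-square), and exact
   multi-set intersection tests of the per-condition altered sets via the
   chained hypergeometric distribution
   `D_j(x) = Σ_y D_{j−1}(y) · HypergeomPMF(N, y, n_j)(x)`.

A seeded synthetic-benchmark generator (`generateBenchmark()`) produces all
six input table types with planted convergently impacted modules, so the
whole pipeline is verifiable by recovery — no downloads needed.

## Worked example

```r
library(ModuleImpact)

bundle <- generateBenchmark(benchmarkConfig(seed = 1))
writeBenchmark(bundle, "bench/in")
res <- runPipeline("bench/in", "bench/out",
                   pipelineConfig(nRand = 1000, seed = 1))

length(res$library)                                  # 27
length(res$selected)                                 # 12
truthRecoveryScore(bundleTruth(bundle), res$selected)
#> $recall
#> [1] 1
#> $falsePositives
#> [1] 0
compareSelectedVsRest(res$library, res$selected, res$disease)$p
#> [1] 1.254931e-05
```

On this benchmark the library holds 27 modules (12 planted impacted terms,
15 connected but unimpacted "decoy" terms, and the random terms that fail
enrichment); all 12 planted modules — and nothing else — pass the 20%
overall-impact cut-off, and the selected modules are significantly enriched
in disease-linked proteins (Wilcoxon p ≈ 1.3e-5). The RIP-prevalence
chi-square contrasts the ~35% bound fraction among altered transcripts in
selected modules with ~21% among altered transcripts outside any module
(p ≈ 7.7e-3).

All thresholds above are defaults of `pipelineConfig()` /
`benchmarkConfig()` and can be changed; outputs are deterministic TSV files
(byte-identical given the same config and seed).

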