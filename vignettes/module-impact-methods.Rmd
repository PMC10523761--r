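---
title: "Detecting convergently impacted functional modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergently impacted functional modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ModuleImpact` asks whether several gene knockdowns that alter largely
disjoint sets of transcripts nevertheless converge on the same protein
functional modules. This vignette explains the model behind each stage, the
parameters that matter, the synthetic benchmark the package is validated on,
and the design decisions taken where the procedure was genuinely open.

## The model

The unit of analysis is a *functional module*: the subgraph of a
tissue-specific protein–protein interaction (PPI) network induced by the
genes annotated to one over-represented annotation term (e.g. a Gene
Ontology Biological Process). The premise is that a biological process can
be similarly disrupted by hits on *different* members of the same physical
module, so convergence should be scored at the module level, not the
transcript level.

### Tissue network

The unspecific interactome (an APID-style edge list) is collapsed to an
undirected simple graph: duplicate and reversed pairs merged, self-loops
dropped, and proteins left without any interaction removed. The
tissue-specific network keeps only edges whose **both** endpoints pass the
expression filter — strictly more than `fpkmThreshold` (default 1) FPKM in
the tissue expression table — and is re-cleaned. The comparison is strict on
purpose: boundary values are non-expressed, and the same strictness applies
to every significance threshold in the package (adjusted p and FDR `< 0.05`).
The network is *not* reduced to its largest connected component; sparse
peripheral interactions are legitimate module material.

### Enrichment with a randomization FDR

Each term is tested with the hypergeometric upper tail
$P(X \ge k),\; X \sim \mathrm{Hypergeom}(N, K, n)$, where $N$ is the
background size (the unspecific network's nodes), $K$ the annotated genes in
the background, $n$ the candidate size (the tissue network's nodes) and $k$
the annotated genes among the candidates. `stats::phyper()` evaluates this
in log space, so extreme tails are exact to machine precision.

Because term sizes and annotation overlap make the per-term null
distributions heavily discrete and dependent, significance is controlled by
randomization rather than an analytic multiple-testing correction: for each
of `nRand` (default 1000) rounds, a candidate set of the observed size is
redrawn uniformly from the background and all term p-values are recomputed.
The estimated FDR at an observed p-value $t$ is

$$\widehat{\mathrm{FDR}}(t) =
  \frac{\mathbb{E}_{\text{rand}}\,\#\{\text{null terms with } p \le t\}}
       {\max(1, \#\{\text{observed terms with } p \le t\})},$$

made monotone non-decreasing in $p$ by a cumulative maximum from the
smallest p-value and capped at 1. Terms pass at FDR ≤ `enrichFdr`
(default 0.1). Resampling the *candidate gene set* (not term labels)
preserves term sizes and the annotation structure under the null. The
estimator is the standard empirical-null construction; its Monte-Carlo error
with 1000 rounds is negligible next to the 0.1 threshold for the effect
sizes of interest. Randomization is the only stochastic step of the
pipeline; it is driven by one seed and the caller's RNG state is restored.

### Module extraction

A term's module is the induced subgraph of its annotated genes on the tissue
network, *including* its disconnected parts: proteins collaborating in one
process need not all interact physically (a receptor does not bind the
transcription factor downstream of it). Isolated clusters are discarded only
when the largest connected component covers strictly more than
`keepFraction` (default 0.9) of the induced nodes — in that regime the small
parts are stray annotations rather than genuine sub-complexes. A share of
exactly 0.9 keeps everything. Singleton nodes count as components; they are
exactly what the rule targets.

Module size is measured **after** this discard, and the library keeps
modules with `minSize ≤ size ≤ maxSize` (inclusive; defaults 10 and 100).
Both orderings of the rule and the window are defensible; measuring the
final module is used here because the retained node set is what every
downstream statistic sees, and the alternative is one configuration flag
away (`keepFraction = 1` disables the discard). Pairwise redundancy
(Jaccard and overlap coefficient) is reported, never filtered: term
redundancy is a property of the annotation source the user should see.

### Impact and selection

For module $M$ and condition $c$ with altered set $A_c$ (DE up, DE down and
AS genes pooled, each gene counted once),

$$\mathrm{impact}_c(M) = 100 \cdot \frac{|M \cap A_c|}{|M|},
\qquad
\mathrm{overall}(M) = \min_c \mathrm{impact}_c(M).$$

The minimum encodes convergence: a module with overall impact $X$% has at
least $X$% of its nodes hit in *every* knockdown. Selection is inclusive at
`impactThreshold` (default 20%). The denominator is all module nodes, not
only nodes with measured transcripts — the score describes the module, and
unmeasured nodes are evidence of absence of impact, not missing data; a
stricter denominator can be emulated by pre-filtering the input tables.

### Super-modules and statistics

Selected modules often overlap heavily. They are coalesced by building the
overlap graph (edges between selected modules sharing at least one altered
transcript, weighted by the shared-altered count for display and by the
node-set Jaccard index for decisions), keeping edges with Jaccard ≥
`minJaccard` (default 0.2) and taking connected components. This replaces a
manual grouping step with a deterministic, input-order-free rule driven by
the same signal (edge density); semantic similarity of term names is
deliberately *not* encoded, because term-name semantics are not available to
an algorithm in any principled flat-table form. Pairwise super-module
overlap is reported as the overlap coefficient (percentage of the smaller
node set), the conservative choice among min/union/mean denominators and
configurable in code.

Three association statistics characterize the selection:

* **Disease enrichment** — per-module percentage of disease-linked
  proteins, selected versus non-selected library modules, two-sided
  Wilcoxon rank-sum. The test is exact by enumeration when the pooled
  sample is ≤ 12 with no ties, otherwise normal with tie and continuity
  corrections; the boundary affects precision only, never direction. A
  zero-variance comparison (all fractions identical) reports p = 1.
* **RIP-target prevalence** — fraction of bound transcripts (positive
  log2 FC, adjusted p < 0.05 in any protein/compartment pull-down, pooled
  by union) among altered genes inside selected modules, inside
  non-selected modules, and in no module; pairwise Yates-corrected
  chi-square on the 2×2 counts.
* **Multi-set intersections** — the observed overlap of the per-condition
  altered sets against the exact distribution of $|A_1 \cap \dots \cap
  A_k|$ for independent uniform fixed-size subsets, built by chained
  hypergeometric mixing
  $D_j(x) = \sum_y D_{j-1}(y)\,\mathrm{HG}(x; N, y, n_j)$, with expectation
  $N\prod_i (n_i/N)$. The universe $N$ is an explicit parameter (the
  pipeline uses the expression universe); results scale with it, so it is
  always reported alongside the p-value.

## The synthetic benchmark

`generateBenchmark()` produces a complete input bundle plus ground truth.
What it emulates, and the reference values (`benchmarkConfig()` defaults):

* **Universe and expression** — 2000 genes, 80% expressed. Expressed genes
  draw FPKM from a log-normal (meanlog 3, sdlog 1; median ≈ 20 FPKM)
  truncated to > 1, so the expressed set and the FPKM > 1 universe coincide
  exactly and threshold behaviour is testable as a set identity;
  non-expressed genes draw from (0, 1].
* **Interactome** — preferential attachment over the expressed genes
  (mean degree ≈ 6), giving the heavy-tailed degree distribution of curated
  PPI networks; non-expressed genes are wired in with 1–2 degree-weighted
  edges so the tissue filter has something to remove. Five percent of genes
  get a self-loop and ~2% of rows are duplicated reversed, so cleaning is
  exercised on every run.
* **Terms** — 150 total. 12 *planted* terms are grown breadth-first as
  connected subgraphs of the expressed network (40–80 genes, mutually
  disjoint so that planted impact estimates do not leak between modules); a
  quarter of them receive one disconnected satellite gene to exercise the
  isolated-cluster rule. 15 *decoy* terms are grown the same way (25–50
  genes, avoiding planted genes) but left at background alteration rates:
  they pass enrichment and populate the library's non-selected side, which
  keeps the selected-versus-rest comparisons well-posed — with planted terms
  alone, the empirical FDR admits at most a term or two of random background
  into the library and the Wilcoxon comparison group would be near-empty.
  The remaining 123 terms are random gene sets (sizes log-uniform in
  [5, 150]) that calibrate the enrichment null.
* **Knockdowns** — three conditions. Each planted-term gene is altered
  independently per condition with probability 0.35, every other gene with
  probability 0.08; altered genes are DE-up / DE-down / AS-only with
  probabilities 0.4 / 0.4 / 0.2 (mirroring roughly balanced up/down calls in
  real knockdown data while reserving mass for splicing-only changes).
  Significant calls draw padj or FDR from U(0, 0.05) and DE magnitudes from
  0.1 + Exp(1) with the matching sign; everything else draws from
  U(0.05, 1). With these rates a planted module's per-condition impact is
  Binomial(|M|, 0.35)/|M|, so the overall impact (the minimum of three) sits
  comfortably above the 20% threshold for 40–80-gene modules, while decoys
  (union alteration ≈ 22%, per-condition 8%) essentially never pass.
* **RIP and disease** — altered planted genes are bound with probability
  0.35 versus 0.15 background, each bound gene showing positive enrichment
  in one random (protein, compartment) table of six; planted-term genes are
  disease-linked with probability 0.30 versus 0.05 background.

What the generator does **not** emulate: correlated noise between
conditions, batch or treatment covariates (upstream of the package's
inputs), annotation bias, identifier mapping problems, or degree-dependent
alteration. Passing the recovery tests therefore shows the pipeline's rules
and statistics are implemented correctly under known structure — not that
the biological effect sizes of any real study are recoverable.

## Numerical and degenerate-input choices

* All tabular output is TSV with doubles at 6 significant digits and
  canonical row order; two runs with one config and seed are byte-identical.
* Missing `padj`/`fdr` values are non-significant, never errors
  (DESeq2-style outputs legitimately contain them); malformed numerics
  parse to missing, out-of-range probabilities and negative FPKM are hard
  errors.
* `log2fc == 0` with significant padj belongs to neither DE direction.
* Component ordering inside a module breaks size ties by first node name;
  super-module identifiers derive from the smallest member term id — both
  purely for determinism.
* An empty module, an empty sample, a zero chi-square margin and an empty
  comparison group are errors (or reported as skipped at the pipeline
  level); an empty universe after filtering is a warning, since a caller
  may legitimately probe thresholds.
* Recall over zero planted terms is defined as 1; the selected fraction of
  an empty library is 0.

## Problem sizes

The test suite validates the statistical engines against brute-force
enumeration on all small instances (hypergeometric N ≤ 12; tie-free rank-sum
samples up to 8; multi-set intersections with N ≤ 6, k ≤ 3, cross-checked by
Monte-Carlo at N = 100), and runs the full pipeline with the
1000-randomization FDR on the 2000-gene reference benchmark and on a fully
null benchmark (no planted or decoy terms). Unit tests use a 400-gene
variant with three planted and three decoy terms of 20–30 and 12–18 genes —
sizes at which planted enrichment is still decisive against a 30-term
annotation set.

## Known limitations

* One identifier namespace is assumed across all inputs; no ortholog or
  alias mapping is performed.
* Annotations are consumed flat: no ontology graph propagation or
  parent-term inheritance, and no semantic redundancy collapsing.
* Interaction confidence levels are not modelled; the edge list is taken
  as given.
* The multi-set intersection model assumes independent uniform sets; for
  gene sets with strong shared structure it is a null model, not a fit.
* The 2×2 chi-square uses the asymptotic distribution; for very small
  groups an exact test would be preferable, and prevalence counts are
  reported so one can be applied externally.
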