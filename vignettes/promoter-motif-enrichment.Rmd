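---
title: "Promoter hexamer enrichment in trend-clustered gene sets: methods and design"
author: "promoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter hexamer enrichment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoscan)
```

## The question the pipeline answers

When a stress such as soil flooding induces (or represses) a set of genes
more strongly in a wild-type plant than in a hormone-deficient mutant, a
natural hypothesis is that the difference is wired into the promoters:
the affected genes should share transcription-factor recognition motifs
— abscisic-acid-responsive elements (ABREs), G-boxes, W-boxes and the
like — at frequencies above the genome-wide background. `promoscan`
implements that test end to end for a two-genotype, two-treatment
replicated RNA-seq design: it selects trend clusters from an FPKM
matrix, extracts a fixed window upstream of every protein-coding gene,
counts all hexamers in the cluster's promoters against all promoters in
the genome, and reports motifs that are both effect-size enriched and
significant under false-discovery-rate control, annotated against a
table of known plant cis-regulatory elements.

## The enrichment model

For a motif $m$, let $k$ be its count in the promoters of the foreground
gene set, $K$ the foreground total, $n$ its count in all genome
promoters and $N$ the genome total. The effect size is the **enrichment
fraction**

$$E(m) \;=\; \frac{k/K}{n/N},$$

the ratio of the motif's relative frequency in the foreground to its
relative frequency genome-wide; $E = 1.25$ reads as "25% above the
genome expectation". Significance uses the upper-tail hypergeometric
probability of drawing at least $k$ motif-positive promoters when $K$
promoters are sampled without replacement from $N$ of which $n$ are
positive:

$$p(m) \;=\; \sum_{i \ge k} \frac{\binom{n}{i}\binom{N-n}{K-i}}{\binom{N}{K}} .$$

Raw p-values over all $4^k$ motifs are adjusted by the
Benjamini–Hochberg step-up procedure, and a motif is retained when
$E \ge 1.1$ and $q \le 0.05$ (both thresholds are arguments).

Three design decisions deserve explanation:

* **Counting mode.** `countMotifs()` offers `presence` (promoters
  containing at least one occurrence; denominators are promoter counts)
  and `occurrence` (every sliding window; denominators are window
  totals). Presence is the default: it makes the genome denominator the
  number of promoters, which is the scale on which published
  count tables of this kind are reported, and it matches the sampling
  model of the hypergeometric test exactly. Occurrence mode is provided
  for sensitivity analysis and the mode is recorded in the result
  metadata. The enrichment arithmetic itself is mode-independent — it
  only divides the four counts it is given.
* **Strandedness.** Motifs are counted on the extracted promoter strand
  only. Collapsing reverse complements would merge biologically distinct
  entries (an ACGT-class element and its complement are bound by
  different factor families in several cases), and it would halve the
  test family in a way the annotation stage cannot undo. Reverse
  complement *matching* is available as an option at the annotation
  stage instead.
* **The BH family.** Adjustment runs over all $4^k$ motifs in the count
  table — including motifs absent from the foreground, which are kept
  with $E = 0$, $p = 1$ — never over the post-threshold subset.
  Filtering by effect size first and correcting afterwards would
  misstate the FDR; the effect-size filter is applied after adjustment,
  at the reporting step.

Windows containing any non-ACGT character are skipped in both modes, in
numerator and denominator alike.

## Promoter extraction

A promoter is the `upstream` bases (default 1000) immediately 5' of the
transcription start site, excluding the TSS base itself: for a
plus-strand gene with TSS $t$ the window is $[\max(1, t-L),\, t-1]$; for
a minus-strand gene, the reverse complement of
$[t+1,\, \min(\mathrm{end},\, t+L)]$. All promoters are therefore stored
5'→3' relative to their gene. One window is extracted per gene, anchored
at the gene-level TSS (the 5'-most annotated base; when a GFF3 carries
mRNA children the gene feature's extent already reflects this).
Internally coordinates are handled 1-based inclusive, the GFF3
convention, so no off-by-one conversion crosses the I/O boundary.

Two edge policies are explicit decisions rather than annotations of
fact: windows truncated by a contig edge are **retained** at their
realized length (discarding them would silently shrink the genome
denominator), and a gene whose window is empty (TSS at the first or
last base) is skipped with a warning, not an error. Soft-masked
(lowercase) genome sequence is uppercased on read; `N`s are preserved
and handled by the window-skipping rule above.

## Trend clustering and labeling

Genes are clustered on their replicate-mean FPKM per
(genotype, treatment) cell — four values per gene in the 2×2 design —
after row z-scoring, using Euclidean distance and complete linkage
(`stats::hclust`), and the tree is cut into `nClusters` groups.
Row standardization is what makes the clustering follow *trend shape*:
on raw FPKM, complete-linkage Euclidean clustering groups genes by
expression magnitude, which is not the question. The cost of
standardization is that flat (non-responding) genes become pure noise
directions — their z-profile is noise scaled to unit variance — so
"null" genes never form a tight cluster except in the noise-free limit.
The test suite therefore asserts *exact* partition recovery only on
noise-free planted data, and asserts ≥95% sensitivity for the planted
up/down groups at realistic noise, where null genes may straggle into
labeled clusters (hurting precision, which is not asserted) without
hurting sensitivity.

Each cluster is then labeled from its cell means: with pseudocount $c$
(default 1 FPKM), the cluster-level fold change per genotype is
$\log_2\!\big((\bar{x}_{\mathrm{flooded}}+c)/(\bar{x}_{\mathrm{control}}+c)\big)$,
where $\bar{x}$ averages over the cluster's genes and replicates. A
cluster is `up_enhanced` when the reference genotype's fold change is
positive and strictly larger than the other genotype's, `down_enhanced`
in the mirrored case, and `other` otherwise — ties go to `other`, so
the two labeled lists can never double-count a gene. The cluster count
has no privileged value in this kind of analysis and is a required
parameter (default 8); the labeling rule is applied per cluster, so a
finer cut mainly splits the labeled lists, it does not change the rule.
Ties in the agglomeration itself are resolved by `hclust`'s
deterministic input-order rule; on continuous expression data exact
distance ties have probability zero, and the permutation-invariance
property is asserted on such data.

## The synthetic-data generator

The generator exists so that every stage has a ground truth without any
external download; it is first-class, tested code.

* `syntheticGenome()` lays genes on a regular grid — alternating
  intergenic spacers and gene bodies with a trailing spacer — so every
  TSS has at least `intergenicLen` gene-free bases upstream on either
  strand. With the default spacer (1500 bp) exceeding the promoter
  window (1000 bp), promoter windows never overlap neighboring genes by
  construction, which isolates extraction tests from any overlap
  policy. Bases are i.i.d. with a GC-fraction knob (default 0.36, a
  typical dicot genome-wide value); strands are drawn from the seeded
  stream.
* `plantMotifs()` gives each foreground promoter one planted motif copy
  with probability `foregroundRate` (background promoters analogously),
  at a uniform offset, overwriting exactly $k$ bases so lengths and
  coordinates never change. The log records planted copies only: chance
  occurrences elsewhere are intentional, and downstream tests use
  presence, which is monotone under extra copies.
* `syntheticExpression()` plants `up_enhanced` / `down_enhanced` /
  `null` trend groups with genotype-contrasted log2 fold changes
  (defaults $\pm 2$ in the reference genotype vs $\pm 1$ in the other,
  base level 50 FPKM, 3 replicates) and multiplicative log-normal noise
  (default sd 0.1 on the natural-log scale). Noise is log-normal on
  FPKM rather than negative-binomial on counts because the analysis
  consumes FPKM; no read-level process is simulated.

What the toy data do **not** emulate — and hence what green tests do not
show about real genomes: promoter base composition structure (TATA
boxes, local GC skew), overlapping and nested genes, isoform-resolved
TSSs, assembly gaps (`N` runs), library-size artifacts in FPKM, and
correlated motif co-occurrence. The planted-motif benchmark shows the
statistic recovers a known signal; it cannot certify motif discovery on
a real genome.

All generators are pure functions of their arguments including `seed`,
and the RNG state of the caller is left untouched.

## Numerical choices

* The hypergeometric tail is computed by `stats::phyper(lower.tail =
  FALSE)`, which works in log space internally and is accurate in the
  far tail; the test suite checks it against direct
  $\binom{\cdot}{\cdot}$ summation on an exhaustive grid ($N \le 30$) to
  $10^{-12}$ relative error, and checks strict monotonicity in $k$.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`, verified
  against a from-the-definition step-up evaluation on exhaustive
  permutations.
* The enrichment fraction is plain double arithmetic; no rounding is
  applied anywhere, and the bundled regression table of published
  counts reproduces all printed values to $5\times 10^{-7}$ (printed
  precision is 7–8 decimals).
* Motifs with $k = 0$ keep $E = 0$, $p = 1$; a motif with $n = 0$
  cannot be scored by the fraction (error in the low-level function,
  retained as $E = 0$ rows by the table-level scorer).
* Zero-variance profiles z-score to exact zeros rather than NaN.
* Retained motifs are sorted by enrichment descending with raw p as the
  tie-break, so output order is deterministic.

## Validation scale

The bundled validation runs at desk scale, chosen to exercise every code
path in seconds: a 2,000-promoter genome with a 200-promoter foreground
and 1-kb windows for the planted-motif and null-calibration benchmarks
(20 seeded repetitions for the latter), a 300-gene expression matrix
(100 up / 100 down / 100 null) for trend recovery, and the full
transcription of the published count tables (21 rows; 34,417 genome
promoters) for the enrichment arithmetic. The statistic itself is
scale-free, and the genome-scale inputs of a real study enter only
through the four counts per motif.

## Known limitations

* The pipeline tests *over*-representation only; depletion would need
  the lower tail, which is a one-line change but is not exposed.
* Presence counting ignores motif multiplicity within a promoter;
  occurrence mode captures it but couples the denominators to promoter
  length.
* The bundled cis-element table is a small curated snapshot of
  well-characterized plant elements, not a mirror of any database
  release, and the containment matching rule (pattern within motif, or
  motif within longer pattern, IUPAC-aware) is deliberately permissive;
  both are user-replaceable (`readCisElements(path)`,
  `matchCisElements(..., revcomp = )`).
* Cluster labels depend on the pseudocount at very low expression;
  1 FPKM is conventional but genes expressed far below it are
  effectively unlabelable.
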