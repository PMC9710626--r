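---
title: "Disease modules and hub regulators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease modules and hub regulators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modhub)
```

# The problem

Transcriptomic disease modules — connected sets of genes on a
protein–protein interaction (PPI) network that jointly carry
differential-expression evidence — are a standard device for moving from
a list of differentially expressed genes to a mechanistic hypothesis.
Their practical weakness is size: module methods routinely return
hundreds to thousands of genes, too many to act on. `modhub` implements
a pipeline that shrinks a module to its regulatory core: it infers a
Clique-Sum module, predicts hub transcription factors (TFs) from the
same expression data by consensus over several gene-regulatory-network
(GRN) inference methods, keeps only the module genes that are targets of
hubs whose regulons are statistically overrepresented inside the module,
and finally validates candidate regulators against genomic evidence
(SNP enrichment in binding regions, eQTL fold-enrichment).

# Module inference: Clique Sum

Maximal cliques of the PPI network (found with pivoting Bron–Kerbosch
enumeration via igraph) are scored with Fisher's combined probability
statistic over their members' DE p-values,

$$ S(C) \;=\; -2 \sum_{g \in C} \ln p_g , $$

so a clique of genes with no evidence ($p_g = 1$) scores 0 and the score
grows as member p-values shrink. Genes present in the network but absent
from the DE table are kept with $p = 1$ rather than removed, so cliques
remain cliques.

Significance is assessed against a size-matched permutation null:
for each clique size $s$, `nPerm` random draws of $s$ genes (uniform,
without replacement, from the DE table) are scored, and the empirical
p-value uses +1 smoothing,
$p = (\#\{S_{null} \ge S_{obs}\} + 1)/(n_{perm} + 1)$, which avoids
exact zeros and makes the module monotone in the significance level.
Under uniform p-values Fisher's statistic is exactly
$\chi^2_{2s}$-distributed, which the test suite verifies by a
Kolmogorov–Smirnov check on the permutation null. P-values are
Benjamini–Hochberg adjusted across cliques by default, and the module is
the union of the cliques passing `alpha`.

This null is *competitive*: it asks whether a clique's combined evidence
exceeds that of a random gene set of the same size drawn from the same
study. When a large fraction of all genes carries signal, random sets
carry signal too and the null sharpens accordingly — a property to keep
in mind with very broad DE signatures.

Defaults: `minSize = 3`, `nPerm = 10000`, `alpha = 0.05`, BH
adjustment. All are exposed; an optional degree cap guards clique
enumeration on pathologically dense networks (default: none).

# Hub prediction: consensus outdegree

Four GRN inference methods ship with the package — absolute Pearson and
Spearman correlation, a CLR-style context-likelihood score
(squared correlation standardized per regulator and per target,
combined as $\sqrt{\max(z_r,0)^2 + \max(z_c,0)^2}$), and per-target
multiple regression on all TFs with standardized coefficients. They
cover the correlation, mutual-information-style and regression families
at desk scale; externally computed edge lists join the compendium
through `makeRankedEdgeList()`. All four are deterministic; the `seed`
argument exists for interface uniformity with stochastic plug-ins.

Each method contributes a ranked TF→target edge list. Per-regulator
outdegree is counted among the top `topE` edges, averaged across
methods (`averageOutdegree()`), and the top 10% of TFs by average
outdegree are selected as hubs — the fraction at which consensus hub
prediction has previously performed best, and the package default.

**The edge budget.** Outdegree only discriminates hubs if it is counted
at a sensible depth. Regulatory networks are sparse — on the order of a
few regulators per gene — so the default budget is
`defaultEdgeBudget(nGenes) = min(100000, 2 * nGenes)`. A budget
proportional to the number of *possible* TF–gene pairs (e.g. 10% of
them) reaches far into the noise ranks, where indirect edges cluster: a
decoy TF that is spuriously correlated with a hub inherits edges to that
hub's entire regulon, inflating its outdegree by tens of edges at once.
On the planted benchmark below, recovery of planted hubs degrades from
5/5 at the density-scaled budget to ~3.7/5 when the budget is set to 10%
of all pairs. The same budget trims the consensus network before
filtering (next section), for the same reason: untrimmed, each
significant hub drags its deep noise edges into the filtered module.

The consensus network averages normalized ranks: a method ranking an
edge $r$-th out of $m$ contributes $1 - (r-1)/m \in (0,1]$, methods
that do not rank the edge contribute 0, and edges are ordered by the
mean with deterministic (regulator, target) tie-breaking.

# Hub filtering

For each hub $h$ the genes of the evaluation universe (by default all
consensus-network targets, the hub itself excluded) are cross-tabulated
by membership in the hub's regulon and in the module:

|              | in module | not in module |
|--------------|-----------|---------------|
| target of h  | a         | b             |
| not a target | c         | d             |

Overrepresentation is tested with the one-sided (greater) Fisher's
exact test — the hypergeometric tail $P(X \ge a)$ — and a hub is called
significant when the *sample* odds ratio $ad/bc$ exceeds 2 **and**
$p < 0.05$. Both thresholds are raw (no multiple-testing correction
across hubs), matching the published decision rule; a BH option exists
but is off by default. The filtered module keeps the module genes with
a consensus edge from at least one significant hub; with no significant
hub it is empty, while the per-hub statistics table is always complete.
A hub that is itself a module gene stays only if another significant
hub regulates it.

Two design points were genuinely open and are resolved as follows. The
test is one-sided because the question is overrepresentation; a
two-sided test with the OR > 2 condition would be defensible but
weaker-targeted. The universe is anchored to the consensus-network
targets (not all measured genes) because the comparison is against the
remaining network.

# Enrichment analysis

Modules are evaluated by over-representation analysis: the upper-tail
hypergeometric probability of the observed overlap between the module
and each term of a GMT collection, BH-adjusted across the terms
retained by the size filter (defaults 3–500 genes after background
restriction). The background defaults to all genes in the DE table.
ORA (rather than a ranked GSEA) is used because the evaluated object is
a fixed gene set. User-chosen gene labels can be joined into the output
table. The package ships no ontology; collections are user-supplied
GMTs, and tests use a miniature synthetic collection with one planted
disease term.

# Genomic validation

`permutationEnrichment()` tests whether a SNP set falls inside a set of
binding regions more often than chance: each region is re-placed
uniformly at random on its own chromosome (length preserved, in
bounds), the overlap — SNPs covered by at least one region, each
counted once, half-open interval semantics — is recounted `nPerm`
times, and the empirical p-value is +1-smoothed. The z-score
$(obs - \mathrm{mean}_{null})/\mathrm{sd}_{null}$ is reported alongside
(0, with a warning, when the null is degenerate). Uniform per-chromosome
re-placement was chosen over circular shifts as the plainest null that
preserves region lengths and chromosome assignment; masked or gapped
genome regions are not modeled, so the genome is just a table of
chromosome lengths.

Promoter annotation labels an element as promoter if it intersects
$[\mathrm{TSS} - 2000, \mathrm{TSS} + 500)$ on the + strand (mirrored
around the TSS on the − strand); the window is configurable and the
coordinates follow the 0-based half-open file convention throughout.
eQTL fold-enrichment compares the eQTL fraction of a foreground SNP set
with a background set and tests the 2×2 table with the same one-sided
Fisher's exact test. LD expansion of SNP lists is out of scope: the
input list is assumed already LD-expanded, with any p-value threshold
applied upstream (the CLI accepts an optional p-value filter for
convenience).

# The synthetic-data generator

All tests and the acceptance script run on generated data with planted
truth; nothing is downloaded.

* `generateRegulatoryExpression()` plants hub regulons in expression
  data: hub TF profiles are standard normal; each target is
  `weight * hub + noise` with `|weight| ~ U(0.5, 1.5)`, random sign,
  and Gaussian noise. Decoy TFs regulate at most two targets at double
  noise; unassigned genes are pure noise. The defaults — 5 hubs × 40
  targets, 45 decoy TFs, 200 samples, noise sd 0.5 — are the planted
  benchmark conditions under which hub recovery is asserted.
* `generatePPIWithCliques()` superimposes complete subgraphs on an
  Erdős–Rényi background.
* `generateDETable()` gives signal genes log-uniform p-values between
  1e-8 and the `signalP` cap (default 1e-3) and all others U(0, 1).
  The lower bound is deliberate: with an unbounded heavy left tail a
  single extreme gene drawn into the permutation null can outscore an
  entire planted clique, so the calibration of the module test would be
  driven by the tail of the p-value distribution rather than by clique
  structure.
* `generateGenomeTracks()` places regions uniformly on a 5 Mb
  three-chromosome genome (50 × 1 kb = 1% coverage by default) and
  drops each SNP inside a random region with probability
  `insideFraction` (default 0.5) or uniformly otherwise, with
  stratified eQTL rates (0.4 inside, 0.05 outside).
* `generateDiseaseStudy()` composes the end-to-end fixture: 3 planted
  hubs regulating 60 disease genes that tile 12 planted 5-cliques and
  carry DE signal, 30 decoy-signal genes in 6 further cliques but
  regulated by no hub, 310 background genes, 150 samples. The decoy
  cliques enter the Clique-Sum module but should be discarded by hub
  filtering — which is exactly the property the acceptance checks
  measure (precision of the filtered module vs the unfiltered one).

What the generator does *not* emulate: count-level RNA-seq noise and
normalization artifacts (inputs are assumed normalized; DE p-values are
generated directly, since the pipeline consumes p-values), LD structure
among SNPs, genome gaps/masks, and correlated TF–TF programs. Passing
tests therefore demonstrate the statistical machinery under its stated
model, not robustness to upstream preprocessing.

# Numerical choices and degenerate inputs

* Empirical p-values are +1-smoothed everywhere; no zero p-values.
* Zero DE p-values are clamped to the smallest positive double at
  load (logged).
* Odds ratios with `b*c = 0` are `Inf` when `a*d > 0`, else 1
  (uninformative tables, including all-zero, give OR 1 and p 1 and can
  never be significant).
* Ties are broken lexicographically by identifier in every ranking
  (edges, hubs, consensus), so all outputs are deterministic under a
  fixed seed; reruns of the pipeline are byte-identical and unchanged
  upstream stages are reused via content-hash caching.
* Correlations of constant-expression genes are defined as 0 (logged).
* STRING-style confidence scores are auto-detected as 0–1 or 0–1000 by
  their maximum, and the cutoff (default 0.7 ≙ 700) is interpreted on
  the detected scale. The published use case names STRING but no
  cutoff, so it is configurable.
* Coordinates are 0-based half-open in every file, 1-based closed
  GRanges in memory; the shift is applied exactly once at each IO
  boundary. narrowPeak summit offsets are ignored.
* Gene identifiers are opaque case-sensitive strings; no symbol
  mapping is attempted.

# Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic
data sized for a desk machine: the Fisher oracle sweep covers all
~136k 2×2 tables with N ≤ 40; clique enumeration is cross-checked on
200 random graphs of up to 12 nodes against a 2^n subset oracle; null
calibration uses 10000 permutations against χ²; hub recovery and
filtering precision average over 10 generator seeds; permutation-test
calibration uses 200 replicates of 200 permutations. The full suite
runs in about a minute and a half; the acceptance script in about one
minute.

# Known limitations

* Clique enumeration is exponential in the worst case; very dense PPI
  networks need a confidence cutoff or the degree cap.
* The competitive permutation null weakens when a large share of all
  genes carries DE signal (see above).
* The four shipped GRN methods are desk-scale stand-ins for a larger
  compendium; tree-ensemble methods (GENIE3-class) are intentionally
  out of scope but can be plugged in as external edge lists.
* The exact module sizes and enrichment p-values of any particular
  published case study depend on the external resources used there
  (expression set, STRING version, ontology builds) and are not
  reproduced by this package.
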