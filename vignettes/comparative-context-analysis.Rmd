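---
title: "Characterizing a protein superfamily: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a protein superfamily: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

famcontext implements the downstream, statistical half of a comparative
genomics study of a protein domain superfamily: given curated families,
profile-profile comparison scores, phyletic presence counts, and annotated
genomes, it scores membrane propensity, quantifies phyletic distribution,
detects higher-order family assemblages, and tests the functional
composition of a domain's genomic context. The upstream search machinery
(PSI-BLAST/HMMER searches, profile construction, alignment, structure
prediction) is deliberately out of scope: its outputs are this package's
inputs.

```{r setup}
library(famcontext)
```

## Membrane propensity

For a protein $P_i$ of length $n$, the propensity score is the mean
per-residue value on a hydropathy scale,

$$H_i = \frac{1}{n}\sum_{j=1}^{n} h_j,$$

where $h_j$ is the scale value of residue $j$. The shipped scale is the
transmembrane-tendency scale of Zhao & London (2006), on which residues
favoured in TM helices score positive (F = 1.98 the most) and charged
residues score strongly negative (K = -3.46). Because that scale was
constructed to place the soluble/TM divide near zero, `classify_families()`
defaults to `boundary = 0`; the statistic defaults to the family median,
which matches the way per-family score distributions are usually displayed
(boxplots) and is robust to a few divergent members. Both are explicit
arguments, since any fixed divider on a continuous hydropathy axis is a
convention, not a measurement.

Two residue-handling decisions matter in practice. Ambiguity codes
(X, B, Z, U, O) have no principled scale value, so the default policy skips
them (with a logged count) rather than inventing one; `ambiguity_policy =
"error"` makes the scorer strict. Second, when core-helix intervals are
available, `use_core = TRUE` scores only those segments; otherwise the full
sequence is scored and the result set is flagged full-length. Core-helix
delineation itself requires structural analysis that this package does not
attempt.

Across-family comparison uses the Kruskal-Wallis rank test (via
`stats::kruskal.test`, tie-corrected, $\chi^2$ approximation on $k-1$
degrees of freedom) followed by Dunn's post-hoc test implemented from the
mean-rank formula with tie-corrected pooled variance and Bonferroni
correction over all $k(k-1)/2$ pairs. The `cd_groups` output encodes a
critical-difference diagram: families joined through any non-significant
pair (adjusted $p \ge \alpha$) fall in one connected component. This
grouping coarsens monotonically as $\alpha$ decreases, which the test suite
checks as a property.

## Phyletic spread and depth

For a clade observed across $M$ lineages, with $n_j$ of $N_j$ sampled
species in lineage $j$ carrying at least one member,

$$S = \frac{m}{M}, \qquad D = \frac{\sum_{j=1}^{M} n_j}{\sum_{j=1}^{M} N_j},$$

where $m$ counts lineages with $n_j > 0$. $D$ is the mediant of the
per-lineage occupancy fractions and therefore always lies between their
extremes, weighting each lineage by its sampling depth. Two readings of
the formulas were fixed deliberately: the mediant sums over all $M$
lineages including absent ones (the summation bounds say so), and $n_j$
counts species, so within-species paralogs do not inflate presence. The
bar encoding exported by `phyletic_table()` uses width $S$ and height $D$,
the conventional display for these metrics.

## Family similarity networks

Profile-profile comparison records (query, target, p-value, e-value)
become an undirected weighted graph: reciprocal records of a pair are
combined — by default keeping the smaller p (`max_weight`), since either
direction finding a strong alignment is evidence of relationship — and the
edge weight is $-\log_{10} p$. P-values are the default edge score;
e-values sit behind `use_evalue`. Three numerical choices are explicit
because no convention fixes them: the edge-inclusion threshold defaults to
p = 0.05; zero or underflowed p-values are floored at 1e-300 with a warning
so weights stay finite; isolated families remain as nodes so community
output covers the full family set.

Sub-networks are detected with the Leiden algorithm (igraph
implementation) optimizing modularity at resolution 1 by default, with CPM
available. Leiden is stochastic, so `detect_communities()` runs 20
seed-derived restarts and keeps the best-quality partition; the result is
deterministic given `(seed, n_restarts)`. Whether to threshold edges
before community detection is genuinely open; the default applies the
threshold, and running on the complete weighted graph is one flag away
(`p_threshold = 1`).

## Contextual networks and enrichment

Domain architectures (domains of one product, ordered by alignment start)
and gene neighborhoods (maximal runs of consecutive same-strand genes with
intergenic gaps at most 200 bp, windowed to at most 7 genes per side of a
focal-domain gene) are decomposed into ordered domain strings. Minus-strand
runs are reversed so domain order follows transcription. Consecutive
domains contribute edges to the contextual graph; edge support counts
distinct contributing genomes; repeat-domain self-adjacencies are dropped.
These window rules are standard operon-context heuristics — the underlying
adjacency definition is a modelling choice, so every cutoff is a visible
argument rather than a constant.

A focal domain's dense subgraph is the union of all maximal cliques
containing it (Bron-Kerbosch with pivoting, restricted to the focal node's
closed neighborhood, which provably loses nothing). The clique size floor
defaults to 3: with a floor of 2 the merge collapses to the induced ego
graph — an identity the test suite exploits as an oracle on random graphs,
and which would make "dense subgraph" a trivial notion. When the floor is
at most 3, any edge between merged nodes closes a triangle with the focal
node, so the merged edge set equals the induced edge set on the merged
nodes; the implementation uses this shortcut when it provably applies and
the explicit clique union otherwise, and both paths are tested for
equality.

Enrichment of a functional category among the subgraph's non-focal nodes
is tested against the background of all other graph nodes (the focal node
excluded from both sides, so it cannot bias its own context), with the
one-sided hypergeometric tail computed by exact log-space summation and
Benjamini-Hochberg correction across categories at $\alpha = 0.05$.
Counting is node-level: each domain counts once regardless of how many
genomes repeat it, matching a graph whose nodes are domains. For real
genome collections, a conservation filter
(`min_conserved_genomes`, applied to neighborhood signatures; the `context`
CLI subcommand defaults it to 3) stands in for the sequence-clustering
conservation analysis of full pipelines; it is off by default in the R
function because the synthetic benchmark draws neighborhood contents
independently, where signature recurrence is not a meaningful notion.

## What the synthetic data emulates — and what it does not

The generators produce every input with planted truth:

* **Sequences** use a two-residue mixture (the scale's extremes) whose
  weight solves the target mean propensity in closed form, with
  per-sequence targets drawn Normal(target, `tm_sd`). The default study
  conditions are 30 families of 30 sequences x 120 residues, 18 families
  at target +1.2 (TM-like) and 12 at -1.0 (soluble-like), `tm_sd` = 0.2 —
  separations comparable to the spread between real TM and soluble family
  medians on this scale.
* **Phyletic profiles** are built deterministically to hit planted
  (S, D) on the achievable rational grid (M = 10 lineages, 10 species
  each, 30 clades on an S in 0.1..1 grid with D = 0.6 S).
* **Comparison tables** plant 4 communities of 10 families: within-pair
  p = $10^{-u}$, u uniform on (5, 20); between-pair p uniform on
  (0.05, 1); both directions drawn independently to mimic asymmetric
  profile alignment.
* **Genomes** (200 by default) carry one focal neighborhood among 5
  background neighborhoods of 3-7 tandem genes (fixed 900 bp genes, 50 bp
  gaps, 10 kb between neighborhoods); non-focal slots draw the enriched
  category with probability 0.8 in the focal neighborhood versus 0.2
  elsewhere, otherwise uniformly from the rest of a 100-domain, 4-category
  pool. The pool is kept large relative to the number of adjacency draws
  because real domain vocabularies are; a small pool saturates the
  adjacency graph into a complete graph that carries no contextual signal.

None of this simulates protein evolution, HMM score distributions, genome
rearrangement, or correlated operon content. Passing tests therefore
demonstrate that the statistics recover what was planted under their own
model assumptions — not that the upstream search and curation steps of a
real analysis are error-free.

## Problem sizes and numerical notes

The validation suite runs at desk scale by design: formula oracles on
1,000 random inputs; exhaustive Fisher enumeration for all tables with
N &le; 40; clique oracles on 200 random graphs of at most 12 nodes;
community recovery over 100 seeds; 200 null and 100 planted context
datasets for error control and power. Ties in rank tests use mid-ranks
with the standard tie correction, and a fully constant dataset is rejected
as degenerate rather than scored. All randomness flows through explicit
integer seeds (`withr::with_seed`), so every table the pipeline writes is
byte-reproducible.

## A worked example

```{r example, eval = FALSE}
spec <- simulation_spec(seed = 1)
records <- gen_family_sequences(spec$families, seed = 2)
sets <- family_scores(records, tm_tendency_scale())
table(classify_families(sets))
#> soluble      TM
#>      12      18

ctx <- gen_context_dataset(seed = 4)
res <- context_analysis(ctx$genes, ctx$hits, ctx$labels, "ConeTM")
head(res$enrichment[, c("category", "a", "b", "c", "d", "q_value")], 2)
```

## Known limitations

Architecture and neighborhood adjacencies are pooled into one graph (an
edge attribute records which kind contributed); analyzing them separately
is possible by passing `kinds` to `decompose_contexts()`. The enrichment
background is the non-subgraph remainder of the same contextual graph —
defensible and self-contained, but not the only possible null. GFF3 output
stores one genome per file since the format has no genome field. The Dunn
implementation reports the asymptotic normal p-value; for very small
groups a permutation test is preferable (the suite uses one as an oracle).
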