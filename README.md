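# famcontext

Comparative-genomics toolkit for characterizing a protein domain
superfamily across genomes. It covers the four statistical arms such a
characterization needs once families are curated and searches are done:

1. **Membrane propensity** — per-sequence scores
   `H = (1/n) Σ h_j` on the Zhao–London transmembrane-tendency scale,
   TM/soluble family classification against a score boundary, and
   across-family comparison with Kruskal–Wallis plus Dunn's post-hoc test
   (Bonferroni), summarized as critical-difference groups.
2. **Phyletic metrics** — spread `S = m/M` (fraction of lineages with at
   least one member) and depth `D = Σn_j / ΣN_j` (the mediant of
   per-lineage species occupancy), with the width×height bar encoding.
3. **Similarity networks** — family-relationship graphs weighted by
   `-log10 p` from profile–profile comparisons, with Leiden community
   detection (modularity or CPM, seeded restarts).
4. **Contextual networks** — decomposition of domain architectures and
   gene neighborhoods into a domain-adjacency graph, merging of all
   maximal cliques around a focal domain into its dense subgraph, and
   one-sided Fisher tests (BH-corrected) for functional-category
   enrichment of that subgraph against the rest of the graph.

A seeded synthetic-data module generates every input format with planted
ground truth (family sequence sets with controlled mean hydropathy,
phyletic profiles on an exact (S, D) grid, block-structured comparison
tables with planted communities, and annotated genomes with a planted
neighborhood enrichment), so the whole pipeline is testable offline.

Intended users: computational biologists running gene-neighborhood /
domain-architecture analyses who want the statistics reproducible and
separated from the search machinery (BLAST/HMMER/HHpred etc., which this
package deliberately does not wrap).

## A worked example

```r
library(famcontext)

spec <- simulation_spec(seed = 1)

# 30 families, 18 planted as membrane-propense
records <- gen_family_sequences(spec$families, seed = 2)
sets    <- family_scores(records, tm_tendency_scale())
table(classify_families(sets, boundary = 0, statistic = "median"))
#> soluble      TM
#>      12      18

kruskal_wallis(sets)$p_value      # family scores differ strongly
#> [1] 3.492052e-119

# contextual enrichment around the focal domain "ConeTM"
ctx <- gen_context_dataset(seed = 4)   # 200 genomes, rates 0.8 vs 0.2
res <- context_analysis(ctx$genes, ctx$hits, ctx$labels, "ConeTM")
res$enrichment[1, c("category", "a", "b", "c", "d", "p_value", "q_value")]
#>           category  a  b c  d      p_value      q_value
#> 1 lipid_metabolism 25 48 0 27 9.572338e-05 0.0004786169
```

The enrichment row reads: of the non-focal domains in the focal domain's
dense subgraph, 25 are lipid-metabolism domains and 48 are not, versus 0
of 27 in the rest of the contextual graph — the planted association is
recovered at q ≈ 5e-4.

A command-line wrapper with subcommands `simulate`, `tmscore`,
`phyletics`, `simnet` and `context` is installed at
`system.file("scripts", "famcontext", package = "famcontext")`; every
subcommand takes `--seed`, `--out-dir`, `--log-level` and an optional
`--config` YAML whose values individual flags override.

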