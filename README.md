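# pagnet

Gene-set analytics against interaction networks: cohesion scoring,
size-bias correction, intra-set gene prioritization, enrichment and
set-to-set network construction.

## The problem

Collections of gene sets — pathways, annotated lists, expression
signatures (collectively *PAGs*) — vary enormously in quality: some group
genes that genuinely act together, others are loose associations. `pagnet`
quantifies that, for any corpus of sets and a confidence-weighted
protein–protein interaction (PPI) network, fully offline:

- **CoCo** (cohesion coefficient): for a set of *n* genes with
  `op` of its `n(n−1)/2` member pairs covered by PPI edges and `ot` of its
  `n(n−1)(n−2)/6` trios forming PPI triangles,

  `CoCo = −log10 P(X2 ≥ op) − λ·log10 P(X3 ≥ ot)`

  where `X2 ~ Hypergeom(C(N,2), E, n(n−1)/2)` draws pairs from the
  background of `E` edges among `C(N,2)` possible pairs in the `N`-gene
  universe, and `X3` is the analogous trio statistic over background
  triangles. Large CoCo ⇒ the set is far more internally connected than
  chance.
- **nCoCo**: raw CoCo grows with set size simply because bigger sets test
  more pairs. `pagnet` fits `log2(CoCo) ~ poly(log2 n, 3)` across the
  corpus and rescales: `nCoCo = 2^(log2 CoCo − g(log2 n) + ref)`. nCoCo
  comparisons are size-unbiased (rank correlation with size ≈ 0).
- **RP-score**: ranks genes *inside* a set by a random-walk-with-restart
  weight on the confidence-weighted induced PPI subgraph, boosted by how
  often the gene recurs across the corpus:
  `rp(g) = w(g)·(1 + log2 f(g))`.
- **Enrichment**: hypergeometric upper-tail `P(X ≥ k)` of a query list
  against every set, Benjamini–Hochberg FDR across the tested family, and
  the standard filter chain (type, size 2–1000, cosine similarity ≥ 0.1,
  overlap > 1, nCoCo ≥ 100, FDR ≤ 0.05 — all configurable).
- **Set-to-set networks**: undirected *m-type* edges from significant
  membership overlap (−log10 PMF > 5 and −log10 tail > 10) and directed
  *r-type* edges from enriched gene-regulation flow between exclusive
  members of two sets (PMF < 0.05 and tail < 0.05), with GraphML/SIF
  export.

A deterministic synthetic-data generator (scale-free PPI, planted cohesive
modules, planted cross-set regulation, log-uniform set sizes with an
optional spike at 200) makes every claim testable without downloads.

## Worked example

```r
library(pagnet)

sim <- generate_synthetic(synth_config(seed = 7, n_genes = 600, n_sets = 40,
                                       planted_regulation_auto = 1))
rec <- apply_normalizer(cohesion_records(sim$corpus, sim$ppi))
head(rec[order(-rec$ncoco),
         c("set_id", "n", "theoretical_pairs", "observed_pairs",
           "coco", "ncoco")], 5)
#>     set_id   n theoretical_pairs observed_pairs   coco  ncoco
#> 16 SET0016  12                66             56 178.57 1540.8
#> 19 SET0019  12                66             56 178.57 1540.8
#> 14 SET0014  55              1485           1220 640.00 1160.1
#> 11 SET0011  39               741            175  65.51  233.8
#> 23 SET0023 132              8646           7122 640.00  162.2
```

The top sets are exactly the planted cohesive modules
(`sim$truth$planted_sets` contains SET0014, SET0016, SET0019, SET0023, …).
Note the inversion nCoCo exists for: SET0023 (132 genes) has a saturated
raw CoCo of 640 — larger than SET0016's 178.6 — yet after size
normalization the small, almost fully connected SET0016 (56 of 66 pairs)
ranks far above it.

```r
head(rp_score(sim$corpus$sets$SET0016, sim$ppi, sim$corpus), 3)
#>    set_id   gene weight frequency rp_score rank
#> 1 SET0016 G00154 0.0878         9    0.366    1
#> 2 SET0016 G00284 0.0913         8    0.365    2
#> 3 SET0016 G00482 0.0840        10    0.363    3

r <- build_r_type(sim$corpus, sim$regulation)
sim$truth$planted_regulation   # SET0010 -> SET0040, recovered in r
```

The same flows are scriptable end to end:

```sh
Rscript -e 'pagnet::pag_cli(commandArgs(TRUE))' simulate --seed 7 --out run/
Rscript -e 'pagnet::pag_cli(commandArgs(TRUE))' score --gmt run/corpus.gmt --ppi run/ppi.tsv --out run/
Rscript -e 'pagnet::pag_cli(commandArgs(TRUE))' normalize --cohesion run/cohesion.csv --out run/
```

Every run writes a `manifest.json`; identical configurations produce
byte-identical output trees.

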