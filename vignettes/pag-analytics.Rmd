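---
title: "Scoring gene-set cohesion and building set-to-set networks with pagnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene-set cohesion and building set-to-set networks with pagnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pagnet)
```

# Scope and model

`pagnet` analyzes a *corpus* of gene sets (PAGs: pathways, annotated lists,
gene signatures, types P/A/G) against two molecular networks: an undirected
protein–protein interaction (PPI) network with edge confidences in [0,1],
and a directed gene-regulation network. All statistics share one background
population: the corpus *universe* of N genes — by default the union of all
set members, optionally extended by a declared background list. Symbols are
trimmed and uppercased at ingest, because every downstream computation is
symbol-exact set arithmetic.

## Cohesion: CoCo

A set of n genes contains n(n−1)/2 unordered pairs and n(n−1)(n−2)/6
trios. Let `op` be the number of pairs covered by a PPI edge (passing the
confidence cutoff) and `ot` the number of trios whose three pairwise edges
all exist (full triangles — connected-but-open triples deliberately do not
count, since a triangle is the strongest three-way evidence and the open
alternative would mostly re-count degree). The null model asks: if
n(n−1)/2 pairs were drawn at random from the C(N,2) possible pairs in the
universe, of which E are actual edges, how surprising is covering at least
`op`? Formally

```
S2 = −log10 P(X2 ≥ op),  X2 ~ Hypergeometric(C(N,2), E, n(n−1)/2)
S3 = −log10 P(X3 ≥ ot),  X3 ~ Hypergeometric(C(N,3), T, n(n−1)(n−2)/6)
CoCo = S2 + λ·S3,  λ = 1 by default
```

with T the number of triangles in the background network. Tail
probabilities are floored at 1e-320 before the log, so each term saturates
at 320 (a set like the 132-gene planted module in the README, with seven
thousand covered pairs, hits CoCo = 640 exactly). Singletons carry no
cohesion: scoring one is an error, and corpus-level reports give them
CoCo = nCoCo = 0. An empty PPI network yields CoCo = 0.

This functional form — pair and trio coverage scored by hypergeometric
surprise — is this package's documented definition. It is designed to
reproduce the published *behavior* of such scores (coverage-driven,
size-biased raw score; see the acceptance tests), not any specific
database's printed values.

The pair/trio null treats the drawn pairs as exchangeable, which ignores
the constraint that a set's pairs share vertices; that makes S2/S3
conservative orderings rather than calibrated p-values. Since CoCo is used
as a score, not a test, this is acceptable and is the standard trade-off.

## Size normalization: nCoCo

Raw CoCo grows with n under any fixed density, simply because larger sets
draw more pairs. The normalizer fits, across all corpus sets with CoCo > 0,

```
log2(CoCo) = g(log2 n) + ε,   g a polynomial of degree 3 (default)
```

by ordinary least squares on the raw polynomial basis, then rescales:

```
nCoCo = 2^( log2 CoCo − g(log2 n) + ref ),   ref = mean fitted value
```

Sets exactly on the trend map to the common value `2^ref`, so nCoCo is a
residual score re-expressed on the original scale. Choices worth recording:

- **Log-log space.** Set sizes span three decades and score distributions
  are conventionally binned in powers of two; the trend is smooth and
  near-linear there.
- **Degree 3 default.** Flexible enough for curvature at both ends of the
  size range without chasing noise; configurable (`--degree`). Degree 0
  reduces to mean-centering, and the fit errors out when fewer than
  degree + 2 positive records exist or all sizes coincide
  (rank deficiency).
- **CoCo = 0 sets** are excluded from the fit (log of zero) but keep
  nCoCo = 0 in reports, and summary tables count both the "CoCo > 0" and
  "nCoCo > 1" populations, since published release notes have used both
  filters without distinguishing them.
- **Saturation caveat.** Sets whose CoCo hit the 640 cap compress the top
  of the trend; with realistic corpora this affects only extreme planted
  modules.

`cp50(scores, groups)` summarizes per-source quality as the score at
cumulative fraction 0.50 under the lower-interpolation (type-1 quantile)
convention: `cp50(c(1,2,3,4))` is 2, not 2.5.

A monotonicity note: raising the confidence cutoff filters both a set's
observed coverage and, in `cohesion_records`, the background (E, T). With
the background held fixed, less coverage can only lower CoCo — that is the
property the tests assert. If the background is recomputed at the stricter
cutoff, shrinking E can occasionally raise the score; both quantities are
legitimate, they answer different questions.

## Intra-set prioritization: RP-score

Gene weights come from a random walk with restart (RWR) on the
confidence-weighted subgraph induced by the set's members: with restart
probability r (default 0.7), the walker teleports to a uniform
distribution over members, otherwise steps along edges proportionally to
confidence. The fixed point solves `p = (1−r)·W·p + r·u`; members with no
passing edge generate no outflow and retain only restart mass, and the
result is renormalized to sum to exactly 1. Power iteration stops when
successive iterates differ by < 1e-10 in L1 (cap 1e5 iterations); tests
verify agreement with a dense linear solve to 1e-8. RWR was chosen because
it blends direct and indirect interaction evidence — on a star graph the
hub always outweighs the leaves for any r < 1 — and r = 0.7 is the common
default in network-propagation practice; smaller r diffuses further.

The final score multiplies in corpus membership frequency f(g):

```
rp(g) = w(g) · (1 + log2 f(g))      ("boost", default)
```

The log damping keeps the factor modest (frequency 8 ⇒ ×4). Whether
recurrence should reward or penalize a gene is genuinely open — published
examples promote well-known multi-pathway genes, which is the boost
behavior — so the mode is a flag (`boost`/`penalize`/`off`). Ties break
lexicographically by symbol so ranks are deterministic.

## Enrichment

For a query list q (unmapped symbols dropped with a warning; a fully
unmapped query is an error naming the symbols), each set passing the
*pre-filters* (type in {P,A,G} selection, size in [2, 1000]) is tested:

```
p = P(X ≥ k),  X ~ Hypergeometric(N, |set|, |q ∩ universe|)
```

The inclusive tail (counting k itself) is used — the exclusive variant
would assign overlap-1 sets p < 1 even when one shared gene is expected.
BH-FDR is computed across exactly the tested family (the pre-filter count
is the denominator, recorded as `attr(res, "n_tested")`), then the
*post-filters* decide `passed`: cosine/Ochiai similarity
`|q∩S|/sqrt(|q||S|)` ≥ 0.1, overlap > 1, nCoCo ≥ 100, FDR ≤ 0.05
(defaults mirror the standard advanced-search screen; every threshold is a
flag). Cosine was preferred over Jaccard as the similarity because it is
less punishing when query and set sizes differ by an order of magnitude;
Jaccard is available via `similarity_method = "jaccard"`.

## Set-to-set networks

**m-type** (membership): for every unordered pair with overlap k ≥ 1,
V1 = −log10 PMF(k) and V2 = −log10 P(X ≥ k) under
X ~ Hypergeometric(N, |A|, |B|); an edge requires V1 > 5 AND V2 > 10.
Since P(X ≥ k) ≥ PMF(k), the PMF threshold is partially redundant — the
dual filter is kept for fidelity to the published thresholds. Logs are
base 10 and the tail is upper: the source never states either, and this
reading makes the two printed thresholds (5, 10) mutually consistent.

**r-type** (regulation): for each ordered pair (A, B), k counts regulation
edges from A∖B to B∖A — shared members are excluded from both sides, since
a gene regulating its own set-mates would otherwise guarantee hits. The
null is X ~ Hypergeometric(N(N−1), E, |A∖B|·|B∖A|) over ordered gene
pairs; a directed edge needs k ≥ 1, PMF < 0.05 and tail < 0.05, and is
weighted by −log10 of the tail. Endpoints classify as sPAG (size 1) or
mPAG (size > 1); `classify_and_count` tallies all four direction
categories including s→s, which published tables omit.

Exports: SIF (`source kind target`) and hand-written GraphML with node
attributes (type, size, degree, optional score) in sorted order, so equal
inputs give byte-equal files; round-trips through igraph's GraphML reader
are tested.

## The synthetic world

`generate_synthetic(synth_config(...))` produces a corpus, PPI network,
regulation network and truth labels, byte-deterministic under the seed
(all randomness flows through R's RNG, which is restored afterwards so
callers' streams are undisturbed). What it emulates, and the defaults:

- **Set sizes**: log-uniform on [1, min(1000, n_genes)] — gene-set corpora
  are right-skewed over three decades — with an optional spike at 200
  (probability 0.05 by default) mimicking curated signature collections
  that standardize on 200-gene signatures; the spike is where size bias
  distorts raw CoCo most.
- **PPI**: preferential attachment (m = 3 edges/vertex) for a scale-free
  degree tail, edge confidences uniform on [0.5, 1] as in
  confidence-scored interaction databases.
- **Planted cohesion**: 20% of sets with ≥ 3 members get their induced
  subgraph filled to edge density ≥ 0.8 — a construction guarantee, which
  the tests assert directly.
- **Regulation**: 2000 uniform background edges plus planted pairs wiring
  30% of the cross-set ordered pairs between chosen sets. Pairs can be
  named by index (erroring if a pair has no exclusive members) or chosen
  automatically from the largest eligible sets (`planted_regulation_auto`).

What it does **not** emulate: real corpora's nested/redundant set
structure, hub-biased set membership, confidence correlated with degree,
and any organism-specific identifier scheme. A green test on this world
establishes algorithmic correctness and the stated statistical properties
(bias removal, truth recovery), not biological performance on a real
database.

## Determinism and the CLI

`pag_cli()` exposes simulate/score/normalize/rank/enrich/net/summary with
every threshold as a flag. Data goes only to files, logs to stderr, and
each run writes `manifest.json` (subcommand, parameters, package version).
The manifest records input files by basename and omits the output
directory, so a run's identity is its configuration — two runs of the same
config are byte-identical, which the acceptance suite checks end to end.

## Known limitations

- CoCo saturates at 320 per term (the 1e-320 probability floor); extremely
  cohesive large sets tie at 640.
- The pair/trio hypergeometric nulls ignore vertex-sharing between a set's
  pairs (scores, not calibrated p-values).
- The all-pairs m-/r-type builders are quadratic in corpus size — intended
  for corpora up to a few thousand sets, not millions of pairs.
- BH assumes the tested sets' p-values are exchangeable under the null;
  heavily overlapping sets violate independence (BH remains the standard
  practice).
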