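---
title: "Percolation matching of PPI networks: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percolation matching of PPI networks: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(properalign)
```

## The alignment model

A PPI network is an undirected simple graph G(V, E) over protein
identifiers. Given G₁(V₁, E₁), G₂(V₂, E₂) and a table 𝒮 of BLAST bit-scores
for couples in V₁ × V₂, the aligner builds a partial injective mapping
π : V₁ → V₂ in two stages.

**Stage one (seeding)** treats a high bit-score as strong evidence that two
proteins correspond, and a low one as no evidence at all. Couples with score
≥ ℓ are matched greedily in descending score order; each match forbids every
other couple sharing one of its proteins; equal scores are resolved by a
uniform random draw. The result is a maximal one-to-one matching among
couples above the threshold.

**Stage two (percolation)** is purely structural. A couple [i′, j′] is a
*neighbour* of a matched couple [i, j] when (i, i′) ∈ E₁ and (j, j′) ∈ E₂;
the *score* of an unmatched couple is its number of matched neighbours. The
couple with the maximal score is matched permanently, provided the score
reaches r, and its unmatched neighbour couples gain a point; ties are broken
by the smallest degree difference, then smallest degree sum, then a uniform
draw. The process stops when no fully-unmatched couple reaches r. Because
matches are permanent and scores only grow as π grows, checking the final
state certifies termination, and the suite does so after every run.

The underlying assumption is evolutionary: if both observed networks derive
from a common ancestor by *loss* of proteins (probability 1 − t each) and of
interactions (probability 1 − s each), then true couples accumulate common
matched neighbours faster than false ones, and a correct seed set percolates
to most of the true correspondence. Deviations from that model — gene
duplication, gained interactions, systematic ascertainment bias between
interactome screens — are exactly the regimes where the greedy, irrevocable
matching can go wrong.

## Parameters

* `ell` (ℓ, bit-score units, default 150): minimum sequence similarity for a
  seed. Raising it shrinks the seed set toward higher-confidence couples;
  because percolation refills the alignment, the final size is far less
  sensitive to ℓ than the seed count is (the package's acceptance run shows
  the seed set shrinking by more than half between ℓ = 150 and ℓ = 600 while
  the final alignment size stays essentially constant).
* `r` (matched common neighbours, default 1): structural evidence required
  to match a couple. A couple containing a node of degree < r can never be
  matched, so on real interactomes — where a large share of proteins have
  degree one — r = 1 is the practical operating point; larger r makes
  individual matches more reliable at the cost of coverage.
* `delta` (δ, conserved in-pathway interactions, default 4): threshold for
  calling a pathway successfully aligned in `pathway_recall()`. δ ≥ 2 is the
  sensible minimum (one conserved edge is too weak a signal); the default 4
  asks for a small conserved subnetwork.
* `seed`: every random draw (seed-score ties, percolation ties, all
  generators) comes from R's RNG stream, so one `set.seed()` — or the
  `seed` argument of `proper()` — reproduces a run exactly.

## Numerical and algorithmic choices

* The percolation engine keeps candidates in a max-priority queue keyed by
  (score, −degree gap, −degree sum) with *lazy invalidation*: entries whose
  couple has been matched or whose recorded score is stale are discarded
  when popped. A couple's score never decreases, so a discarded entry is
  stale forever and the scheme is exact; the test suite verifies the engine
  couple-for-couple against a naive full-rescan implementation on hundreds
  of random instances, including the RNG draw order.
* Random tie-breaks draw uniformly from the tied set materialized in
  canonical lexicographic couple order, making results identical across
  platforms for a fixed seed. A draw is consumed only when the tie is real
  (more than one candidate survives all deterministic criteria).
* Tie-breaking uses static input-network degrees, not residual degrees.
* Seeds enter π as a block before any scoring, so initial candidate scores
  reflect the full seed set rather than an arbitrary seed order.
* Score comparisons in seeding are exact on the stored floating-point
  values; no epsilon grouping. Bit-scores arrive as printed decimals, and
  grouping would silently change which couples count as tied.
* Seed couples whose proteins are absent from the networks are admitted
  (the seeding rule operates on 𝒮 alone) with a warning; they occupy their
  partners but cannot percolate.
* Duplicate similarity entries keep the maximum score; duplicate edges and
  self-loops are dropped with a warning; isolated nodes are kept, since
  |V₁| is the denominator of NC, ANBS and the LCSC share.
* Measures with a zero denominator (EC on an edgeless network, ICS on an
  edgeless image, recall with no eligible pathway, precision of an empty
  alignment) are reported as `NA`, never as 0.
* A couple's GO-consistency with an empty term union is 0, keeping the GOC
  sum over V₁ well defined; proteins absent from the annotation file have
  empty term sets. No GO-namespace filter is applied by default; the
  experimental-evidence filter `{EXP, IDA, IMP, IGI, IEP, IPI}` is opt-in.
* ANBS requires a positive self bit-score for every aligned protein (the
  error names the offending protein); couples without a recorded
  cross-score contribute 0 to the sum.
* `evaluate_alignment()` reorients its inputs so the smaller network plays
  G₁ (the measures assume |V₁| ≤ |V₂|) and records the orientation; the
  aligner itself preserves the user's network order.
* The non-overlapping pathway subset uses a deterministic greedy rule:
  pathways by decreasing total size, kept iff disjoint from everything kept
  so far on both sides. Other selection rules are defensible; this one is
  reproducible and documented.

## The synthetic generator

`sample_bigraph(n, p, t, s)` draws an Erdős–Rényi ancestor G(n, p) and two
independent descendants: nodes survive with probability t, edges with both
endpoints surviving are kept with probability s. `noisy_copy(g, s)` is the
single-network variant — node *and* edge sampling share the one probability
s, and nodes left isolated by edge sampling are removed by default (pure
node-sampling expectations overestimate observed network sizes when
degree-zero proteins are unobservable; the flag `drop_isolated = FALSE`
preserves them). `sideinfo_table()` reveals a Bernoulli(fraction) subset of
the true couples with a score of 2ℓ (safely above threshold) and unit
self-scores; a score generator argument produces heterogeneous score
distributions, and a spurious-couple rate is available for robustness
studies (default 0: by default the side information contains no false
couples).

What the generator emulates: divergence by random loss, partial and
fully-correct homology knowledge, known ground truth. What it does not:
duplication and divergence, hubs and degree heterogeneity of real
interactomes, assay noise that *adds* edges, biased (non-uniform) homology
coverage. Passing the synthetic benchmarks therefore demonstrates that the
implementation behaves correctly under the loss-only model, not that any
particular accuracy will carry over to a given pair of real interactomes.

Default study conditions follow the benchmark setup: a base network of about
1000 nodes with mean degree ~10 (ER p = 0.01), noise levels 1 − s between 5%
and 25%, side information for 50% of proteins, ℓ = 150, r = 1. The test
suite runs 10 replicates per noise level at full size (seconds per
replicate with the compiled engine) and scales the purely statistical
property checks down to a few hundred nodes.

## Known limitations

* Greedy permanent matching cannot revise an early mistake; in ambiguous
  regions (automorphic subgraphs, near-twin proteins) ties are resolved
  arbitrarily and NC degrades even at zero noise.
* Stage two never consults sequence similarity, by design; a couple with
  overwhelming sequence evidence but score r − 1 will not be matched.
* Only two-network alignment is supported; no directed or weighted graphs.
* The pathway measures credit a protein only for landing in the *same*
  pathway id; biologically equivalent placements in related pathways score
  zero.
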