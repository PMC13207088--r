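---
title: "Methods: cross-disease interactome convergence and molecular bridges"
author: "bridgenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-disease interactome convergence and molecular bridges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgenet)
```

## The question the package addresses

Two diseases can share no susceptibility genes yet converge on a common
pathophysiological module: the proteins encoded by their distinct risk-gene
sets may interact densely within the human interactome. The motivating case
is chronic kidney disease (CKD) and Parkinson's disease (PD) — an
epidemiologically linked pair with zero overlap between their
high-confidence risk genes. `bridgenet` quantifies this protein-level
convergence and extracts the direct cross-disease interactions ("molecular
bridges", e.g. the apolipoprotein A1 to alpha-synuclein edge) that could
mediate it.

The pipeline has six phases: (1) tiered curation of gene–disease
association tables; (2) construction of a confidence-thresholded
protein–protein interaction (PPI) network over the union of the two gene
sets, with topology metrics and an edge-enrichment test; (3) extraction and
prioritization of cross-set bridges; (4) hypergeometric over-representation
analysis (ORA); (5) hub ranking by Maximal Clique Centrality (MCC),
together with tissue-expression and vesicle-catalog annotation joins; (6) a
threshold sensitivity analysis.

## Curation model

Gene–disease associations carry a confidence score and an Evidence Index
(EI, the fraction of supporting publications), both in [0, 1]. Curation is
tiered and disease-specific: the default thresholds retain genes with score
>= 0.8 and EI >= 0.4 for the first disease and score >= 0.6, EI >= 0.4 for
the second, reflecting the different maturity of the two genetic
literatures. All comparisons are inclusive (`>=`); a gene with several rows
passes if any row passes. Raising a threshold can only shrink the retained
set, which the test suite asserts as a monotonicity property.

## Evidence combination

Edge confidence follows the STRING probabilistic convention. Each of seven
evidence channels (experimental, curated database, text-mining,
co-expression, neighborhood, fusion, co-occurrence) reports a score
$s_i \in [0,1]$. With prior $p_0$ (default 0.041, the conventional
probability that a random protein pair interacts), each channel is
prior-corrected,

$$s_i' = \max\!\left(0, \frac{s_i - p_0}{1 - p_0}\right),$$

corrected channels are combined as independent probabilities,
$S' = 1 - \prod_i (1 - s_i')$, and the prior is restored,
$S = S'(1 - p_0) + p_0$; a pair with no channel above the prior scores 0.
The formula is monotone in every channel, invariant to channel order, and
the single-channel case round-trips unchanged — all asserted in tests
against an independently coded scalar evaluation. Analyses built on STRING
exports rarely restate this formula; adopting the documented STRING
convention is a design choice made here because it reproduces the semantics
of exported scores and is independently testable.

## Network construction and the enrichment null

The network keeps edges with combined score at or above the confidence
cutoff (default 0.700) whose endpoints both lie in the union of the two
gene sets; curated genes without surviving edges remain as isolated nodes.
Reported topology metrics are the node and edge counts, average degree
$2E/N$, and the network clustering coefficient — the unweighted mean of
local clustering with nodes of degree < 2 contributing 0, the only
convention consistent with a single [0, 1] network-level value.

Edge enrichment asks whether the observed edge count $E$ exceeds the count
expected for a random network of the same size and degree distribution.
Two nulls are provided:

* **Analytic (Poisson).** With expected count $\lambda$ — supplied
  externally (platforms such as STRING print one) or estimated by the swap
  null — the p-value is the Poisson upper tail $\Pr(X \ge E)$. Poisson is
  the standard approximation for edge counts under degree-preserving
  randomization; at the scales involved a binomial alternative differs
  negligibly.
* **Degree-preserving permutation.** The candidate edge list is rewired by
  double-edge swaps (default 100 attempted swaps per edge; rejected
  proposals count as staying in place, preserving the uniform stationary
  distribution over simple graphs with the fixed degree sequence). Scores
  travel with edges, so passing the unfiltered candidate set lets rewiring
  carry high-confidence edges outside the disease union; the replicate
  statistic is the count of above-cutoff edges inside the union, and
  $p = (1 + \#\{\text{replicates} \ge E\})/(1 + R)$. Every replicate's
  degree sequence is asserted equal to the original in the test suite, and
  on six-node graphs the null mean is checked against exhaustive
  enumeration of all graphs with the same degree sequence.

When $\lambda = 0$ with $E > 0$ the p-value is reported as the bound
$1/(1+R)$ with an explicit flag rather than 0.

## Bridges

A bridge is an edge with one endpoint in each disease set and combined
score strictly greater than the bridge threshold (default 0.700). The
strict comparison follows the reporting convention for bridges; network
construction itself is inclusive. The asymmetry is deliberate and
documented: at the default cutoff the packaged 15-edge reference fixture
gives the same answer under both readings.

Prioritization is a stable total order: score tier first (combined > 0.8
before the rest), then evidence-channel consistency (experimental or
curated-database support, then other non-text-mining channels, then
text-mining only), then combined score descending, then lexicographic
endpoint pair. The evidence tiers operationalize a stated preference for
experimentally validated interactions over text-mined ones; no numeric
weighting is published, so a minimal ordinal encoding was chosen. A
packaged theme map assigns the named bridge genes to three non-exclusive
functional themes (inflammation/ECM, metabolic/RAS, lipid/protein
homeostasis) for descriptive tallies.

## Hub ranking

MCC of a node $v$ is $\sum_{C \in M(v)} (|C|-1)!$ over the maximal cliques
containing $v$; when the neighborhood of $v$ has no internal edge every
such clique is a single edge and the score reduces to the degree, the
documented fallback. Maximal cliques come from pivoting Bron–Kerbosch
(igraph); enumeration, MCC and betweenness are all verified against
exhaustive subset/path-counting oracles on graphs of up to 10 nodes across
100 seeded trials. Betweenness is reported unnormalized since only ranks
are consumed downstream. MCC accumulates in double precision: factorials
are exactly representable far beyond clique size 20 and remain finite to
size 170, so at the package's scales (networks of ~10²
nodes) ranking is unaffected; an arbitrary-precision integer path was
considered and rejected as unnecessary at these sizes.

## Over-representation analysis

For a term with $K$ members in a universe of $M$ genes and $k$ hits in a
query of $n$, the p-value is the hypergeometric upper tail
$\Pr(X \ge k)$, BH-FDR is applied across all terms tested in one call (one
family, mirroring common web-tool behavior), and the effect size is
STRING's "strength", $\log_{10}(k / (nK/M))$. Terms with fewer than 2
in-universe members are skipped as degenerate. The default universe is the
analysis network's own gene union: published FDRs from proprietary
genome-scale backgrounds cannot be reconstructed, so they are format
examples rather than targets, and the universe is overridable. Tail
probabilities are validated against exhaustive enumeration of all draws
for every configuration with $M \le 12$.

## Synthetic data generator

The generator emulates the study conditions: 64 + 17 disjoint gene sets,
tiered thresholds 0.8/0.4 and 0.6/0.4, a 0.700 cutoff, and 15 planted
cross-set bridges with combined scores drawn from 0.701–0.970 — the
observed range of the reference bridge table. Members' association rows are
drawn to pass their thresholds exactly; two decoy rows per member fail on
score or EI. Within-set edges appear with probability 0.12 (chosen to give
edge counts of the observed order on the default sizes) at scores at or
above the cutoff; distractor cross-set edges appear only strictly below the
cutoff, with a 0.105 safety margin so that no +/-0.1 cutoff perturbation
can promote a distractor into a bridge; background genes outside both sets
carry edges that exercise network restriction and the permutation null.

Planted combined scores are decomposed into channels algebraically: the
text-mining channel is anchored near 0.400 (a jittered anchor, echoing the
recurring text-mined evidence level in real exports) and the experimental
channel is solved so recombination reproduces the target within 1e-9; low
targets fall back to a single channel. The central recovery property —
bridge extraction at the configured cutoff returns exactly the planted
pairs, precision = recall = 1 — is asserted across 50 seeded
configurations.

What the generator does **not** emulate: literature co-mention structure,
correlated channels, scale-free degree structure (within-set wiring is
Erdős–Rényi), or realistic gene symbols. Passing tests therefore
demonstrate correctness of the algorithms under controlled structure, not
performance on real exports.

## Sensitivity analysis

The grid is the factorial product of offsets (default −0.1, 0, +0.1) on the
two association-score thresholds and the confidence cutoff (the bridge
threshold moves with the cutoff); EI thresholds are not varied. Stability
is quantified as the Jaccard index of bridge sets and the top-10 hub
overlap fraction against the baseline point — the published analysis states
stability only qualitatively, so these minimal quantitative measures make
it assertable. The baseline self-comparison equals 1 exactly, out-of-range
points are skipped with a warning, and bridge sets are provably nested
along the cutoff axis (both filters only tighten), which the tests assert.

## Numerical and degenerate-input choices

* Edge identity is unordered; canonical storage is lexicographic, and
  duplicate unordered pairs merge by per-channel maximum (conservative and
  deterministic).
* Table writers print full-precision decimals so write-then-read
  round-trips are exact; the human-facing report rounds combined scores to
  3 decimals, average degree to 2, clustering to 3.
* Empty networks, empty bridge sets, all-isolated graphs, single-term
  GMTs, and genes without expression rows all return well-formed empty or
  flagged results rather than errors; truly invalid inputs (self-loops,
  out-of-range scores, malformed tables) raise classed validation/format
  errors naming the offending row.
* Reports contain a parameter/seed provenance header and no timestamps, so
  identical inputs and seed give byte-identical output directories.

## Problem sizes used in the test suite

Oracle-verified checks run on graphs of 4–10 nodes (exhaustive subset and
path enumeration), ORA enumeration on universes up to 12 genes, planted
recovery on sets of 10–30 + 5–9 genes across 50 seeds, and the full
end-to-end pipeline on the packaged 81-gene fixture. These sizes keep every
brute-force oracle exact while exercising the same code paths used at
realistic scale.

## Known limitations

* Identifier handling is case-folding only; no alias or cross-database
  mapping.
* The permutation null mixes by double-edge swaps; for very sparse or
  near-complete graphs the chain may mix slowly, and the replicate count
  is the user's control.
* Published expected-edge counts from external platforms cannot be
  re-derived without their full channel-score ensembles; the analytic null
  therefore accepts an external expected count as an input.
* ORA performs no annotation-graph propagation (e.g. GO ancestors).
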