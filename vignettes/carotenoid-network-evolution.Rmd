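---
title: "Methods: carotenoid network evolution on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carotenoid network evolution on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caronet)
```

## The model world

Avian carotenoid metabolism is represented as a directed graph whose nodes
are compounds and whose edges are unary enzymatic reactions (one
substrate, one product). A distinguished set of *dietary* compounds seeds
all metabolism: birds cannot make carotenoids from non-carotenoids, so
every expressed (plumage-deposited) compound must be reachable by a
directed path from a dietary entry point. Reversible chemistry appears as
two opposing edges only when both are curated in the input; parallel
edges and self-loops are invalid.

Species observations arrive as inventory records — (species, compound,
tissue evidence) with the closed vocabulary *diet, plumage, plasma,
liver, gut, fat, faeces, seminal_fluid, integument*. Evidence maps to
roles: `diet` to *dietary*, `plumage` to *expressed*, any other tissue to
*intermediate*; roles may overlap (a dietary compound deposited unchanged
is dietary and expressed). When several inventories exist per species
(sexes, ages), records are pooled so the fullest network is used.

### Minimum and maximum networks

The *minimum* network answers "what is the least machinery this species
needs": a union of cheapest dietary-to-expressed paths on the global
network. The path combination is chosen to minimise the size of the union
(exhaustive over combinations of per-target shortest paths up to a budget
of 4096 combinations, greedy beyond), with deterministic tie-breaking —
first by coverage of observed compounds, then lexicographic node order —
so rebuilding is byte-identical. Unobserved compounds required on a
chosen path are inserted with role *intermediate*. The *maximum* network
answers "what could this species' machinery do": all global reactions
among recorded compounds that lie on some dietary-to-expressed path
(substrate reachable from the diet, product leading to an expressed
compound). Interior path nodes are restricted to recorded compounds by
default; `allow_unrecorded_interior = TRUE` relaxes this, because the
curation convention behind "reactions among recorded compounds" is
genuinely ambiguous. A reaction directly linking two dietary compounds is
removed unless the pair is experimentally whitelisted for the species —
multiple dietary entries are ecological alternatives, not substrates of
one another.

Descriptive analyses use minimum networks; redundancy-sensitive measures
(knockout robustness, vulnerability, degree-preserving null comparisons)
use maximum networks, since a minimal path union has little redundancy by
construction.

## Distances, trees, and comparative tests

The metabolic distance between two networks is the fraction of compounds
plus reactions in which they differ (symmetric difference over union,
computed jointly over the compound and reaction sets). It is a
Steinhaus-type metric: symmetry and the triangle inequality are
property-tested on random network triples. Role-restricted distances
(dietary / intermediate / expressed subnetworks) keep a reaction only
when both endpoints carry the role; a pair of empty filtered networks
yields a missing value, never zero.

Standard tree machinery is delegated: neighbour joining to `ape::nj`
(negative branches clamped to zero with the deficit moved to the sibling
edge, count reported), Robinson–Foulds counts to `phangorn::RF.dist`,
strict consensus to `ape::consensus(p = 1)`, patristic distances to
`ape::cophenetic.phylo`, and independent contrasts to `ape::pic`. The
package's own contributions — the distance, the network constructions,
the null models, scope, and the gain/loss machinery — are implemented
here and cross-checked against independent oracles in the tests.

Divergence–time regressions bin species pairs by patristic distance into
half-open windows (default 20 My) and report the standardized slope
`b_ST` (the Pearson correlation, i.e. the slope in SD units) per bin and
role, plus an overall Spearman rank correlation. Species pairs are not
phylogenetically independent; p-values are nominal and labelled so. The
robustness–elongation association is instead tested with Felsenstein
contrasts and regression through the origin; polytomies are resolved with
zero-length edges and zero branch lengths replaced by 1e-8 My so contrast
scaling stays defined.

## Null models

"Degree-preserving randomization" is implemented as the double-edge-swap
(switching) null: repeated swaps `(u1→v1, u2→v2) → (u1→v2, u2→v1)`,
rejecting self-loops and parallel edges, 10×|R| attempted swaps by
default, roles pinned to nodes. A plain Erdős–Rényi draw would not
preserve degrees, so the degree-preserving reading is the only coherent
one. z-scores are (observed − null mean)/null SD over B replicates;
replicates where a metric is undefined (no surviving dietary-to-expressed
path) are excluded and counted, and an SD of zero flags the comparison
degenerate rather than producing an infinite z.

Greedy agglomerative modularity (igraph's fast-greedy, undirected
projection, seeded tie-breaking) is used because no specific optimizer is
canonical for these data; the score is floored at the trivial
one-community partition (modularity 0), which greedy merging can
undershoot on degenerate graphs.

## Gain/loss model and ancestral networks

Compound and reaction presence/absence evolve as independent two-state
continuous-time Markov chains with gain rate α and loss rate β
(events/My). The likelihood is computed by the pruning algorithm with a
stationary root prior (β/(α+β), α/(α+β)), optimised over log-rates by
bounded quasi-Newton from three seeded starts; all characters can be
pooled (one α, β) or fitted per character (invariant characters hit the
box bound and are flagged). Marginal ancestral posteriors come from
up–down message passing; the MAP state is *present* only when the
posterior exceeds 0.5, ties resolving to absent. Character independence
is an approximation: the endpoint-consistency rule (a reaction cannot be
present without both endpoint compounds) is enforced after assembly, not
inside the likelihood, and dropped reactions are counted per node.

Branch elaboration rate = reaction gains / branch duration. "Highly
elevated" is the upper quartile of the *strictly positive* rates
(including the zero-rate majority would collapse the quartile on
stasis-heavy trees); zero-gain branches are stasis-or-shrinkage. For
every branch pair where the ancestral branch is highly elevated, the
descendant regime and whether the descendant's node network gained a new
dietary compound are tabulated; `k` of `n` elevated-to-elevated
transitions with dietary gains are tested against 0.5 with the
continuity-corrected one-proportion z. Waiting times per compound
distance bin are total tree time divided by the number of gain (loss)
events, with a bootstrap SE over compounds; a bin with no events reports
a waiting time longer than the total tree length (`Inf`). This estimator
is a documented approximation — the exact published estimator for such
waiting times is unstated in the literature this package follows.

## The synthetic world

The simulator's defaults are the stated conditions of the analysis, fixed
once: a global network of 100 compounds on 8 layers with 15 dietary
compounds; a pure-birth tree rescaled to 113.5 My with 152 tips (tests
use 64 tips to stay inside time budgets — the per-tree dynamics are
unchanged); reaction recruitment at α = 1/My per available candidate;
reaction loss β = 0.002/My; dietary acquisition 0.05/My once encountered;
dietary loss 0.002/My (never the last entry point).

Two structural choices matter:

* **Interior dietary compounds.** About a third of dietary compounds are
  root entry points; the rest sit on interior layers, both producible and
  ingestible — as zeaxanthin is in real avian networks, where it is
  encountered only several biochemical generations from lutein. Without
  this, every compound's distance from *any* diet would equal its layer
  and a new dietary acquisition could never extend elongation: rescue
  would be structurally impossible.
* **The rescue rule.** Gains whose product lies more than `horizon`
  (default 3) reactions from the permitting dietary set are forbidden.
  With rescue on, every acquired dietary compound joins that set,
  resetting the counter — elongation continues past the horizon only via
  dietary acquisitions. With rescue off, the horizon stays anchored at
  the founding dietary compound, so pathways stall there. The default
  horizon of 3 reflects that gains of compounds ≥3 steps from the diet
  are rare on the ~100-My timescale of avian radiation.

What a green simulated run establishes: the pipeline's statistics recover
a mechanism that is true in the generator — elevated-to-elevated elaboration
transitions carry dietary gains under rescue (fraction ≈ 0.75, z > 2 over
50 paired seeds) and do not otherwise; elongation reaches the 8-step
ceiling only under rescue; robustness and elongation associate positively
under contrasts; observed pathway metrics sit below degree-preserving
null expectations. What it does not establish: empirical effect sizes
(divergence slopes, null-model z magnitudes, the published transition
counts), which require the curated avian dataset; and the *sign* of the
modularity null comparison — simulated layered networks are not more
modular than their rewirings, unlike real carotenoid networks, a known
limitation of the generator. Simulated species also occupy a larger
share of their global network than real species do; inventories
therefore report only the six deepest terminal metabolites as plumage
compounds, which keeps the built minimum networks near empirical scale.

## Numerical conventions

* Distances from diet are counted in reactions, 0 for dietary compounds,
  `Inf` for unreachable ones.
* Longest simple paths are found by exhaustive DFS with an expansion
  budget (default 1e6) — exact at curated-network scale (≤ ~100 sparse
  nodes); the budget guards pathological inputs, and the implementation
  is verified against an independent enumeration oracle on hundreds of
  random graphs.
* All stochastic steps (rewiring, bootstraps, simulation, optimizer
  starts) take explicit integer seeds; identical seeds give bit-identical
  results, and the simulator's event log can be replayed to reproduce
  every node state exactly.
* The pipeline derives stage seeds from one master seed by fixed offsets,
  recorded in the run manifest.
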