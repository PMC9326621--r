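---
title: "Layered adipokine networks: construction, centrality, and robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered adipokine networks: construction, centrality, and robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiponet)
```

## The model

Adipokines — peptide hormones secreted by adipose tissue, such as leptin
and adiponectin — sit between sleep physiology and metabolic regulation:
sleep disturbances and physiologic perturbations alter adipokine levels,
and adipokines in turn act on molecular targets and physiologic pathways
that feed into disease processes. `adiponet` represents this as a
*layered, signed, directed* knowledge graph with six node categories:

1. physiologic perturbations (e.g. obesity, exercise),
2. sleep disturbances (e.g. obstructive sleep apnea, sleep deprivation),
3. adipokines,
4. molecular targets (e.g. AMPK, JAK–STAT3),
5. physiologic functions (e.g. insulin signaling, food intake),
6. disease processes (e.g. metabolic syndrome).

Edges encode direction of information flow and carry a sign (positive,
negative, or uncertain association). Only the transitions produced by the
five curation rules are legal — perturbation/sleep → adipokine,
adipokine → target, target → function, function → disease, plus the
"shortcut" edges adipokine → function/disease for relations whose
mechanism has not been pinned down. The transition table is closed-world:
anything else (e.g. disease → adipokine) is rejected by
`validate_network()`. It is also an explicit argument everywhere, so a
curator who needs, say, target → disease edges can extend it without
touching package code.

Two structural consequences are worth noting, because tests rely on
them: perturbation and sleep nodes can only have out-degree, disease
nodes only in-degree; and therefore all three layers have betweenness
exactly zero — only adipokines, targets, and functions can lie *between*
other nodes.

## From assertion tables to networks

The raw input is an *assertion table*: one row per curated relation
(`source`, `source_category`, `target`, `target_category`, `sign`,
`provenance`). `build_network()` applies the curation semantics:

* duplicate assertions collapse to a single edge;
* an `uncertain` sign is overridden by a definite sign (uncertainty is a
  weaker label, not a contradiction);
* a pair asserted both `positive` and `negative` is a contradiction.
  The default policy (`drop_edge`) removes just that edge; the stricter
  `exclude_node` policy removes a configurable endpoint (default: the
  target) with all its incident edges, mirroring curation practice where
  nodes with inconsistent literature are excluded outright. The curation
  reports do not say which endpoint to blame, hence the configurable
  side. Every resolution is logged as a conflict record.

Construction is order-invariant (node and edge tables are canonicalized
on the normalized, case-folded names), and `to_assertions()` inverts it
for conflict-free networks. Entity names are compared case-insensitively
after whitespace normalization; synonym resolution (e.g. "AMPK" vs
"AMP activated protein kinase") is deliberately out of scope — a
conservative choice that errs toward keeping distinct nodes distinct.

## Centrality

Degree centrality is `C_i = deg(i)`, reported as in-, out-, and total
degree. Betweenness follows the shortest-path counting definition

$$C_{bet}(i) = \sum_{x \ne y,\; i \notin \{x,y\}}
  \frac{\sigma_{xy}(i)}{\sigma_{xy}},$$

where `σ_xy` counts shortest *directed* paths from `x` to `y` and
`σ_xy(i)` those passing through `i` as an interior node. Choices, all
matching the definition as printed rather than any particular tool's
defaults: directed (the network is directed), unweighted (signs are
labels, not costs), unnormalized (no normalization factor appears in the
definition), endpoints excluded, unreachable pairs contribute nothing.
`directed = FALSE` and `normalized = TRUE` flags are available for
cross-tool comparison.

Two independent implementations are shipped. `betweenness()` is Brandes'
algorithm (one BFS per source plus reverse dependency accumulation,
O(|V|·|E|)). `betweenness_oracle()` is a deliberately naive
enumerator — BFS distances, then depth-first enumeration of every
shortest path per ordered pair, counting interior passages directly. The
test suite holds them equal within 1e-9 on two hundred random layered
networks and on the pedagogical fixtures, and additionally cross-checks
Brandes against `igraph::betweenness()`. Node iteration order is fixed
(sorted names), so floating-point accumulation — and hence every
reported value — is reproducible across runs.

## Hubs, bottlenecks, nonhub bottlenecks

The field's definitions are qualitative: hubs have "much higher" degree
than the rest; bottlenecks have high betweenness; nonhub bottlenecks
combine low degree with high betweenness and often mark regulatory
chokepoints (AMPK in the adipokine literature). `classify()` makes them
operational with quantile cutoffs that are always reported back:

* **hubs** — degree at or above the 0.90 quantile of all node degrees
  (and positive);
* **bottlenecks** — betweenness at or above the 0.90 quantile of the
  *positive* betweenness values. Restricting to positive values matters:
  in a layered network roughly half the nodes are pure sources or sinks
  with betweenness zero, and quantiles over the full vector would let
  zeros dominate;
* **nonhub bottlenecks** — bottlenecks, not hubs, with degree at or
  below the 0.50 quantile of the degrees of positive-betweenness nodes.
  The "low degree" judgement is made against the population actually
  being compared (nodes that lie on paths), not against all nodes: pure
  leaves would otherwise drag the median down to 1 and no conduit node
  could ever qualify.

Quantiles use the nearest-rank method (the ceiling(q·n)-th smallest
value) for bit-identical results across platforms; ranks are ordinal
with lexicographic tie-breaks. All three cutoffs can be frozen to
explicit numbers, which the robustness module uses.

`degree_distribution()` summarizes the degree histogram and applies a
heavy-tail screening heuristic: the least-squares slope of log(count)
against log(degree) must be at most −1 (with a 1e-9 boundary tolerance)
and the maximum degree at least four times the median. This is labeled a
heuristic deliberately. Naive log–log regression on a raw histogram is
known to be a blunt instrument, and for a network of this size and
density (94 nodes, 264 edges, mean degree 5.6) it sits close to its own
threshold: the constraint set (fixed node and edge totals plus a
dominant hub) caps how steep the fitted slope can get, so the flag is
sensitive to seed-level fluctuation. Rigorous maximum-likelihood tail
fitting is out of scope for a 94-node network — there is simply not
enough tail to fit.

## The synthetic generator

`generate_network()` stands in for the curated network, whose full
relation table exists only as a figure appendix with no
machine-readable deposit. Defaults emulate the published headline
statistics: 94 nodes split as 6/4/6/28/25/25 across the six layers (only
the total and the six adipokines are pinned down; the split is an
informed default and plain configuration), 264 edges, sign mix
0.5/0.3/0.2, two planted adipokine hubs with Zipf(1.6) attachment
weights, and 20% shortcut edges.

Generation runs in three deterministic phases:

1. **Planted motif.** Every planted hub points at a designated bridge
   molecular target, which feeds three functions, each wired to three
   diseases of its own. The bridge's downstream chain takes no other
   incoming edges — the AMPK → fatty-acid-oxidation pattern, where a
   mechanism's downstream elements are reachable only through it. The
   bridge takes no random edges at all, so its degree stays fixed and
   low while every upstream-to-chain shortest path runs through it.
2. **Coverage.** Each remaining node receives one schema-legal incident
   edge, making node counts exact. Upstream nodes are wired to the
   planted hubs first: the best-studied adipokines are the ones
   perturbations get reported against, and this keeps the full upstream
   layer flowing through the hubs.
3. **Fill.** Edges are drawn from the allowed transitions until the
   budget is met exactly (duplicates are resampled, with a 10^6-attempt
   cap guarding infeasible configurations). Transition types are drawn
   with fixed weights that favor the large downstream layers — the small
   upstream layers saturate their few legal pairs quickly. Adipokine
   endpoints use the configured Zipf(hub_skew) weights; other endpoints
   use Zipf rank weights with exponent 1.3 within their layer, which
   spreads within-layer degrees roughly as inverse rank and gives the
   aggregate histogram its decay.

The generator is the package's only source of randomness besides
`stability()`; both take explicit seeds, restore the caller's RNG state,
and are byte-reproducible.

What the synthetic data does *not* emulate: real entity identities and
synonyms, evidence strength, correlated curation (papers contribute
many edges at once), publication-date structure, and the true per-layer
node counts of the curated network. Passing tests on synthetic data
therefore demonstrate that the *algorithms* recover planted structure
under the stated statistical conditions — not that any particular
biological claim holds.

## Robustness under curation noise

Literature-curated networks inherit publication bias; roles may change
as evidence accumulates. `stability()` operationalizes this: each
replicate independently deletes every edge with probability
`edge_drop_prob` and adds `Binomial(|E|, edge_add_prob)` random *legal*
absent edges (curation noise produces plausible relations, not arbitrary
ones), then reclassifies with the numeric thresholds frozen at their
baseline values, so that the reported membership frequencies measure
network instability rather than threshold instability (re-quantiling per
replicate is available as a flag). With both probabilities zero the
baseline classification is reproduced exactly — a property the test
suite asserts.

On the default synthetic network, planted hubs are markedly more stable
than the planted bridge under 10% edge dropout: hub status rests on many
redundant edges, bridge status on a handful of specific ones. That
asymmetry is the practical reading of the robustness module — degree
calls are trustworthy under curation noise, nonhub-bottleneck calls
deserve scrutiny.

## Problem sizes used by the tests

The shipped suite runs the oracle-equivalence check on 200 generated
networks between 35 and ~187 nodes, the parameter-recovery check on 100
default-sized (94-node) networks, and robustness checks at up to 40
replicates; the acceptance script repeats the headline computations at
the same sizes. These sizes keep the brute-force oracle exact while
exercising every code path at the scale of the curated network itself.

## Known limitations

* Synonym/ontology resolution is not attempted; name normalization is
  whitespace-and-case only.
* Edge signs are carried through construction and export but do not
  enter centrality; signed-path analysis is future work.
* The heavy-tail flag is a screening heuristic with the caveats above.
* The per-layer node counts of the published network are unknown; if the
  appendix is ever transcribed, `synthetic_config()` accepts the true
  split directly and `read_assertions()` ingests the transcription.
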