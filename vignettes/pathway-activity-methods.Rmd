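---
title: "Methods: pathway activity, topology significance and differential calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway activity, topology significance and differential calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathact)
```

`pathact` takes, per sample, a binary answer to one question — *which
ortholog groups (KO/EC identifiers) have any RNA-Seq evidence?* — and turns
it into pathway-level statements. This vignette documents the two models,
the choices made where several readings were defensible, and what the
synthetic fixtures do and do not demonstrate.

## The uniform binary activity model

A pathway $w$ is a set of ortholog groups; the family $W$ of pathways
overlaps because a group can act in several pathways. The model makes two
assumptions:

* **uniformity** — a group's molecules participate in every *active*
  pathway containing it in equal proportions, so the participation of $g$
  in $w$ is
  $g_w = \left(1 + \sum_{w' \ni g,\, w' \neq w} \delta(w')\right)^{-1}$,
  and the activity level is $f_w = \sum_{g \in w} g_w$;
* **binary activity** — $\delta(w) = 1$ iff $f_w \ge T_w$ for a (possibly
  pathway-specific) threshold $T_w$.

The iteration starts with every pathway active and alternates the two
equations. Because the status vector lives in a finite space it must
eventually revisit a state; we stop at the first revisit and call the
distance back to the earlier occurrence the *period* (1 = fixed point). On
realistic inputs the iteration settles within a handful of steps, usually
into a fixed point or a period-2 oscillation driven by groups fluctuating
between competing pathways.

Choices worth making explicit:

* **Cycle-mean levels.** "The level after convergence" is ill-defined on an
  oscillating trajectory, so reported levels are the arithmetic mean of
  $f_w$ over the states of one terminal cycle; for a fixed point this is
  just the converged level. The reported `final_status` is the first state
  of the cycle.
* **A pathway's own status does not gate its own level**: the sum in the
  denominator runs over *other* pathways only, and the constant 1 remains
  even when $\delta(w) = 0$. An inactive pathway can therefore regain
  activity later — this is what makes oscillation possible.
* **Boundary**: $f_w = T_w$ counts as active (the update uses $\ge$).
* **Threshold default** $T_w = 1$: one full ortholog-group-equivalent of
  participation. Thresholds are not printed alongside most published
  activity rankings because the *ordering* of pathways by $f_w$ is largely
  insensitive to $T_w$; the test suite checks this as a property (Spearman
  correlation of rankings under a 2-fold threshold change exceeds 0.8 on
  overlapping synthetic families).
* **Working family**: the activity branch runs on pathways restricted to
  the sample's expressed groups, keeping every pathway with at least one
  expressed member (`min_groups = 1`). Running on full KEGG definitions
  instead is possible by skipping `restrict_to_sample()`, but with a binary
  expression model the unexpressed members would only add constant terms
  equal to zero participation, so restriction is the natural default.
* **KO and EC identifiers are never translated** into one another:
  translation needs an external database and silently merging the
  namespaces would corrupt the group index. Ids are compared as exact
  strings (KO normalized to uppercase `K`).

## Directed enzyme graphs and their metrics

A KGML pathway map is parsed into a directed graph with one node per
`ortholog`/`gene`/`enzyme` entry (labels = the entry's space-separated
KO/EC names) and one edge per relation. Two readings existed for entries of
other types; we treat **enzymes as nodes**: `map` and `compound` entries
are dropped, and a relation chain passing through a compound is collapsed
to a direct enzyme→enzyme edge. Parallel edges and self-loops are removed
at parse time, because the metrics below are only well-defined on a simple
graph.

Given a sample, a node is *mapped* when any of its labels is expressed
(the "green" enzymes on a KEGG rendering). The **induced mapped subgraph**
(mapped nodes, edges with both endpoints mapped) is scored by:

* **density** $= |E| / (|V| - 1)$, set to 0 when $|V| \le 1$ (the
  denominator is otherwise undefined; such pathways are excluded by the
  size filter anyway);
* **zero-degree fraction** $=$ (#nodes with out-degree 0 + #nodes with
  in-degree 0) $/\, (2|V|)$ — the division is by $2|V|$, which keeps the
  fraction in $[0, 1]$ (an isolated node contributes both terms);
* counts of **weakly** connected components and the largest component's
  nodes and edges. Weak connectivity is used because KEGG maps are drawn
  as largely linear cascades where visual connectedness ignores edge
  direction.

Pathways with fewer than 3 distinct mapped ortholog groups are excluded
from the graph branch (`min_mapped = 3`): below that, density and degree
statistics carry no information.

## Permutation null models and the empirical p-value

* **Vertex label swapping** fixes the topology and repeatedly exchanges the
  mapped flags (and labels) of two randomly drawn nodes with *different*
  flags. Edge set, degree sequence and mapped count are invariant. This
  null asks: *given how many enzymes are expressed, is their placement on
  the map unusually coherent?* Its known bias: high-degree nodes end up
  connected in most draws, which can inflate significance.
* **Edge swapping** fixes the labelling and rewires edge pairs
  $(a\!\to\!b, c\!\to\!d) \mapsto (a\!\to\!d, c\!\to\!b)$, rejecting swaps
  that would create a self-loop or duplicate edge; every node keeps its in-
  and out-degree. The whole pathway graph is permuted and the induced
  subgraph re-derived per ensemble member.

`n_swaps` counts *attempted* swaps, which guarantees termination on rigid
graphs; at the default $n = 10^6$ the difference from counting accepted
swaps is irrelevant for mixing. The ensemble holds $m$ **pairwise
distinct** states (distinct flag assignments for the vertex model,
distinct edge sets for the edge model): duplicated null states would bias
the rank, so a slot that cannot find a fresh state within `max_retries`
raises an error suggesting a smaller $m$ rather than degrading silently.

The observed record is ranked in the ensemble sorted by density
(descending) then zero-degree fraction (ascending); the p-value is
`rank / m` with classes at 5 %, 1 % and 0.5 %. Ties are resolved
*conservatively*: the observed graph is placed after equal-keyed random
graphs, so ties can only inflate the p-value. When the observed graph
ranks last among the $m + 1$ items, `rank / m` would exceed 1 and is
clipped.

## Differential analysis

Activity levels of two samples are compared by their ratio; the default
calls are `up` at ratio ≥ 1.5 and `down` at ≤ 0.66 (the reciprocal fold in
the other direction). A zero denominator yields an explicit `undefined`
rather than a pseudocount, and pathways present in only one sample survive
the outer join marked `one_sided`. Significance runs are compared through
$\mathrm{probDiff} = (1 - p_{\text{small}})\, p_{\text{large}}$, symmetric
in its arguments, bounded by $1/4$ when $p_1 = p_2$, and a pathway is
called differentially significant when probDiff strictly exceeds 0.5. No
multiple-testing correction is applied across pathways in either branch —
a deliberate mirror of the method's original formulation; treat the calls
as a ranking, not as FDR-controlled discoveries.

## Synthetic fixtures: what they emulate, what they don't

The generators produce (i) overlapping pathway families — each pathway
draws a fraction (`overlap_fraction`, default 0.3) of its members from
groups already used — with an expressed set covering planted-active
pathways plus 10 % background noise, and (ii) uniform simple directed
graphs of configurable size with a mapped fraction, serializable as
minimal KGML. Defaults (15 nodes / 40 edges) match the smallest pathway
maps worth analysing; families default to 20 pathways of 4–10 groups.
These fixtures reproduce the *structural* conditions the methods depend on
(sharing, directedness, partial mapping) but not biological realism: no
hub-enzyme degree distribution, no correlated expression along cascades,
no KO/EC mixture within one map. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration, not biological
validity on real KEGG data.

## Test-scale parameters and statistical checks

The suite runs ensembles at $m \le 200$ and `n_swaps` $\le 10^4$ — on
fixture-sized graphs label/edge mixing saturates well below that, and the
full suite completes in well under a minute. Two checks deserve a note:

* **Self-null uniformity.** When the observed labelling is itself drawn
  from the null, its rank should be uniform. This holds *marginally* over
  ensembles but not conditionally on a single fixed ensemble (whose
  empirical CDF deviates from the truth), so the test draws a fresh
  $m = 19$ ensemble per replicate, making observed and null members
  exchangeable, and applies a coarse chi-square over 100 replicates.
* **Planted recovery.** A graph whose 9 mapped nodes form a complete
  directed subgraph is strictly denser than any other flag assignment, so
  it must rank first (p = 1/m) — this exact construction also drives
  `scripts/acceptance.R` — while a scrambled relabelling of the same graph
  ranks mid-ensemble.

## Known limitations

* The binary expression model ignores abundance: a weighted (read-count)
  participation model is a natural extension but is out of scope here.
* Density comparisons across pathways of very different size are not
  calibrated against each other; p-values are within-pathway statements.
* KGML `maplink` cross-references are not edges, and reaction
  stoichiometry is ignored.
* Oscillating trajectories make the cycle-mean a modelling choice, not a
  limit theorem; inspect `period` in the output when interpreting levels.
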