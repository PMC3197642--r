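---
title: "Estimating ancestral areas: methods, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ancestral areas: methods, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancarea)
```

# The problem

Given a rooted phylogeny of a monophyletic group and, for every terminal,
the set of operational areas it occupies, the ancestral-area problem asks
which areas the most recent common ancestor of the group (and of its
subclades) occupied.  `ancarea` implements the three classical
parsimony-style answers — Fitch optimization, weighted ancestral area
analysis (WAAA) and dispersal-vicariance analysis (DIVA) — as exact,
fully-tested algorithms, together with the upstream step of delimiting the
operational areas themselves from point occurrences (a grid-based
areas-of-endemism search) and a simulator of range histories with known
ancestral ranges that lets every stage be validated against a ground truth.

All three reconstruction methods are cladogram-only: branch lengths are
accepted on input and ignored.  Ranges are encoded internally as bit masks
against a fixed, ordered `area_set` (at most 28 areas; the order defines
the bit positions), so every set operation is a mask operation.

# Fitch optimization and MPR sets

A reconstruction assigns one area to every internal node; its length is the
number of branches whose endpoints disagree, where a terminal occupying
several areas is compatible with any of them at no cost (polymorphic
coding).  `fitch_downpass()` runs the textbook set-intersection/union pass
and reports its length; `fitch_mpr()` computes, for every node, the set of
areas the node takes in at least one minimum-length reconstruction (the MPR
set), using a two-pass unit-cost dynamic programme that conditions each
node on the best completion of the rest of the tree.  The two agree on
binary trees.  At polytomies the down-pass folds children pairwise in input
order and warns — its length can depend on child order there — while the
dynamic programme always attains the true minimum.  The root MPR set is the
Fitch ancestral-area answer: it should be read as alternative single-area
origins, not as one widespread range.

Terminals are observations, not hypotheses: MPR output reports each
terminal's observed range unchanged.

# Weighted ancestral area analysis

WAAA asks, per area, how strongly the cladogram supports that area being
ancestral, favouring areas that enter the tree deep (plesiomorphic) and
often.  The published descriptions of the weighting are qualitative, so the
package fixes one concrete, fully-testable formulation:

* **Gains** are counted under an ancestor-absent, gains-only model: a
  virtual origin edge above the root lacks the area, and gains must explain
  exactly the observed presence pattern.  The minimal placement is unique —
  one gain on the edge entering every *maximal* clade whose terminals all
  carry the area — and is also the deepest possible placement.
* **Losses** are the mirror image: ancestor present, losses only, one loss
  entering every maximal all-absent clade.
* Every step on the edge entering node $v$ weighs $1/\mathrm{level}(v)$,
  where the virtual origin edge is level 1 and each level below adds one.
  Deeper steps therefore weigh more, and areas occupied by many terminals
  accumulate more gain weight.

The probability index is $PI = GW/LW$.  An area never lost has $LW = 0$ and
an infinite PI; it is ranked first and flagged `never_lost` rather than
regularized with a pseudo-count, which matches the qualitative expectation
that the most plesiomorphic area dominates the index.  For reporting, PI is
rescaled by the largest finite PI, and `waaa()` returns the areas with
rescaled PI at or above a threshold (default 0.5).  The threshold is
presentation only — the ranked table is the full answer — and the top area
is always included because its rescaled PI is 1 by construction.

One caveat this formulation makes precise: the gain weight is **not**
monotone in the presence pattern.  Completing a clade merges several gain
edges into a single shallower one, and the merged weight $1/L$ can fall
below the sum it replaces (e.g. $1/3 + 1/5$ collapsing to $1/2$).  What
does hold, and what the tests assert, is that an added presence forming its
own maximal clade adds exactly its edge weight.

Per-clade WAAA answers are computed on the clade's subtree: the probability
index is clade-internal, and terminals outside the clade do not affect it.

# Dispersal-vicariance analysis

DIVA scores a reconstruction (a non-empty area subset at every internal
node, terminals fixed to their observations) by summing cladogenetic
transition costs: a single-area ancestor duplicates into both daughters for
free; a widespread ancestor splits by vicariance into two disjoint
non-empty parts for free; each daughter then pays one **dispersal** per
area it has beyond its inherited part and one **extinction** per inherited
area it lost.  `split_cost()` exposes this transition cost directly;
`diva()` minimises the total exactly by dynamic programming over all
non-empty subsets of the areas present in the terminals.

Implementation notes that matter to users:

* The per-node combination uses a hypercube distance transform
  ($g(I) = \min_C \mathrm{cost}(C) + |I \,\triangle\, C|$ in $O(k2^k)$)
  followed by submask enumeration over vicariance partitions
  ($O(3^k)$ per node), rather than materialising the full
  $(2^k)^3$ transition matrix.
* Polytomies are rejected, as in classical DIVA software.  More than 14
  areas triggers a warning (the classical limit was 15 area units) and more
  than 16 an error: beyond that the exact subset programme stops being
  desk-scale, and the historical practice is to merge overlapping areas
  first (`apply_merge_map()`).
* `maxareas` caps the size of ancestral ranges; it must be at least the
  largest terminal range, and the minimal cost is non-increasing as the cap
  is relaxed (a tested invariant).  `weight` and `age` are accepted for
  fidelity to classical settings files but only the neutral value 1 is
  implemented; anything else is an error rather than a silent deviation.
* All optimal root ranges, the per-node families of subsets occurring in at
  least one optimal reconstruction, and the reconstructions themselves are
  returned.  Enumeration is deterministic — depth-first with nodes in
  pre-order and subset masks ascending — and stops at `hold` (default
  32767, the classical setting).  The *exact* number of optima is computed
  separately by a product dynamic programme, so the `truncated` flag and
  `n_optimal` are correct even when the list is capped.
* The ancestral-area answer can be taken as the union of optimal root
  ranges or per reconstruction (`diva_ancestral_area()`); reports flag
  clades with several optima with an asterisk, since published tables
  conventionally print one set per clade and mark ambiguity.

Because vicariance is free, DIVA tends to return large, often widespread
root ranges, and adding a basal outgroup occupying a novel area provably
enlarges the root union by exactly that area — a property the test suite
checks, and a practical warning against using distant outgroups to
"anchor" the root.

# Areas of endemism on a grid

`build_grid()` assigns each occurrence to one cell of a regular
longitude–latitude grid.  Cells are half-open — $[x_0 + cs,\, x_0+(c+1)s)$
in longitude and $(y_0-(r+1)s,\, y_0 - rs]$ in latitude, rows counting
southward from the origin corner — so boundary records are assigned
deterministically.  The defaults (origin $(-80, 5)$, cell size
$0.75^\circ$) match common practice for South American squamate data sets.

The per-species endemicity score against a candidate cell set $A$ is fully
specified so that every test is closed-form:
$$\mathrm{score} = \frac{o}{|A|} \cdot \frac{o}{o+u},$$
with $o$ the species' cells inside $A$ and $u$ those outside: coverage of
the area times containment of the species.  It is 1 exactly when the two
cell sets coincide.  The area score is the sum over endemic species (score
$\ge$ 0.5 by default); candidate areas need at least 2 endemics and score
$\ge$ 1.5.  Classical endemism software exposes further options — fill and
assume radii, edge proportions — whose semantics are not reproducible from
their descriptions; they are deliberately not implemented rather than
guessed at.

The search hill-climbs from seed cell sets (each species' occupied cells,
plus a seeded random sample of 3×3 neighbourhoods of occupied cells),
taking the first strictly improving single-cell change with moves examined
in lexicographic cell order — removals before additions — so a run is fully
deterministic given its seed and invariant to occurrence row order.
Duplicate cell sets are collapsed; a candidate is superfluous when, against
a better-scoring candidate, fewer than half of its endemic species are
unique.  `consensus_areas()` pools replicates: exact duplicates are
removed, candidates are grouped so every pair within a group has Jaccard
similarity of endemic-species sets at or above the cutoff (default 0.40),
and each group is replaced by the union of its cells, rescored.  Jaccard is
used because "percent of species similarity" admits several formalisations
and Jaccard is the symmetric, standard one.

# The simulator and what passing tests mean

`simulate_tree()` builds random binary trees by sequential coalescence;
`simulate_range_history()` evolves ranges from a root range of chosen size:
widespread ranges split by vicariance with probability `p_vicariance`
(uniform over ordered two-block partitions), otherwise duplicate; each
branch then receives Poisson numbers of dispersals and extinctions with
means equal to the rates, applied in random order, extinction never
emptying a range.  Branch lengths are ignored, consistent with the
cladogram-only methods; Poisson-per-branch is the simplest model matching
their event-count semantics.  Every simulation records the true range of
every node and a complete event log, and `replay_history()` re-derives all
ranges from the log alone — an internal-consistency check run in the tests.

`generate_occurrences()` places points uniformly inside the cells of each
species' areas (with an optional uniform noise fraction), which feeds the
endemism stage with a known planted truth.

The simulator emulates the event structure the methods assume — and only
that.  It does not model time-calibrated rates, diversification-linked
range evolution, spatial autocorrelation of sampling, taxonomic error or
the patchiness of real museum records.  Passing the vicariance-recovery
tests therefore shows the algorithms are correct and coherent under their
own model, not that the methods are reliable on real data; indeed the
package reproduces the known pathologies (all-dispersal readings of Fitch,
plesiomorphy dominance in WAAA, near-universal root ranges in DIVA) by
construction.

# Validation design and problem sizes

Every non-trivial algorithm is checked against an independent brute-force
oracle at small sizes, where exhaustive enumeration is feasible and exact:

* DIVA: 200 random instances with 3–6 terminals and 2–4 areas, enumerating
  every assignment of non-empty subsets to internal nodes; minimal cost,
  optimal root ranges and per-node optimal families must match exactly.
* Fitch: 200 random instances with 3–8 terminals and 2–4 areas, enumerating
  every single-area assignment; length and MPR sets must match exactly.
* WAAA: 200 random instances, enumerating edge subsets for the minimal
  directional placements; gain and loss weights must match exactly, and a
  uniquely universal area must rank first.
* Recovery: 100 vicariance-only simulations (8 terminals, 5 areas, root
  range 4) must give DIVA cost 0 with the true root among the optima, and a
  Fitch root MPR contained in the true root range — both hold by
  construction, and the suite confirms 100/100.
* Endemism: a planted 6-cell block carrying two exactly co-distributed
  species among 10 scattered noise species must be recovered with area
  score exactly 2.0 and survive a 20-replicate consensus as a single area.

These sizes keep each oracle suite within seconds while covering the
combinatorics densely; the same computations, re-seeded from the command
line, are what `scripts/acceptance.R` reports.

# Known limitations

* Exact DIVA is exponential in the number of areas; the 16-area cap is a
  deliberate scope line, with area merging as the supported route beyond it.
* The WAAA weighting is one defensible formalisation of a qualitatively
  described method; alternative weightings exist, which is why the full
  GW/LW/PI table is always returned rather than only a thresholded set.
* The endemicity score is a deliberately simple two-factor index, not a
  reimplementation of any specific endemism program's optimality criterion;
  the search is a local hill-climb and inherits the usual dependence on
  seeds, mitigated by replicates plus consensus.
* NEXUS input, unrooted trees and likelihood-based range evolution (DEC-style
  models) are out of scope.
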