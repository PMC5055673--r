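---
title: "Mapping threatened and range-restricted evolutionary history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping threatened and range-restricted evolutionary history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylospot)
```

## The problem

Conservation planning based on species counts treats all species as equal.
Weighting sites by the *evolutionary history* they hold instead asks how much
of the tree of life is at stake in each place. `phylospot` computes, for every
cell of an occurrence grid, how much phylogenetic diversity is expected to be
lost to extinction, how concentrated the most irreplaceable endangered species
are, and how much evolutionary distinctiveness is confined to small ranges;
it then screens cells against permutation null models, selects hotspots, and
asks whether protected areas cover them better or worse than chance.

## The three indices

Let the regional phylogeny have branches $b$ of length $L_b$, with $D(b)$ the
tip set descending from $b$, and let species $i$ have an extinction
probability $p_i$ (from its IUCN category) and a range of $r_i$ grid cells.

**Expected PD-loss.** With independent extinctions, a branch is lost only if
*all* of its descendants die — the phylogenetic complementarity of extinction
risk. For the assemblage $A$ of a cell,

$$\mathrm{ExpPDloss}(A) \;=\; \sum_{b\,:\,D(b)\cap A \neq \emptyset}
  L_b \prod_{i \in D(b) \cap A} p_i .$$

By default every branch from the cell's species up to the *regional root*
counts, because the quantity of interest is the loss of regional evolutionary
history represented in the cell; a `subset_mrca` mode that stops at the
assemblage's most recent common ancestor is available as a configuration
switch (`rooting` argument) since either reading of "the PD of a cell" is
defensible.

**HED / HEDGE.** The heightened evolutionary distinctiveness of species $i$
is the expected phylogenetic diversity secured by guaranteeing its survival,

$$\mathrm{HED}_i = \sum_{b \in \mathrm{path}(i)} L_b
  \prod_{j \in D(b)\setminus\{i\}} p_j ,
\qquad \mathrm{HEDGE}_i = p_i \cdot \mathrm{HED}_i ,$$

which equals (and is tested against) the conditional-expectation definition
$E[\mathrm{PD} \mid i \text{ survives}] - E[\mathrm{PD} \mid i \text{ extinct}]$.
HED is bounded between the species' terminal branch length and its
root-to-tip distance.

**BED.** Biogeographically weighted evolutionary distinctiveness replaces
probabilities by range restriction. Under the default *union-range*
weighting,

$$\mathrm{BED}_i = \sum_{b \in \mathrm{path}(i)} \frac{L_b}{R_b},
\qquad R_b = \Bigl|\bigcup_{j \in D(b)} \mathrm{range}(j)\Bigr| ,$$

so a deep branch is range-restricted only when all of its descendants are
confined to the same small area. The original formulation of the metric
partitions each branch in proportion to descendant range sizes
($L_b\, r_i / \sum_j r_j$); it is available as
`bed_scores(..., weighting = "occurrence_sum")`. We default to the
union-range reading because it expresses the complementarity idea that
motivates the index — the occurrence-sum variant is kept for comparability
with earlier work, and the choice is exposed rather than hidden because the
two can rank species differently when ranges overlap strongly.

**Filtering.** Extinct, regionally extinct and not-applicable species are
excluded everywhere. Data-deficient species are excluded from the two
probability-based indices (no category, no probability) but retained for
BED, which needs only ranges. `species_filter()` implements exactly this.

**Extinction probabilities.** IUCN categories are converted to 50-year
extinction probabilities with the IUCN50 transformation
(LC 0.00005, NT 0.004, VU 0.05, EN 0.42, CR 0.97), shipped as an editable
JSON preset (`iucn50_probabilities()`); any strictly increasing mapping
LC < NT < VU < EN < CR can be substituted. The probabilities are treated as
data, not constants of the method.

## Null models and F-values

Raw per-cell sums track richness almost mechanically, so hotspots are
defined on null-model exceedance frequencies instead:

* **Risk shuffle** (for expected PD-loss): extinction probabilities are
  permuted across the species of the filtered pool, cell composition held
  fixed — the statistic is a property of the site, so the site is kept and
  the risks are randomized. 1000 permutations by default.
* **Identity shuffle** (for HEDGE and BED sums): within each cell, species
  identities are redrawn uniformly from the regional pool at fixed richness,
  independently across cells and replicates — these statistics are
  properties of species, so species are moved instead. No constraint is
  placed on range sizes in the null.

The F-value of a cell is the frequency with which its observed value
*strictly* exceeds the simulated ones. Ties count against the cell, which
means fully degenerate inputs (identical scores everywhere) give F = 0 for
every cell; the same strict rule is used by the protection test below, and
the asymmetry with the complementarity p-value (which uses $\geq$) is
deliberate and preserved.

Numerically, the risk-shuffle engine evaluates all cells at once in clamped
log space ($\log p$ floored at $-10^6$, whose exponential underflows to
exactly 0), and the observed value is computed by the same code path as the
replicates, so a permutation that happens to reproduce the observed
probability vector reproduces the observed statistic bit-exactly — strict
comparisons then behave correctly. The scalar `expected_pd_loss()` uses
exact products, switching to log space only when a probability is below
1e-12.

## Hotspot selection

Cells are ranked by F (descending), ties broken by the raw score
(descending), then by cell id for determinism. Two selection rules:

* **Aichi rule**: the top $\mathrm{round}(0.17\,N)$ cells (round-half-up;
  with the two grid sizes used at continental scale, 477 and 1489 cells,
  this gives 81 and 253 hotspots). The 17% matches the Convention on
  Biological Diversity's area target.
* **Alternative rule** (no size constraint): for expected PD-loss, cells
  above the grid mean with $F \geq 0.5$; for HEDGE/BED, cells holding at
  least one top-10% species with $F \geq 0.5$. The selection can exceed 17%
  of cells.

`capture_complementarity()` measures the fraction of the regional metric
represented by the union of species over the hotspot cells and compares it
with equally sized random cell sets; `richness_correlations()` reports the
Spearman correlations that quantify how far plain richness surrogates would
have gone.

## Protection analysis

A protection layer records per-cell covered fractions for all protected
areas and for the I/II/IV management categories (the ones whose objectives
directly target species). Two scenarios: *minimum* (a cell is protected if
it intersects any protected area) and *strong* (more than half of its area
covered — exactly 50% does not qualify). The F\_PA statistic compares the
observed protected proportion of a hotspot set against random equally sized
sets, classifying coverage as UNDER ($F_{PA} \le 0.25$), AS\_EXPECTED
($0.25 < F_{PA} \le 0.75$) or OVER ($F_{PA} > 0.75$); the intervals are
half-open so the classes never overlap. When every simulation ties the
observed value (e.g. complete protection) the strict rule yields
$F_{PA} = 0$; the result is flagged (`ties = TRUE`) so it is not misread as
under-protection. `species_gap()` lists top species whose entire range lies
in unprotected cells.

## The synthetic-data module

The real inputs of a continental analysis — IUCN range polygons rasterized
to a grid, published dated phylogenies, the world protected-area database —
cannot be bundled, so the package generates data with the same structural
features:

* `simulate_tree()`: pure-birth (Yule) trees, ultrametric by construction,
  grown from the root split with an uncensored final waiting time so the
  expected depth is exactly $\sum_{k=2}^{n} 1/(\lambda k)$ — which the test
  suite checks by Monte Carlo.
* `simulate_ranges()`: spreading-dye ranges — contiguous patches grown one
  frontier cell at a time (4-neighbour by default, 8-neighbour optional),
  exactly hitting their target sizes. Right-skewed size distributions
  (lognormal) emulate the endemic-rich structure of Mediterranean-type
  faunas.
* `assign_categories()`: a latent severity mixes normal scores of negative
  range size (association between threat and small ranges, target rank
  correlation `threat_range_corr`), a Brownian trait on the tree
  (phylogenetic clustering of extinction risk, strength `clustering`) and
  independent noise, then is cut into LC…CR at configurable proportions
  (defaults 0.55/0.15/0.12/0.10/0.08, i.e. 30% threatened — deliberately on
  the threatened side of real regional assessments so the risk indices have
  signal). The realized category-versus-range Spearman correlation is
  attenuated slightly by the 5-level thresholding; the contract (checked at
  n = 500) is agreement with the target within ±0.15, and at
  `threat_range_corr = 1` the smallest-range species receive the most severe
  categories exactly, up to ties.
* `simulate_protection()`: a smoothed Gaussian field decides which half of
  the cells intersect any protected area; intersecting cells get Beta
  fractions calibrated so the grid mean equals the coverage target (default
  0.05, matching the low single-digit coverage typical of the region), with
  a zero-inflated share (mean 0.2, the approximate share of I/II/IV areas
  in real networks) assigned to the strict categories.
* `planted_hotspot_scenario()`: the end-to-end harness. A 10×10 grid;
  17 planted cells exclusively hold all 12 species of a critically
  endangered clade sitting on a long stem (distinct evolutionary history),
  while 50 least-concern background species occur everywhere. Ground-truth
  labels are returned, and the acceptance suite requires the expected
  PD-loss pipeline to recover at least 80% of the planted cells at 1000
  permutations.

All randomness flows from one root seed through named substreams
(`tree`, `ranges`, `categories`, `protection`, one per null model), so any
stage can be regenerated independently and whole runs are byte-identical
given the seed.

What the generator does *not* emulate: real grids are irregular coastlines,
not rectangles; real ranges follow habitat, not isotropic diffusion; real
threat status is assessed from criteria partly *defined* by range size; and
protected areas follow political boundaries. Passing tests therefore show
that the statistical machinery is correct and well calibrated under
controlled structure, not that any particular real region will behave like
the fixtures.

## Numerical and design choices

* Round-half-up for the 17% cell count (no rounding rule is canonical; the
  choice is fixed and tested at 477 → 81 and 1489 → 253).
* Ties at every cutoff (top-species sets, smallest-range sets, cell
  rankings) break lexicographically by id, making selections deterministic.
* Zero-length branches are allowed and contribute zero to every metric
  without special-casing; a zero-length root edge in Newick input is
  tolerated.
* Grafting a species into a single-member genus has a forced attachment
  point; it is implemented as a cherry at the midpoint of the member's
  terminal branch, preserving ultrametricity. For multi-member genera the
  MRCA polytomy uses a terminal length equal to the mean tip depth below the
  attachment node (on dated trees, exactly the node's height).
* Empty cells score zero on every index; they are data, not errors.
* `polytomy_sensitivity()` correlates raw per-cell scores (not F-values)
  across re-grafts: placement uncertainty acts on the scores, and rerunning
  1000-replicate null models inside every sensitivity replicate would
  multiply runtime for no extra information about placement.

## Problem sizes

The shipped tests run the enumeration oracles on 200 random trees of up to
12 tips (exhaustive over all $2^n$ extinction outcomes), the null-model
calibration on a 50-cell fixture at 1000 replicates, and the planted
recovery on the default 10×10 grid with 62 species at 1000 replicates —
sizes chosen so the full suite exercises the study conditions while staying
comfortably within a coffee break on one core. Realistic continental grids
(several hundred to ~1500 cells, a few hundred species) run the complete
pipeline in well under a minute.

## Limitations

* Extinction events are treated as independent across species given the
  probabilities; correlated threats (shared habitat loss) would concentrate
  losses further than the model predicts.
* The identity-shuffle null ignores range cohesion, so spatially structured
  scores can inflate F in large contiguous regions; this is the standard
  trade-off of richness-constrained nulls.
* GIS preprocessing (rasterizing polygons, equal-area projections, buffering
  point-only protected areas) is upstream of this package; the occurrence
  matrix and coverage table are the contract.
* Trees must be rooted, binary or polytomous, with finite non-negative
  branch lengths; reticulation and tree uncertainty (beyond polytomy
  placement) are out of scope.
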