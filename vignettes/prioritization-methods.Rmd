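---
title: "Methods: grid-based diversity surfaces, hotspot overlay, and conservation gap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-based diversity surfaces, hotspot overlay, and conservation gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
conventions each module implements, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The analysis chain

The package implements the standard workflow of grid-based conservation
prioritization for a species-rich flora: clean raw occurrence records,
rasterize them to a presence–absence matrix on an equal-area grid, compute
complementary diversity surfaces, select and overlay hotspot cells at a
family of area thresholds, and confront the result with an existing
reserve network to quantify effectiveness and gaps. Two satellite modules
handle the ethnobotanical use matrix (which groups use which species) and
ensemble species-distribution post-processing under climate scenarios.

## 2. Grid and geometry

**Projection.** Cells must be equal-area for `q` per cent of *cells* to
mean `q` per cent of *land area*. We use a Lambert cylindrical equal-area
projection configured from the data extent (central meridian and standard
parallel at the extent midpoint). An Albers-style conic was considered;
the cylindrical form was chosen because it is exactly area-preserving,
closed-form in both directions, and dependency-free — the choice is
configurable and no particular projection is canonical for this analysis.

**Cell membership** is half-open: a point exactly on a shared edge belongs
to the cell for which that edge is the upper boundary, i.e. the cell with
the lower id (ids are row-major from the south-west). Cell indices are
snapped to the lattice at 1e-9 cell widths so projection round-trip jitter
cannot move an edge point across a boundary.

**Geometry representations.** The runtime environment provides no
simple-features or raster stack, so vector layers are plain-text tables:
reserves are axis-aligned rectangles (projected km) with a `class`
attribute, native ranges are per-species geographic bounding boxes (or
polygons, tested point-in-polygon by even-odd ray casting), and climate
"rasters" are cell-id × predictor tables on the package grid. Rectangle ∩
cell intersection is exact interval arithmetic; "covered" means any
positive-area intersection (a configurable minimum covered fraction is
available, default 0, because published usage deems a grid protected as
soon as a reserve touches it).

## 3. Record cleaning

Five filters, applied in a fixed order with each record attributed to the
first filter it violates (the source convention names the filters but not
an order; a fixed order makes reports deterministic and the counts
reconcile by construction):

1. missing or unparseable coordinates (unparseable numerics become `NA`
   at read time and are caught here), or no usable locality;
2. latitude numerically equal to longitude — a classic transcription
   artifact; note this is *not* deduplication of repeated coordinate
   pairs across records;
3. either coordinate exactly zero, or both coordinates integer-valued.
   "Zero and/or integer" is ambiguous between *either* and *both*
   integral; we require **both** to be integers (a single coincidentally
   integral coordinate is common in legitimate data) while zeros are
   always suspect. The per-record disposition log lets users audit the
   alternative reading.
4. point not on land (off-grid or in a sea cell);
5. point outside the species' native range, skipped and logged for
   species without a supplied range polygon.

## 4. Diversity surfaces

For presence matrix `P` (species × land cells), range `r(s)` = occupied
cells of `s`:

- `SR(c) = Σ_s P[s,c]`;
- `WE(c) = Σ_s P[s,c]/r(s)` — each species distributes one unit of weight
  across its range, so `Σ_c WE(c) = S` to machine precision; this
  identity is asserted on every generated world.
- **Complementarity** is the greedy minimum-set heuristic: repeatedly take
  the cell adding most unrepresented species (ties: higher SR, then lower
  cell id) until all species are covered. The greedy cover is within the
  harmonic bound `H(d)` of the optimum (`d` = richest cell), verified
  against an exhaustive oracle on small instances. Because hotspot
  selection needs a per-cell surface, selection order is encoded as
  descending scores (first selected = highest, unselected = 0); this is
  the one faithful reading of "ranking by complementarity" when no
  per-cell statistic is defined by the method itself.
- `PD(c)` is the total branch length of the subtree connecting the cell's
  species to the **root** (Faith's original convention; recorded in the
  surface provenance because unrooted conventions differ by the root path
  length). The supplied tree is used as-is: tips absent from the matrix
  keep the tree structure but never enter a cell; matrix species absent
  from the tree are excluded from PD/PE only (they remain in SR/WE/SC)
  and are logged — mirroring analyses where a few non-seed-plant taxa are
  missing from the megatree.
- `PE(c) = Σ_b L(b)/range(b)` over the same subtree, where `range(b)` is
  the number of **analysis-grid** cells occupied by the union of `b`'s
  descendant tips. "Global range" is interpreted as the study grid
  because that is the only range the analysis observes.
  `Σ_c PE(c) = total tree length` (telescoping), asserted at 1e-9
  relative tolerance.
- `PA(c) = PD(c)/PD_max + PE(c)/PE_max ∈ [0, 2]`; the maxima are recorded
  in provenance. A zero maximum (empty landscape) is an error, not a NaN.

Both PD and PE are computed by a single edge × cell incidence product and
are tested for exact agreement with an independent brute-force
implementation (per-tip root-path walking) on random 8-tip × 6-cell
instances.

## 5. Hotspot selection and overlay

Per metric, the top `k` cells are selected with `k = floor(q · n_land)` by
default. Published grid counts at these thresholds are *not* a plain
floor of the cell fraction (land-area weighting and coastal cells
intervene), so `k` is an explicit parameter (`n_target`) and any
convention can be reproduced exactly.

The four per-metric top sets (SR, SC, WE, PA by default) are merged by
**rank-sum**: every candidate (union of the top sets) is scored by the sum
of its dense ranks in each metric's *full* surface — cells outside one
metric's top set are still comparable, which the overlay description
leaves unspecified — and the `n_target` smallest rank-sums win. Ties are
broken by per-metric membership count, then SR, then cell id, so the
selection is deterministic. Cells identified by 4/3/2 metrics are Class
I/II/III; cells identified by only one metric get an explicit
"unclassified" tier rather than silently vanishing.

## 6. Effectiveness and gaps

Grid-level effectiveness for scope ∈ {NNR, PNR, NNR-PNR} is the percentage
of hotspot cells covered under that scope. A species counts as
*effectively conserved* iff it occurs in at least one **covered hotspot
cell**; the denominator is the full trait-table category total (the only
reading consistent with published numerator/denominator pairs). Gap cells
are the uncovered hotspot cells; gap species are those occurring in at
least one gap cell (a species can be both conserved and gap-exposed).
Percentages round half-up (base R rounds half-even) at 2 decimals by
default.

`protection_fixture()` realizes any stated accounting — hotspot/covered
cell counts and per-category conserved/gap species counts — as an explicit
world, which is how the acceptance worked examples recompute published
percentages from their printed numerators and denominators.

## 7. Ethnic-use analytics

The use matrix `U` (species × groups, 0/1) yields composition tables
(species used by exactly one group are *unique* to it; by two or more,
*common*), the use-frequency spectrum, and a binary sequence coding
(1 → A, 0 → C, one sequence per group over a fixed species order) exported
as FASTA/NEXUS. Distances are p-distances (Hamming / length), which on
this coding equal simple-matching dissimilarity of the matrix columns —
chosen for transparency. Trees are built by neighbor joining (or UPGMA),
optionally rooted on user-supplied outgroup pharmacopoeia rows. A Bayesian
MCMC on the pseudo-DNA coding was deliberately not reproduced: it is an
external-tool invocation on an encoding artifact, not a defined
computation; the NEXUS export lets users replicate that step externally,
and output metadata labels the in-package tree as distance-based.

## 8. Ensemble SDM post-processing

The module implements everything *around* the statistical learners:
collinearity screening (drop one member of the worst pair with
|r| > 0.85 — the one with the larger mean absolute correlation, ties to
the later name), pseudo-absence sampling (two independent sets by
default, honoring the two-set design; sets are extra ensemble members
rather than pooled, flagged in the manifest), stratified 70/30 splits,
TSS/AUC evaluation (midrank Mann–Whitney AUC; threshold grid = unique
scores; smallest threshold attaining maximal TSS), retention at TSS ≥ 0.5
and AUC ≥ 0.7, TSS-weighted ensembling, max-TSS binarization, stacked
richness, and range-change classification (per-species % area change with
current cells as denominator; zero-current species are classed "increase"
when they gain cells, else "unchanged" — the convention is stated because
the source is silent). Replicate runs (default 10) and all sampling
derive per-task seeds from one master seed.

Learners are pluggable by name through a registry because re-implementing
GLM/GAM/GBM/RF/MaxEnt would be tool-wrapping; the built-in reference
learner is a percentile envelope (suitability = fraction of screened
predictors inside the [p, 100−p] training window, default p = 0), which
is deterministic and sufficient to exercise every downstream contract,
including end-to-end recovery of a known stacked richness surface.

## 9. The synthetic world

`synthetic_world()` states one default world and the tests do not tune it:

- **Landscape**: 30 × 25 grid of 50-km cells, 20 % sea, land grown as one
  connected mass by spreading dye (uniform frontier choice) — connected,
  realistic shapes at trivial cost.
- **Species**: 120; range sizes lognormal(meanlog 2, sdlog 1) truncated to
  the land area — strong right skew, many narrow endemics; a south-west
  richness gradient (seed cells weighted `exp(strength · position)`);
  34 % of species grown inside the south-west quadrant (the endemic flag
  is then computed geometrically, so the realized endemic fraction
  exceeds the growth fraction when free-ranging species happen to fall
  inside — a documented property, not a bug); 5.3 % threatened
  (CR:EN:VU ≈ 24:94:188, assigned to the narrowest ranges) and 3.8 %
  protected — the study system's proportions.
- **Records**: ~3 expected records per occupied cell; 10 % corrupted, each
  planted to trip one specific filter (filters are cycled so failures
  localize), with the first record of every species left clean inside its
  range. Cleaning must recover the hidden validity labels with zero
  mismatches — asserted, and the per-record attributed filter must equal
  the planted one.
- **Phylogeny**: pure-birth (Yule) tree at rate 1 via `ape::rphylo`.
- **Use matrix**: 24 groups in five planted blocks (sizes 7/5/4/3/5,
  mirroring the clade sizes of the study system) at within-block
  probability 0.35 over a 0.03 background. Clustering-recovery tests use
  the harder stated configuration (two blocks, p = 0.95, background
  0.02, 300 species, 20 seeds, ≥ 19 recoveries).
- **Reserves**: 8 NNRs + 14 PNRs (NNRs twice the area), rectangle sizes
  bisected so realized land coverage is within ±20 % relative of the 15 %
  target (the approximate protected fraction of the study region).
- **Climate**: nine predictors named after the retained bioclimatic set,
  each a linear gradient plus smoothed Gaussian noise on a natural scale
  (e.g. annual mean temperature mean 8, sd 7 °C; annual precipitation
  mean 700, sd 450 mm), plus an engineered collinear duplicate of the
  first predictor (r ≈ 1) so screening is provoked unambiguously.
  Scenario stacks apply additive warming (+1.0/+1.8/+2.2/+3.7 °C for the
  four RCP labels, plausible 2070 deltas) and multiplicative
  precipitation shifts (±6 %).

**What a green test establishes — and does not.** The generator emulates
the *structure* of herbarium-derived data (range cohesion, size skew,
dirty-record types, block-structured use, partial reserve coverage,
collinear predictors), not its biases: no collector effort gradients, no
spatial clustering of duplicates, no taxonomic error, no real geography.
Green tests certify the algorithms and their contracts, not the published
landscape-scale numbers, which depend on the original occurrence database and
real climate rasters and are out of reach at desk scale. The acceptance
worked examples are the exception: their inputs are the published
numerators and denominators themselves.

## 10. Numerical conventions and scale choices

- Percentages round half-up; 90.196 % prints as 90.2 at two decimals.
- All generators and samplers are pure functions of their arguments
  including `seed`; sub-seeds derive from the master seed via a fixed
  integer recurrence kept below 2^31.
- Test and acceptance runs scale the expensive knobs down from the study
  design (pseudo-absences 150–200 instead of 10,000; 2 replicate runs
  instead of 10; 10 species instead of 2,138) — the machinery is
  identical and the budgets stay within minutes on one CPU.
- Degenerate inputs error loudly (`divprior_invalid_argument`) rather
  than propagating NaN: zero PD/PE maxima, empty hotspot sets,
  single-class evaluation labels, insufficient pseudo-absence domain.
- Known limitations: reserves are rectangles (no polygon unions or
  holes); the grid is a single contiguous extent; the envelope learner is
  a box model and should not be used for real inference — it exists so
  the ensemble machinery is testable without external model stacks;
  NJ/UPGMA trees carry no support values.
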