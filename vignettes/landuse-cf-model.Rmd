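---
title: "Land-use characterization factors from a fragmentation-aware countryside SAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land-use characterization factors from a fragmentation-aware countryside SAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucf)
```

## The model

`lucf` computes land-use characterization factors (CFs) for life cycle
impact assessment: coefficients that translate an inventory flow — square
metres of land occupied, or transformed — into a biodiversity impact
expressed as a potentially disappeared fraction (PDF) of species.

The core is a countryside species–area relationship whose habitat term
accounts for both land-use intensity and habitat fragmentation. For a
species group $g$ and ecoregion $j$, the regional species loss is

$$\mathrm{RSL}_{g,j} = 1 - \left(\frac{H_{g,j,1}}{H_{g,j,0}}\right)^{z_{g,b}},$$

where the suitable connected area $H = \sum_{i,m} h_{g,i,m}\,
\mathrm{ECA}_{g,i,m}$ sums, over land-use classes $i$ at intensity $m$
(plus natural habitat), the product of habitat affinity $h \in [0,1]$ and
the *equivalent connected area* of the class's patch mosaic. The
reference state is fully natural ($h = 1$ everywhere), so $H_0$ equals
the ecoregion area. $z \in (0,1)$ is the biome- and group-specific slope
of the species–area relationship.

The ECA is the area of a single patch with the same probability of
connectivity as the actual mosaic:

$$\mathrm{ECA} = \sqrt{\sum_x \sum_y A_x A_y\, p_{xy}},$$

which equals the total class area when all patches are fully connected
and tends to the largest patch when they are fully disconnected. The
pairwise dispersal probability uses a negative-exponential kernel
anchored at the group's median dispersal distance, $p = 2^{-d/d_{med}}$
(so $p(0)=1$ and $p(d_{med})=0.5$), where $d$ is the effective
inter-patch distance: the least-cost path over the 8-connected cell
graph, each traversed cell costing $\text{cellSize}\,(1+r)$ with
landscape resistance $r \in [0,1]$ (diagonal steps scaled by $\sqrt 2$).
Natural habitat and the habitat class itself have $r = 0$, so with no
resistance the effective distance reduces to the grid path metric. The
kernel form and the resistance weighting are this package's own
calibration choices; they satisfy the median-distance semantics with the
fewest free parameters.

Four CF families are derived from RSL:

* **average occupation**: $\mathrm{CF} = \mathrm{RSL}\cdot a_{i,m} /
  A_{i,m}$, with allocation factor $a$ (below);
* **marginal occupation**: $\partial\,\mathrm{RSL}/\partial A_{i,m}$ by
  central finite difference (relative step $10^{-4}$);
* **transformation** variants of both: $\mathrm{CF_{tra}} = \tfrac12\,
  t\,\mathrm{CF_{occ}}$, integrating a linear recovery over the
  regeneration time $t$ (years);
* **global** variants of all: the regional CF times the ecoregion's
  global extinction probability (GEP), which sums to 1 per species group
  over all ecoregions.

Occupation CFs describe the long-term committed loss if land use is
sustained (extinction debt included, no discounting).

### Allocation and the marginal derivative

The published framework attributes regional loss to classes through an
allocation factor without printing its body, and leaves open how the
marginal expansion treats the converted natural habitat. We make both
choices on one scale, the *connectivity-discounted effective affinity*
$\tilde h = h\cdot\mathrm{ECA}/A$:

* allocation weights are the connected-habitat deficits,
  $a_{i,m} \propto A_{i,m} - h_{i,m}\mathrm{ECA}_{i,m} =
  A_{i,m}(1-\tilde h_{i,m})$;
* the marginal exchange converts natural habitat at full value into
  class habitat at value $\tilde h$, i.e. $dH = (\tilde h - 1)\,dA$,
  with the pairwise-probability structure frozen.

Without fragmentation ($\mathrm{ECA}=A$) both reduce to the plain
area-times-$(1-h)$ weighting and the analytic derivative of the
species–habitat relationship, which the test suite checks to $10^{-6}$
relative error. Using the same $\tilde h$ on both sides is what makes
the marginal CF provably at least the average CF for every state with
$z<1$ in which the natural matrix is connected: treating the two
inconsistently (for instance, allocating by $A(1-h)$ while crediting the
marginal step with only the proportional ECA change) breaks that
ordering on fragmented landscapes. It also means a fully suitable but
fragmented class ($h=1$, $\mathrm{ECA}<A$) retains a small allocation —
deliberately, since its fragmentation does remove connected habitat.

## Parametrization

**Plants.** Habitat affinity comes from relative local species richness
under land use, $h = \min(1, rr^{1/z})$, capped at 1 because sampled
local richness can exceed the natural reference. Landscape resistance is
estimated from richness, $r = 1 - \min(1, rr_k/rr_{i,m})$ for
surrounding class $k$: a matrix at least as rich as the habitat is fully
permeable. Median dispersal distances per ecoregion are the median over
the species present, after taxonomic gap-filling that averages known
maximum dispersal distances at the nearest populated level (genus,
family, order, class, then kingdom); observed values are never altered.

**Vertebrates.** Ecoregion-level broad-class affinities come from
habitat-suitability species counts ($S/S_{total}$) and are rescaled for
intensity in richness space through globally defined scaling factors
$f = rr_m / rr_{minimal}$: $h_{i,m} = \min(1, h_{broad}\, f^{1/z})$.
Managed forests use the plant route. Resistance combines species overlap
with the intensity factor, $r = 1 - (S_{shared}/S_{habitat})\min(1, f)$;
when a managed forest is part of the pair, the non-forest class's
richness is back-calculated as $rr = h^z$ and the richness route
applies. Amphibians and reptiles use a fixed 9 km dispersal distance.

**Intensity merging.** Adjacent intensity levels of a land use are
merged when their richness estimates differ by less than 0.05
(practically insignificant) *and* Welch's *t*-test on the estimates and
standard errors is non-significant at 0.05. Model-estimate SEs carry no
sample sizes, so the default reference distribution is normal
($df=\infty$); Welch–Satterthwaite df are used when per-estimate df are
supplied. Merged estimates are inverse-variance-weighted means.

**Scaling factors above 1** are allowed (richness ratios can exceed 1
empirically) but flagged with a warning.

## Sensitivity variants, comparison statistics, proxies

The engine exposes the published sensitivity cases as variants:
`rr_lo`/`rr_hi` (95% confidence bounds of relative richness),
`no_intensity` (classes pooled per land use — patches are re-extracted
on the merged class, richness pooled by inverse-variance weighting for
the richness route, and intensity rescaling skipped for the
suitability route), and `no_fragmentation` (ECA replaced by total
area). Variants are compared to the default on ecoregion-level RSL (the
land-use area is identical across variants) via Spearman correlation
and sum-based percent bias, with the newer/default values as the
reference so a negative bias means the compared set is smaller.

Where richness enters as a *ratio* (vertebrate scaling factors, plant
resistance), the confidence bound is applied to the numerator only and
the denominator stays at the point estimate. Applying bounds to both
sides of a ratio is non-monotone and would break the documented
orderings $\mathrm{RSL}(rr_{hi}) \le \mathrm{RSL}(default) \le
\mathrm{RSL}(rr_{lo})$; bounding the numerator isolates the direction of
the perturbation.

Contribution-to-variance shares are squared Spearman correlations of
each factor with the CFs, normalized to sum to 1. The IUCN-style threat
filter keeps threatened species (VU/EN/CR/EW/EX) facing at least one
land-use threat (codes 1, 2.1, 2.2, 2.3 and sub-levels) whose criteria
are not A1–A4 based only on subletters d/e.

Missing CFs are filled by a deterministic, ordered proxy chain, each
output flagged: (1) the nearest intensity sibling in the same ecoregion,
rescaled through the affinity deficit $(1-h)$ ratio (within an
ecoregion, the average occupation CF of a class is proportional to its
deficit); (2) the biome average of natively computed donors (proxies are
excluded from donor pools to avoid cascades), times the target's GEP for
global CFs; (3) for missing GEPs, the biome's mean GEP density times the
target area. Countries that match no ecoregion receive the simple mean
of their three nearest neighbours (centroid distance, ties by
identifier), with SDs pooled as
$\sqrt{\overline{sd^2} + \mathrm{var}(\text{means})}$. Spatial
aggregation itself is an area-weighted mean (ecoregion-within-country
overlap areas; ecoregion or land-use areas globally — proxies force
ecoregion-area weighting) with the relative weighted SD as the
uncertainty measure; taxonomic aggregation averages vertebrate groups
with equal weight, then plants and the vertebrate mean.

## The synthetic world generator

Real inputs for this model are global land-use rasters, richness
meta-analyses, trait databases and Red List exports. The generator
replaces them with an internally consistent system with known ground
truth so that the whole pipeline is testable offline:

* **Landscapes** by seeded cluster growth: each class receives
  `round(share * cells)` cells (exact) placed with a number of accretion
  nuclei controlled by the fragmentation dial $\varphi$: one nucleus at
  $\varphi=0$ (a single connected patch), one per cell at $\varphi=1$
  (independent scatter). Accretion makes the two limits exact, which a
  fractal-noise generator would not.
* **Parameter tables** with the invariants the model assumes:
  $rr(\text{minimal}) \ge rr(\text{light}) \ge rr(\text{intense})$
  within each land use; SEs wide enough that some intensity pairs merge
  under the 0.05 rule and some do not; $z$ in the 0.15–0.35 range
  typical of species–area slopes; plant/bird/mammal dispersal in
  field-plausible ranges and the 9 km amphibian/reptile constant; GEPs
  normalized to 1 per group.
* **Countries** as a Voronoi partition of 4×4 tiles per ecoregion over
  random seeds, so ecoregion–country overlap areas are nontrivial.
* **Threat records** drawn from a template battery covering qualifying
  and masking cases, with the planted truth carried alongside.

All randomness derives from the spec's single seed; identical specs
yield byte-identical worlds. Default conditions: 4 ecoregions of 30×30
cells at 1 km (≈900 km² each), 2 biomes, 3 countries, 5 anthropogenic
land uses totalling 40% of each ecoregion, $\varphi = 0.3$, and 5
species groups. What the generator does *not* emulate: realistic
biogeography, spatial autocorrelation of intensities, species-level
distribution models, or the empirical covariance between richness and
dispersal — so passing tests demonstrate internal consistency and the
model's documented orderings, not calibration against real landscapes.

## Numerical choices and degenerate inputs

* Pairwise dispersal probabilities below $10^{-6}$ are treated as 0 to
  bound pairwise work; within-patch connectivity is exactly 1.
* Patch connectivity defaults to the 8-neighbourhood (raster diagonals
  should not sever habitat); the flood-fill rule is configurable.
* Inter-patch distances are measured between boundary-cell centres
  (edge to edge), not centroids, which would overstate separation for
  large patches. Grid coordinates are (row, col), 1-based in R; areas
  are always m².
* The marginal finite difference uses relative step $10^{-4}$; when no
  natural habitat remains the difference is one-sided (with a warning).
* An all-natural ecoregion yields no CFs (logged), not an error; a class
  with $h=1$ everywhere and intact patches receives allocation 0 with a
  warning.
* Merging with threshold 0 merges nothing; merging everything requires
  threshold $\infty$ *and* $\alpha = 0$, since the statistical gate
  "non-significant at level $\alpha$" ($p \ge \alpha$) can only pass at
  $\alpha = 1$ for exactly tied estimates.
* CSV outputs are sorted on the full record key, so identical runs are
  byte-identical.

## Problem sizes

The test suite and the acceptance script run entirely on generated
worlds, sized so the full suite completes in well under a minute of
compute per module: ordering properties use 20 single-ecoregion worlds
of 14×14 cells and two species groups; the fragmentation gradient uses
20 seeds × 5 dial positions on 18×18 grids; the ECA oracle check uses
200 random mosaics of up to 50 patches; the end-to-end determinism check
uses a 2-ecoregion, 16×16 world. These sizes are the package's own
validation choices; the engine itself has no hard limits beyond memory
(the cell graph grows with grid area, and pairwise patch work
quadratically with patch count under the probability cutoff).

## Known limitations

* Rasters are read from ESRI ASCII grids; there is no GeoTIFF reader or
  vector (polygon) support.
* The CFs quantify composition effects of occupation and transformation;
  they cannot assess a change in the degree of fragmentation itself, and
  the metapopulation-capacity alternative is out of scope.
* The dispersal kernel and resistance weighting are declared forms; real
  calibration data could prefer other shapes.
* The proxy chain guarantees coverage, not accuracy: proxy rows carry a
  flag precisely so downstream users can weigh them differently.
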