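---
title: "Methods: housing-unit-level population allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: housing-unit-level population allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abode)
```

## The two estimators

Both estimators disaggregate the same census-block data to a zone of
interest $j$ (here, radial buffers around wells); they differ in what they
assume about where people are.

**Proportional population allocation (PPA)** assumes uniform density within
each block: the zone is intersected with every block, overlaps are clipped,
their areas recomputed, and each area is weighted by the block's population
density,
$$\mathrm{PAR}_{\mathrm{PPA}}(j) \;=\; \sum_i
  \operatorname{area}(j \cap b_i)\,\rho_i .$$
By default $\rho_i$ is the standard census density (total population,
including group quarters, divided by block area); a `densityMode =
"household"` switch excludes group-quarters persons instead, which makes the
two estimators allocate exactly the same population universe. We default to
the total density because that is what a published persons-per-square-mile
figure means; the choice is visible in output rather than silently made.

**ABODE** assumes people live in discrete dwellings. Candidate address and
building-centroid points are first censored against a gridded land-use
classification (30 m cells by default): points in excluded
commercial/industrial/institutional classes are removed, and the survivors
become residential housing units (RHUs). Each RHU anchored in block $i$
receives that block's average household size
$\overline{pph}_i = (\text{pop}_i - \text{gq}_i)/\text{HU}_i$:
$$\mathrm{PAR}_{\mathrm{ABODE}}(j) \;=\; \sum_i
  \mathrm{RHU}_{ij}\, f_i\, \overline{pph}_i .$$

The cap factor $f_i$ addresses geocoded-unit inflation (non-residential
addresses that survive censoring, or units built after the census): with
`capped = TRUE` (the default reporting mode) $f_i = \min(1,
\text{HU}_i / \text{RHU}_i)$, where $\text{RHU}_i$ counts the units
assigned to block $i$ over its whole extent. Applying one multiplicative
factor per block preserves the intra-block spatial pattern of units, which
is the entire point of the method; an alternative `capMode = "hard"`
truncates each zone's per-block count at $\text{HU}_i$ instead. Uncapped
estimates ($f_i = 1$) are always reported alongside, read as an upper bound
reflecting possible post-census growth.

ABODE deliberately excludes group-quarters populations (prisons,
dormitories): household sizes do not describe them. Any zone intersecting a
block with group-quarters persons raises `gq_warning` so the analyst knows
the estimate is a floor there; no imputation is attempted.

A zone containing no RHU gets exactly zero ABODE population. This is the
false-positive detector: when PPA is positive where ABODE counts zero
units, the PPA estimate is misplaced population, classified `fp_low`
($\le 1$ person) or `fp_high` ($> 1$). The complementary class (`other`,
ABODE positive with PPA zero) is included so the taxonomy is closed, even
though it is rare in practice.

Per-well report rows use each well's individual buffer, so overlapping
buffers can count the same dwelling twice across rows; state and study
totals instead dissolve the buffers into a disjoint union (each RHU counted
once, PPA computed over the union), so total rows are *not* generally the
sum of per-well rows.

## Geometry and numerics

* **Projection.** All computation happens in a local planar frame produced
  by a Lambert azimuthal equal-area projection on the authalic sphere
  (R = 6 371 007.181 m), centred on the data extent. Equal-area is required
  because PPA weights by area; length distortion is below 0.5 % within a
  few hundred km of the centre, far below the uncertainty of geocoded
  points.
* **Buffers.** Circles are approximated by regular polygons inscribed in
  the circle (vertices on the circle), 64 segments by default; the area
  deficit is at most 0.2 % and the approximation is one-sided. RHU-in-zone
  and setback-conflict tests use the exact circle (distance $\le r$,
  boundary inclusive), so counting is unaffected by the polygonal
  approximation; only PPA's clipped areas carry it.
* **Boundary conventions.** Points on a polygon boundary are inside
  (closed-region convention), and a dwelling at exactly the setback
  distance is a conflict. Where a point lies on a shared block boundary it
  is assigned to the block with the lexicographically smallest id — an
  arbitrary but stable tie-break. Land-use cells are half-open intervals,
  so every in-extent point maps to exactly one cell.
* **Overlay.** Polygon intersection and union are delegated to the Clipper
  library (`polyclip`), which snaps coordinates to an integer grid scaled
  to the data extent; at metre scale the induced area error is below
  $10^{-6}$ relative, which the conservation tests (full-block PPA equals
  block population to 1e-6 relative) confirm.
* **Degenerate inputs.** Blocks with zero housing units get
  $\overline{pph} = 0$ and a degenerate flag — a unit mistakenly located
  there contributes nothing, consistent with the cap. Zero-area block
  geometries are rejected. Candidates in unknown land use (off-grid or
  NODATA) are retained by default: over-inclusion is the precautionary
  direction when estimating populations at risk, and `keepUnknown = FALSE`
  reverses it. Duplicate candidate coordinates are distinct housing units
  (multi-unit buildings are represented by duplicate address points); for
  building-centroid sources, where exact duplication is a data artifact,
  `dedupeSources` collapses them.

## Evaluation metrics

`fac2` is the fraction of pairs within a factor of two, with both
boundaries ($0.5$ and $2.0$) included; pairs with a zero observation have
no ratio and are excluded, with the count reported. `mape` removes zero
predictions, and necessarily zero observations as well — both exclusion
counts are reported so the effect of each rule is visible rather than
buried. Spearman correlation is the Pearson correlation of mid-ranks via
`stats::cor`; constant series are flagged undefined rather than returned as
`NA` silently.

The fractional bias is implemented as
$$\mathrm{FB} = \frac{1}{n}\left(
  \frac{\sum (A - P)}{\sum (A + P)/2}\right),$$
*including* the leading $1/n$, because that is the definition the report
tables are built on; note this differs from the conventional fractional
bias (which omits the $1/n$ and is available via `standard = TRUE`), so FB
values here shrink with the number of wells.

The Wilcoxon signed-rank test drops zero differences (Wilcoxon's original
rule; Pratt's zero-inclusive ranking is available since the choice is not
dictated by the data), uses mid-ranks with a tie-corrected variance and a
continuity-corrected normal $z$ (positive when the first series tends to
exceed the second), and switches to exhaustive $2^n$ sign enumeration for
twelve or fewer nonzero differences, where the normal approximation is at
its weakest.

## What the synthetic region emulates — and what it does not

`generateRegion()` produces every input the pipeline reads, plus a truth
table of persons per dwelling, deterministically from a seed (one RNG
stream, fixed draw order, caller's RNG state restored).

* Blocks are a jittered rectangular tiling: interior lattice corners are
  displaced up to half of `boundaryJitter` (default 0.15) times the block
  size (default 500 m), giving irregular quadrilaterals that still tile
  without gaps — enough heterogeneity in shape and area for the estimators
  to disagree, without attempting realistic TIGER geometry.
* Housing-unit counts per block are negative binomial (mean 40, dispersion
  5), reproducing strong overdispersion across blocks; household sizes are
  rounded normals truncated at 1 (mean 2.5, sd 1.2, matching typical U.S.
  household sizes); setting the sd to 0 yields a constant household size,
  under which uncapped ABODE must recover the truth exactly — the
  calibration check used in the tests.
* `placement = "boundary_clustered"` (the default) places dwellings within
  `boundaryBandwidth` (30 m) of a block edge, emulating homes strung along
  roadways that double as block boundaries — the spatial pattern that
  breaks PPA's uniformity assumption. `"uniform"` placement is PPA's
  best case and serves as the control condition.
* Multi-unit buildings appear as duplicate coordinates (`multiunitRate`,
  default 0.1); non-residential contaminant addresses
  (`nonresidentialRate`, default 0.05 of housing units) are placed in
  commercial land-use cells. Commercial cells are chosen among cells that
  contain no genuine dwelling, so dasymetric censoring removes exactly the
  contaminants — the generator guarantees a clean separation that real
  land-use models do not.
* Group quarters: a block hosts a facility with probability `gqFraction`
  (0.05), with Poisson-distributed population (mean 30).

Passing the synthetic suites therefore shows that the estimators behave
correctly *given correct inputs*: it does not validate geocoding quality,
land-use misclassification, temporal misalignment between census and
address data, or block shapes more pathological than jittered
quadrilaterals. Those error sources dominate in real applications and are
exactly what the capped/uncapped bracket and the verification-removal step
exist to absorb.

Two regimes the generator makes testable: with boundary-clustered
placement, the mean absolute error of ABODE against truth is far below
PPA's over hundreds of wells, while with uniform placement and large radii
the two estimators converge; and PPA's false-positive count cannot
increase with the search radius, since once a zone contains a dwelling it
never loses it as the radius grows.

## Problem sizes

The test suite and the acceptance script run synthetic regions of 9 to 144
blocks with 1 to 220 wells at radii of 40–800 m, and Monte-Carlo area
oracles of $10^6$ points — sizes chosen so the full chain (geometry,
censoring, assignment, both estimators, metrics, tables) is exercised many
times over while an entire run of everything stays within a few minutes on
one core. The published-table reconciliation uses the distributed per-state
rows (six states at 200 m, five with setback rules) as typed inputs.

## Known limitations

* Geodesic buffering is not implemented; buffers are planar in the local
  equal-area frame. Sub-percent geometric differences from tools that
  buffer on the ellipsoid are expected.
* Address-location subtypes (building, parcel-with-building, empty parcel,
  street-segment points) are carried as an optional annotation only;
  distinguishing them requires imagery and is out of scope, as is any
  automated visual verification (the package only applies removal lists).
* Capping operates at the block level; it cannot correct geocoding errors
  that move a unit across a block boundary.
* The Wilcoxon exact path enumerates $2^n$ sign patterns and is gated at
  $n \le 12$; larger samples use the tie-corrected normal approximation.
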