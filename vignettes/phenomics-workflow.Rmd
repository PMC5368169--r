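---
title: "Rosette morphometrics and screening statistics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rosette morphometrics and screening statistics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscreen)
```

This vignette documents the models behind `phenoscreen`, the parameters that
matter, the numerical choices made where the underlying instrument
definitions are proprietary or under-specified, and what the synthetic-data
generators do and do not emulate.

## The nine rosette descriptors

A rosette observation is a binary top-view mask (`binary_mask`): a logical
pixel grid with a `mm_per_px` scale, one plant, one day. Foreground is
8-connected; the largest connected component is taken as the rosette and
smaller specks are dropped and flagged. All outputs are converted to
millimetres.

| descriptor | definition | units | range |
|---|---|---|---|
| area *A* | foreground pixel count × scale² | mm² | > 0 |
| perimeter *P* | calibrated boundary length (below) | mm | > 0 |
| roundness | 4πA/P² | — | (0, 1] |
| roundness 2 | 4πA_h/P_h² on the convex hull | — | (0, 1] |
| isotropy | 4πA/P² of the leaf-tip polygon | — | (0, 1] |
| eccentricity | √(1 − λ₂/λ₁) of the moment ellipse | — | [0, 1) |
| RMS | area(H △ D)/area(H ∩ D) | — | ≥ 0 |
| compactness | A/A_h | — | (0, 1] |
| SOL | L²/A, L the skeleton length | — | > 0 |

Roundness compares the rosette with a perfect circle of the same perimeter
and decays as leaves elongate; roundness 2 evaluates the same isoperimetric
index on the convex hull, so it tracks the outline spanned by the leaf tips
and oscillates as leaf pairs emerge and expand; eccentricity and RMS measure
departure from a circular silhouette around the centroid; compactness and
SOL capture petiole length, blade width and leaf slenderness.

### Perimeter estimation

Counting boundary pixels (the literal instrument description) overestimates
smooth boundaries by up to ~8% and is kept only as `method = "edge"`. The
default `"contour"` estimator measures the ordered outer boundary polygon
after circular Gaussian smoothing of the vertex chain (σ = 1 vertex step):
on a rasterized disc of radius 100 px it is within 0.2% of 2πr, on a
100 px square within 1.6% of the true 400 px. A four-direction Crofton
estimator from integral geometry (`method = "crofton"`, identical
coefficient table to scikit-image) is also provided; it is excellent on
smooth convex shapes but biased low by ~5% on axis-aligned rectangles,
which is why it is not the default.

### Hull, moments, skeleton

The convex hull is taken over the *outer pixel corners*, so a filled k × k
square has hull area exactly k²; hull area uses the shoelace formula and
hull perimeter the vertex-to-vertex Euclidean sum. Second central moments
treat pixel centers as unit point masses; eccentricity is the moment-ellipse
definition, not an axis-ratio, and a zero-variance (single-pixel) mask
returns 0.

The skeleton is obtained by Zhang–Suen iterative thinning, with two
refinements:

* **Hole filling.** Where leaf blades overlap, the silhouette encloses
  small background gaps; an unfilled hole forces the skeleton into a loop
  around it and can triple the measured length. Holes are filled before
  thinning so the skeleton traces leaf axes.
* **Canonical orientation.** Directional thinning is not symmetric under
  rotation or mirroring. The grid is first mapped to the lexicographic
  minimum of its 8-member dihedral orbit, which makes skeleton length (and
  hence SOL) *exactly* invariant under 90°/180° rotation and mirroring.

Skeleton length counts orthogonal steps as 1 px and diagonal steps as √2 px;
diagonal links that shortcut an orthogonally connected corner are not
double-counted, and an isolated skeleton pixel contributes one unit so that
SOL stays positive on any non-empty mask.

### RMS and the tip polygon

RMS compares the hull with the equal-area disc centred at the centroid. The
overlap area is computed by exact polygon–disc clipping (per-edge signed
decomposition into chord triangles and circular sectors); tests verify it
against a ≥ 2 × 10⁶-point grid-sampling oracle to 2 × 10⁻³. For a unit
square versus its equal-area disc the index is 0.1991.

The instrument's isotropy polygon is not published. Here leaf tips are
detected as local maxima of the centroid-distance profile along the ordered
boundary, kept when their radial prominence exceeds 5% of the maximum
radius, with peaks closer than 10° in centroid angle merged. With fewer
than three tips (young or circular rosettes) the hull polygon is used and
the record is flagged `isotropy-hull-fallback`. Both the isotropy polygon
and the instrument's exact roundness 2 / RMS conventions are therefore
reconstructions constrained by the published wild-type ranges (roundness
0.1–0.5, roundness 2 0.7–1.0, SOL < 50), which the defaults reproduce.

### Degenerate inputs and clipping

Empty masks raise a classed condition that batch runs convert into an
`empty-mask` QC flag (all-NA row) rather than an abort; masks with fewer
than three non-collinear pixels flag `degenerate-hull` and leave the
hull-based descriptors NA. Discretization can push 4πA/P² marginally above
1; such values are clipped to 1 and flagged. One raster-level caveat
follows from calibration: for *near-convex* shapes any staircase-debiased
perimeter sits slightly below the outer-corner hull perimeter, so measured
roundness can exceed roundness 2 by up to ~0.04 even though the continuous
inequality runs the other way; on genuinely concave rosette silhouettes the
inequality holds with a wide margin.

## Longitudinal genotype comparison

Each descriptor is modelled by ordinary least squares against a polynomial
in day, with the day axis rescaled to [−1, 1] to keep the order-6 bases
well conditioned. The genotype-augmented model adds a genotype main effect
and genotype × polynomial interactions — `order + 1` extra coefficients per
non-reference genotype — so the full curve may differ, not just its level.
Default orders are area 3, perimeter 3, compactness 4, roundness 5,
roundness 2 5, isotropy 6, eccentricity 6, RMS 6, SOL 3.

Model pairs are compared with the Gaussian likelihood-ratio statistic
2(ℓ₁ − ℓ₀) on a chi-square reference with df equal to the coefficient
difference. Repeated measures within plant are acknowledged by an optional
plant-level block bootstrap p-value (whole-plant residual curves resampled
under the small model); the chi-square test is the default because with
iid noise it is exact in spirit and calibrated in practice — under the null
(20 plants per genotype, days 10–20, Gaussian noise) 1000 simulations give
a rejection rate within [0.03, 0.07] at α = 0.05, and a 3-SD area offset is
detected at p < 0.001 in ≥ 99% of runs.

Flowering traits (LAB, DTB) are compared by one-way ANOVA with many-to-one
Dunnett contrasts against the control, using multivariate-t critical points
under the equicorrelation implied by the shared control (via `multcomp`);
the quasi-random integration is run under a fixed local seed so reports are
reproducible. Flower-defect tables use exact percentages displayed
round-half-up plus Fisher's exact test. Experimental rounds are analysed
separately, as they are reported.

## Expression screen, qPCR, RING classification

The expression screen is a plain ratio screen on linear-scale values:
log2(FL) − log2(R) against the developed-rosette reference, strict cutoff
log2FC > 1 (a gene at exactly 2-fold is excluded). Genes with a nonpositive
or missing value in either column are excluded per category and surfaced in
a coverage report; duplicate probe rows collapse to the per-column maximum,
preserving "enriched anywhere" semantics. Venn regions are counted over all
2^k − 1 membership patterns and the union keeps first-seen order.

qPCR fold changes follow 2^−ΔΔCt: technical replicates averaged, ΔCt taken
against the arithmetic mean of the reference genes' mean Cts (the combining
rule across the three standard references is not published; the arithmetic
mean is the simplest symmetric choice, and efficiency-corrected
geometric-mean schemes are out of scope). Classification bands: < 0.1
knock-out, 0.1–0.5 (closed) knock-down, > 2 (strict) up-regulated,
otherwise unchanged.

RING domains are located by the canonical spacing pattern with metal
positions 1, 2, 3, 6, 7, 8 fixed to cysteine and 4, 5 drawn from
{C, H, D, S, T}; the spacing bounds are configuration (`ring_spacing()`),
not constants. Matching is leftmost-longest: earliest feasible start, then
the latest end at that start, remaining interior ambiguity resolved
greedily from the left; tests verify exact agreement with a brute-force
enumeration oracle. Subtypes are assigned from a priority-ordered rule
table shipped as an editable CSV (HC, H2, v by the position-4/5 pair; C2
all-cysteine; D, S/T, G by any matching metal residue; otherwise
non-canonical — G is included for completeness although most tallies omit
it). Proteins with signature evidence whose ligands cannot be located are
reported in a `signature_only` tier rather than silently dropped, and
isoforms collapse to locus ids before set reconciliation.

## The synthetic-data generators

Every generator is a pure function of its seed (the RNG state is saved and
restored, so callers' streams are untouched) and emits ground truth
sufficient to score recovery exactly.

The rosette renderer models leaves emerging in opposite pairs — the first
two pairs decussate, later leaves spiralling at the 137.5° divergence —
each expanding along a logistic curve and drawn as a petiole segment plus
an elliptical, optionally serrated blade, hard-thresholded with no
anti-aliasing so descriptor tests are deterministic. Defaults (first pair
at day 5, one pair every 2 days, asymptotic leaf length 10 mm growing 20%
per pair and capped at 24 mm, logistic rate 0.55/day with a 4.5-day
half-size lag, petiole fraction 0.30, blade aspect 0.70, serration depth
0.05) were chosen once to land the rendered wild type inside the published
descriptor ranges and are not tuned per analysis: the series shows
roundness ≈ 0.3–0.4, oscillating roundness 2 within 0.87–0.94, an early
eccentricity peak (> 0.7 at the two-leaf stage) that decays and returns
late, and SOL between ~10 and ~25. The renderer emulates silhouette
geometry only — no colour, no overlap occlusion from 3D leaf posture, no
nastic movement, no segmentation noise — so passing tests demonstrate
correctness of the measurement pipeline, not robustness to real
segmentation artefacts.

Longitudinal tables use a quadratic baseline plus per-genotype intercept
and slope offsets with iid Gaussian noise. The expression generator plants
a known set of genes at folds strictly above 2 and keeps everything else
strictly below 2-fold so recovery is exact. The Ct generator shifts target
Cts by −log2(fold) in the mutant. The proteome generator writes background
sequences over an alphabet free of metal-ligand residues so the planted
motif is the only possible match. Recovery of fold changes under technical
noise (replicate SD 0.2 cycles) is assessed on the geometric mean over 24
independently seeded replicate tables, mirroring (and extending) the
biological-replication protocol: a single table's ΔΔCt log2-error SD is
~0.19 with three technical replicates, so a per-table 10% check would be a
coin flip regardless of implementation quality.

## Problem sizes and limitations

The test suite runs at desk scale: 1000 null simulations for test
calibration, 150 power runs, a 60-blob property suite plus 20 rendered
rosette series for the descriptor invariants, 200 sequences for the RING
oracle, and end-to-end determinism on 2 plants × 2 genotypes × 5 days at
280 px. Masks of 300–400 px process in ~0.2–1 s each, dominated by
thinning.

Known limitations: the isotropy/roundness 2/RMS formulas are reconstructions
of unpublished instrument definitions; the perimeter of shapes with
interior holes is measured on the outer boundary by the default estimator
(use `"crofton"` or `"edge"` when hole boundaries must count); the growth
test assumes a common residual variance across genotypes; and the Dunnett
step assumes approximately balanced groups for its equicorrelation
structure.
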