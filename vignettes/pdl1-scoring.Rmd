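---
title: "Area-ranked digital PD-L1 scoring for DLBCL: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Area-ranked digital PD-L1 scoring for DLBCL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdl1quant)
```

## The quantification problem

The tumor proportion score (TPS) for PD-L1 is defined as

$$\mathrm{TPS} = \frac{\#\,\text{PD-L1}^{+}\ \text{tumor cells}}
                     {\#\,\text{viable tumor cells}} \times 100\%.$$

In solid tumors the denominator is tractable because tumor regions can be
delineated and cells inside them counted. Diffuse large B cell lymphoma
(DLBCL) breaks this: the malignancy is diffuse, tumor B cells and
non-malignant immune cells intermingle and can both express PD-L1, and no
region boundary separates them. A digital pipeline therefore cannot rely
on region identity to decide which cells enter the denominator.

This package implements a morphology-based selection rule instead. It
rests on one premise: DLBCL tumor B cells are medium-to-large cells whose
nuclei are comparable to macrophage nuclei or more than twice the size of
normal lymphocyte nuclei. Given every segmented cell in the regions of
interest, ranked by nucleus area in descending order:

1. drop the top $m\%$ largest cells — the extreme of the area distribution
   is enriched for non-tumor giants (macrophages, endothelial cells);
2. designate the next $k$ largest cells the *tumor cells*;
3. score

$$\mathrm{TPS}^{*} = \frac{\#\,\text{PD-L1}^{+}\ \text{cells among the top-}k}
                          {k} \times 100\%.$$

The operating point used throughout is $m = 0.06$, $k = 3000$, $t = 0.1$,
where $t$ is the positivity threshold described below. Scores are
stratified at the guideline cutoffs 5% and 50% into low / intermediate /
high expression, the bands that drive immunotherapy decisions.

## Pipeline stages and their parameters

`run_pipeline()` executes five stages; every parameter below lives in
`pipeline_config()` under the block named after the stage.

**ROI delineation** (`roi.*`). A slide is a directory of square tiles
(half-open pixel bounds, origin top-left; a point on a shared edge belongs
to the tile to its lower-right). Non-ROI expert annotations (ASAP XML
polygons: debris, necrosis, fat, burn artifacts...) are *inverted*: a tile
is excluded when more than `roi.overlap_threshold` (default 0.5, a
majority rule) of its pixel centers fall inside the annotated union.
Without annotations, a pluggable per-tile classifier decides; the shipped
baseline is training-free and marks a tile in-ROI when at least
`roi.min_tissue_fraction` (2%) of pixels are chromatic and non-white —
stained tissue is chromatic (blue/brown), while the generator's artifact
tiles and blank glass are achromatic. Learned classifiers can be swapped
in through the same `patch -> {in, out}` contract.

**Cell detection** (`detect.*`). Nuclei absorb hematoxylin, so cell
centers are local maxima of the smoothed hematoxylin optical-density (OD)
channel: Gaussian smoothing at `detect.sigma` (2 px), peaks at least
`detect.min_separation` apart (6 px, the smallest nucleus diameter the
generator produces) and above `detect.threshold` OD (0.15, comfortably
above the background leak of the near-white slide background, below the
0.5–0.9 nuclear concentrations the generator renders). A learned density
regressor can replace this backend; `density_target()` builds the
unit-mass Gaussian training targets such models regress, renormalized
after boundary truncation so the map integrates to the point count.

**Segmentation** (`segment.*`). Seeded region competition (EBImage's
`propagate`) on the hematoxylin OD channel assigns foreground pixels
(`segment.fg_threshold` 0.1 OD after `segment.fg_sigma` = 0.5 px
smoothing) to the nearest seed; seeds stranded on background claim a
minimal 3-px disk so every detected cell has nonzero area and the
downstream ratio is defined. The foreground smoothing bandwidth is kept
deliberately small: with a detection-scale bandwidth (σ ≈ 2 px) a disk
nucleus of radius 8 px inflates by ~50% in area, while at 0.5 px the
inflation stays within the ~15% the area-ranking rule tolerates without
reordering classes. Masks are then dilated by
`segment.dilation_radius` (3 px) so each cell's region reaches past its
membrane — PD-L1 is a membrane stain, and an intact or partial brown
annulus sits just outside the nucleus. Dilation is competitive: contested
pixels go to the Euclidean-nearest region, ties to the lower label id, so
regions never overlap and growing the radius can only grow each area.

**Stain separation and positivity** (`stain.*`). Brightfield IHC follows
Beer–Lambert: per channel, $I = I_0 e^{-\sum_s c_s V_s}$ with $V_s$ the
unit OD vector of stain $s$. `separate_stains()` inverts
$\mathrm{OD} = -\log(I/I_0)$ onto the standard Ruifrok–Johnston H-DAB
basis by least squares (per-slide matrices can be supplied to absorb
staining variation between labs and scanners). A pixel is *brown* when
its DAB OD reaches `stain.dab_od_threshold` (0.15); a cell's *brown-area
ratio* is the brown fraction of its dilated region, and the cell is
PD-L1-positive when that ratio reaches `stain.t` (0.1). The ratio-based
call is robust to incomplete membranes: a half-arc membrane on a radius-8
nucleus still covers ~20% of the dilated region, double the default
threshold, while a negative cell's region carries essentially no DAB.
Positivity is monotone in $t$ by construction — the positive set at a
higher threshold is nested in the set at any lower one — which is what
makes the $t$-sweep in `sweep_parameters()` interpretable.

**Scoring** (`score.*`). `tps_star()` composes ranking, exclusion and
selection as above and reports every intermediate count (total, after
exclusion, selected, positive-selected) plus an area histogram, so a
reviewer can see *why* a slide got its score, not just the number.

## Numerical conventions

Decisions the mathematics leaves open are fixed as follows, once:

- Exclusion removes exactly $\lfloor m N \rfloor$ cells.
- Area ties rank deterministically by (y, x, id), making TPS* invariant
  to the input order of cells.
- `ratio >= t` counts as positive; at $t = 0$ the rule degenerates to
  "any brown pixel", so a fully unstained cell is never positive.
- Strata are left-closed: a score exactly at a cutoff enters the higher
  stratum (TPS = 5 is intermediate, TPS = 50 is high).
- When fewer than $k$ cells survive exclusion, the denominator falls back
  to the selected count and the score carries an `under_k` flag; slides
  with fewer than `score.min_cells` cells in total (default $k$) are
  *unscorable* and return a structured "insufficient cells" outcome
  rather than a number — low-cellularity specimens are excluded from
  outcome statistics, not extrapolated.
- Log-scale MSE is $\log_{10}(\mathrm{MSE} + 10^{-12})$, so exact
  agreement sits at the finite floor of −12.

## Rater concordance

Agreement over a panel of raters (pathologists and/or the algorithm) uses
ICC3k — the two-way mixed-effects, consistency, average-measures
intraclass correlation, appropriate when the same fixed panel rates every
slide and scores are averaged. From the two-way ANOVA mean squares,

$$\mathrm{ICC3k} = \frac{MS_R - MS_E}{MS_R}, \qquad
  F = \frac{MS_R}{MS_E},\quad df_1 = n-1,\quad df_2 = (n-1)(k-1),$$

with the p-value from $F(df_1, df_2)$ and the 95% CI by F-quantile
inversion. The consistency form is invariant to per-rater shifts and to
positive rescaling; rows with missing ratings are dropped listwise with a
logged count. `stratified_agreement()` cross-tabulates clinical strata
between the algorithm and the (mean or median) aggregated raters, where
off-diagonal cells are the clinically meaningful discordances.

## What the synthetic generator emulates — and what it does not

`generate_patch()`/`generate_slide()` exist so that every stage has a
pixel- or label-level oracle. They emulate the features the method's
correctness actually depends on:

- three cell classes with the DLBCL size ordering — small lymphocytes
  (3–5 px nucleus radius), tumor B cells (6–11 px), oversized non-tumor
  cells (12–18 px, ~5% of cells). These radii are generator choices
  consistent with the "more than twice the size" morphology premise, not
  calibrated measurements; the source imagery's 40× scans never state a
  µm/px scale, so all geometry is in pixels.
- hematoxylin nuclei and DAB membrane annuli (2–4 px thick, arc fraction
  0.5–1.0 to emulate incomplete membranes) rendered through the *same*
  forward Beer–Lambert model the stain module inverts, so deconvolution
  is exact up to 8-bit quantization;
- per-class Bernoulli positivity with a recomputable true TPS;
- slide-level artifact tiles (achromatic debris) recorded as ASAP
  non-ROI polygons, exercising annotation inversion and the baseline
  classifier;
- cell placement by sequential dart throwing with a pairwise minimum
  center distance of `spacing_factor` × (sum of the two radii). The
  factor (default 1.1) is the crowding dial; it is defined pairwise
  because a global spacing set by the largest class cannot pack the
  >100 cells per 256-px patch the emulated data contain, and a
  max-radius pairwise rule would let two large nuclei coincide.

Deliberately *not* emulated: chromatin texture, scanner noise and
compression, overlapping/touching nuclei beyond what the spacing rule
allows, out-of-focus regions, and stain spillover. Passing the synthetic
suite therefore demonstrates the correctness of the rule arithmetic, the
geometry, and the color model — not detector or segmenter performance on
real tissue, where learned backends plugged into the same contracts are
expected to replace the classical defaults.

## Validation setup

The test suite validates the pipeline end to end on cohorts of 20
synthetic slides (2×4 tiles of 512 px, ≈4200 cells each, true positive
tumor fractions spanning 0–100%, scored at $k$ = 1500 so the selection
stays inside the tumor-cell population after exclusion), checking TPS*
recovery within 5 percentage points and stratum agreement, alongside
exact brute-force oracles for the rule arithmetic, ANOVA oracles for
ICC3k, and analytic-disk oracles for segmentation.
`scripts/acceptance.R` re-runs a 10-slide cohort of the same design plus
the detection, stain and concordance checks and writes the measured
quantities as JSON.

## Known limitations

- The classical detector and segmenter are tuned to the generator's
  clean imagery; on real slides they are baselines, not claims.
- The brown-pixel definition is an OD threshold on the DAB channel; no
  attempt is made to learn stain vectors from data (a Macenko-style
  estimator would slot in behind `separate_stains()`'s matrix argument).
- TPS* recovery degrades by design when the morphology premise fails —
  e.g. tumor fractions so low that the top-$k$ window reaches into the
  lymphocyte population, or $k$ larger than the tumor population. The
  `under_k` flag and the reported stage counts make such slides visible.
- ICC confidence intervals use F-quantile inversion; other CI
  constructions for average-measure ICCs exist and differ slightly at
  small $n$.
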