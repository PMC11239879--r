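---
title: "ciliomics: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ciliomics: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliomics)
```

This vignette documents the science behind the package: what each model
assumes, what the tunable parameters mean, which conventions were chosen
where several were defensible, and what the synthetic-data tests do and do
not demonstrate about real data.

# The imaging problem

Primary cilia of polarized kidney epithelial cells (IMCD3, mCCD) are thin
(~0.2–0.5 µm wide), a few micrometres long, and protrude apically from the
cell body. Ciliary trafficking studies need per-cilium readouts from 3D
spinning-disk stacks: the cilium's length, whether a cell is ciliated at
all, and how much of a target protein sits in the cilium — resolved into
the **base region** (the proximal segment around the basal body, where
many trafficking factors concentrate) and the remaining **body**. Manual
scoring of hundreds of cilia per condition is slow and biased, hence the
fully automated five-step pipeline in `run_quantification()`.

## Pipeline model and assumptions

1. **Nucleus segmentation.** The nucleus channel is Gaussian-smoothed
   (anisotropy-aware: the sigma in micrometres is converted per axis),
   background is removed by grayscale box opening at a scale well above
   the nucleus radius (a rolling-ball analogue), and one global threshold
   is applied over the whole volume — Otsu's criterion on the
   background-subtracted image by default, with a numeric manual override
   for atypical stainings. 26-connected components below
   `min_nucleus_volume` are discarded. The method assumes nuclei are
   bright, compact and mutually separated; touching nuclei are not split
   (no watershed), which matches monolayer cultures but not dense tissue.

2. **Cilium segmentation and assignment.** The marker channel (e.g.
   acetylated α-tubulin) is smoothed lightly and thresholded **locally**: a
   voxel is foreground when it exceeds the mean of its surrounding window
   (`local_threshold_window`, default 2 µm) by `local_threshold_offset`
   camera units. A positive offset is essential — with an offset of zero,
   half of all background voxels would exceed their local mean and the
   foreground would percolate. The default (300) was chosen once against
   the generator's default amplitudes (marker amplitude 1500 over
   background 100) so that the detected tube tracks the painted tube;
   real data will need this rescaled to the camera's dynamic range.
   Candidates pass a size filter and are assigned to nuclei by overlap of
   their XY projection with the 2 µm-dilated XY projection of a nucleus
   (ties: largest overlap, then nearest 3D centroid). In apical stacks a
   cilium rarely intersects its nucleus in 3D, so the projection rule is
   used instead of volumetric overlap. Per nucleus, only the candidate
   with the highest mean smoothed marker intensity is retained — one
   cilium per cell, the brightest object wins.

3. **Base detection.** The base is the cilium voxel minimizing the
   anisotropy-scaled Euclidean distance to the nucleus center of mass
   (binary centroid by default; intensity-weighted via
   `intensity_weighted_centroid`). This encodes the assumption that cilia
   grow outward from the cell body. Exact ties are broken
   lexicographically by (z, y, x).

4. **Geodesic base region.** Distances are propagated from the base voxel
   with Dijkstra's algorithm *inside the cilium mask only*, over the
   26-neighbour graph with physical edge lengths. The base region is all
   voxels at distance ≤ `base_max_geodesic` (default 1 µm, inclusive);
   the body is the remainder. Mask fragments unreachable from the base
   (segmentation artefacts) are assigned to the body and flagged.

5. **Intensity measurement.** Each target channel is corrected by
   subtracting its own 3D median-filtered copy (`median_filter_radius`,
   default 2 µm — it must exceed the cilium width so the cilium itself
   does not inflate its local background). Negative corrected values are
   retained so that noise averages out instead of biasing means upward.
   MFIs are means of corrected values over whole/base/body; an empty body
   yields `NA`, never 0.

**Length** is the geodesic diameter of the cilium mask: the largest
anisotropy-weighted shortest-path distance between any two mask voxels,
found with a double Dijkstra sweep. For the quasi-one-dimensional masks
that cilia produce, this coincides with the skeleton path length while
avoiding an explicit 3D thinning step; a single-voxel object has length
0, and scaling the voxel spacing by c scales the length by exactly c.
**Ciliation frequency** is the fraction of nuclei with a retained
associated cilium; with zero nuclei it is undefined (`NA`), not 0.

## Numerical choices

* Voxel coordinates are 1-based (z, y, x) integer indices, the natural R
  convention; all physical quantities are micrometres, intensities raw
  camera units.
* The 3D median filter runs on a histogram of 2048 quantized bins
  (quantization error ≤ range/2048 ≈ 0.5 camera units for 12-bit-like
  data) and, by default, on a 2× in-plane subsampled grid
  (`median_downsample`); the background varies on the scale of the filter
  radius, so the subsampled estimate is indistinguishable in practice and
  an order of magnitude faster.
* Geodesic boundaries are inclusive (≤), matching the base-region
  definition; Otsu uses 256 bins between the observed extremes.
* TIFF export stores 16-bit integers with spacing and channel roles in a
  JSON sidecar; intensities round-trip to within one camera unit.

# The synthetic imaging generator

`generate_cell_field()` emulates a spinning-disk stack of a ciliated
epithelial monolayer: ellipsoidal nuclei (default semi-axes
2.2 × 3.4 × 3.4 µm ± 8%) placed near the basal side with a minimum
in-plane center separation (default 2.4× the in-plane semi-axis, i.e.
nuclei sit side by side without touching); each cell is ciliated with
probability `ciliation_prob` (default 0.7, typical of serum-starved
kidney epithelial cultures). A cilium is a bounded-curvature random walk
in continuous space — unit steps of the in-plane pitch, random bend up to
`cilium_curvature` (0.35 rad/µm) per step, apical tilt up to 35° — grown
from the nucleus surface away from the centroid, with length drawn from
N(4, 1) µm truncated at 1.5 µm. The walk is painted as a 0.25 µm-radius
tube (axoneme plus antibody decoration) into the marker channel; the
target channel carries 800 camera units on tube voxels within 1 µm arc
length of the start and 200 beyond, giving a known base-enriched ground
truth. The clean volume is blurred with an anisotropic Gaussian PSF
(σ = 0.11 µm in-plane, 0.3 µm axially — a diffraction-limited spinning
disk), a constant-plus-gradient background is added, Poisson noise is
applied to the expected counts and Gaussian read noise on top — the
standard camera model, in that order. Ground truth (nucleus voxels, axis
polyline, tube voxels, base segment, true length, amplitudes) is recorded
before blur and noise.

Voxel geometry defaults to 0.4 µm z-steps and 0.2 µm pixels over an
88 × 88 µm field with 50 cells — the scale of one image in a transwell
experiment.

Two conventions deserve a note:

* **True length is the arc length of the continuous axis**, not of the
  voxelized polyline. Voxelizing a 35°-tilted curve inflates its
  step-sum length by the lattice zigzag factor (~10%), an artefact of the
  grid that no mask-based measurement could (or should) recover. For
  axis-aligned straight cilia the two conventions coincide exactly. The
  voxel polyline is still exported for geometry tests.
* **Per-cell random sub-streams** are derived from the master seed, so
  increasing `n_nuclei` appends cells without reshuffling earlier ones;
  noise has its own sub-stream.

What the generator does **not** model: depth-dependent PSF broadening,
spectral bleed-through, transwell membrane autofluorescence, multi-cilium
or mitotic cells, and touching nuclei. Passing the recovery suite
therefore demonstrates correctness of the measurement operators under
realistic SNR and anisotropy — not robustness to every real-world
artefact; on real data the thresholds and scales in `quant_config()` are
the knobs to revisit.

Measured on the default conditions (20 stacks, ~700 cilia): detection F1
= 1.0 at a per-object Jaccard ≥ 0.5 criterion, length MAE ≈ 1.6 in-plane
pitches (≈ 0.33 µm), and the base MFI exceeds the body MFI in 100% of
matched cilia — recomputed from scratch by `scripts/acceptance.R` and the
test suite.

# The LFQ differential pipeline

The BioID2 design contrasts KO vs WT for two constructs: the
cilia-targeted ligase (cilia-BioID2, reporting the ciliary proteome) and
the untargeted ligase (BioID2, the whole-cell control). Six technical
replicates per cell line; LFQ intensity 0 means "not quantified".

* **Imputation** (`impute_missing()`): per protein per (construct,
  genotype) group, in log2 space, zeros are replaced by draws from a
  downshifted normal — but only when zeros occupy fewer than half of the
  group's replicates; groups half-or-more missing are left as genuine
  absences for the median/pseudovalue path. The default `perseus_sd` mode
  reads "1.8 below the mean, width 0.5 the spread" in standard-deviation
  units (the Perseus convention): mean − 1.8·SD, width 0.5·SD. Because
  the phrase is ambiguous, a `literal_mean` mode (mean/1.8, width
  0.5·mean) ships for sensitivity analysis; neither is asserted to be the
  original. A group with a single nonzero value has no SD and is left
  untouched with a warning.
* **Ratios** (`group_log2_ratio()`): log2 of the ratio of group medians,
  oriented KO/WT so depletion from the cilium upon knockout is negative
  (the volcano's left side). If exactly one median is zero the infinite
  ratio is replaced by a pseudovalue two units beyond the extreme finite
  ratio — these are the vertical stripes at a volcano's flanks. Proteins
  with both medians zero are dropped from that contrast only.
* **Testing**: two-sided equal-variance Student's t on log2 nonzero
  intensities (≥2 values per group required; zero variance in both groups
  with equal means gives p = 1 by convention), BH-corrected across the
  contrast; and the **Significance A** robust outlier test, with z-scores
  from the 15.87/50/84.13 percentiles of the ratio distribution and
  p = ½·erfc(z/√2).
* **Significance A conventions.** The ½·erfc form is the estimated tail
  probability *in the observed direction*: under a symmetric null it is
  uniform on (0, 0.5], so P(p ≤ α) = 2α. `significance_a()` defaults to
  this directional statistic (it is what a Perseus-style analysis
  reports), while `run_diff_pipeline()` defaults to the doubled,
  two-sided version (`sigA_two_sided = TRUE`), which Monte-Carlo
  calibration confirms satisfies P(p ≤ α) = α. The calibrated version
  keeps the tier boundaries and the control filter at their nominal
  levels — with the directional statistic, the control filter would
  spuriously discard ~10% of all proteins. Users replicating a Perseus
  analysis verbatim can switch the flag.
* **Control filter and tiers**: a protein significant in the whole-cell
  control contrast by *either* criterion (q ≤ 0.05 or SigA ≤ 0.05 — the
  most conservative exclusion) is excluded from ciliary tier assignment;
  remaining proteins are Tier 1 (both), Tier 2 (SigA only), Tier 3 (q
  only) or NS, with inclusive (≤) boundaries and direction from the ratio
  sign.

On simulated null experiments the Tier 1 fraction is ~0; with 50 spikes
at log2FC −2, n = 6, replicate SD 0.5 (the study's scale), ≥ 90% of
spikes reach Tier 1 with the correct direction and ~98% of contaminants
(altered in both constructs) are excluded by the control filter. The
power simulation disables dropout to isolate power; with
intensity-dependent dropout on, strongly depleted proteins lose their
t-test (fewer than 2 quantified KO values) and land in Tier 2 via their
pseudovalue ratios — exactly the behaviour seen at a volcano's edges.

# GO enrichment

Classic (unweighted) one-sided Fisher exact tests per term, over
annotations closed under the true-path rule (a gene annotated to a term
is annotated to all its ancestors); the background is the full protein
universe of the proteomics analysis. The ontology is supplied as a
term-parent edge list or a minimal OBO subset (`id`, `namespace`, `is_a`
only). Within a namespace, p-values are BH-corrected by default (the
"corrected P-value" reading; `adjust = "none"` gives raw Fisher), terms
with corrected p < 0.05 are ranked by *sample* odds ratio (descending,
ties by p then term id) and truncated to the top 30; finally any retained
term that is an ancestor of another retained term is pruned, keeping the
most specific term of each lineage. Pruning is idempotent and removes
only ancestors of retained terms. topGO's elim/weight algorithms are
deliberately not reimplemented — the analysis is the classic Fisher test,
stated as such.

# Group comparisons

`compare_groups()` implements the normality-driven decision tree used for
image-derived measurements: each group is tested for normality at
α = 0.05 — Shapiro–Wilk when n < 8 (the K² moments approximation is
invalid at tiny n), D'Agostino K² otherwise (skewness z after D'Agostino
1970, kurtosis z after Anscombe–Glynn 1983, K² = Z₁² + Z₂² ~ χ²₂; the
implementation is verified against an independent reference to 10
decimals). All groups normal → Student's t (2 groups, equal-variance,
two-tailed) or one-way ANOVA with Tukey HSD; otherwise Mann–Whitney
(normal approximation, continuity- and tie-corrected; all-tied samples
give p = 1) or Kruskal–Wallis with Dunn's pairwise z-tests,
Bonferroni-adjusted (the common default; the source analysis names only
"Dunn's"). A zero-variance group is treated as failing normality, which
routes degenerate data to the rank branch. Stars: ns ≥ 0.05, * < 0.05,
** < 0.01, *** < 0.001, **** < 0.0001.

`normalize_to_control()` divides every value by the control-group mean,
so the control mean is exactly 1 — the "relative MFI, WT-normalized"
convention. Whether per-cilium values or per-animal averages are the unit
of analysis is the caller's choice: aggregate before calling.

# Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run the imaging recovery on 20
stacks of ~50 cells (about 700 cilia), the oracle comparisons at m ≤ 1000
(BH) and 10⁴ null ratios (Significance A), and the FDR/power simulations
at 1000 proteins — sizes chosen to mirror one experimental batch while
keeping a full run within a few minutes on a single core. Every
stochastic stage consumes an explicit seed; identical seeds reproduce
byte-identical stacks, matrices and result tables, and the quantification
pipeline itself contains no randomness at all.

# Known limitations

* No nucleus splitting: touching nuclei merge, and their cilia then
  compete under the brightest-wins rule.
* Length is measured on the segmented mask; systematic under-segmentation
  of dim distal tips shortens it, and mask-width effects add ~1 pixel of
  uncertainty at each end.
* The imputation and Significance A conventions are documented
  interpretations of an ambiguous written description; both alternatives
  are implemented, and conclusions that depend on the choice should be
  checked under both.
* The GO module handles `is_a` edges only; `part_of` and obsolete-term
  handling are out of scope.
* Tissue-section geometry (IHC) and time-lapse tracking are out of scope;
  the operators apply, but section-specific QC does not exist here.
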