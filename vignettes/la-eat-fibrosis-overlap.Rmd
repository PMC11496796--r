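---
title: "Quantifying the spatial overlap of left atrial epicardial fat and wall fibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the spatial overlap of left atrial epicardial fat and wall fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Epicardial adipose tissue (EAT) and wall fibrosis both contribute to the
pathogenesis and progression of atrial fibrillation (AF), and a popular
mechanistic account has EAT inducing fibrosis locally — by infiltration and
paracrine signalling — which predicts that the two tissues should be found
*next to each other* on the left atrial (LA) wall. Water/fat-separated late
gadolinium enhancement (LGE-Dixon) MRI lets both be segmented in one scan:
the water reconstruction carries the hyperenhancement that marks fibrosis,
the fat reconstruction carries EAT. `laoverlap` implements the measurement
chain that turns three co-registered binary segmentations (intramural LA
wall, blood pool, EAT) plus the water image into per-subject overlap
metrics, and the cohort statistics that relate those metrics to the
clinical AF stage (non-AF < paroxysmal < persistent < permanent).

The pipeline has five stages:

1. **Wall surface.** A triangulated isosurface is extracted from the
   binary wall mask at level 0.5 in world millimetres. The shell has two
   sheets (endocardial and epicardial); both are kept, and half the total
   triangle area is reported as the single-sided wall surface.
2. **Outward normals.** Vertex normals are area-weighted averages of
   incident face normals, then oriented "out from the LA": a normal is
   flipped if it does not increase the Euclidean distance-from-blood-pool
   field at the vertex. Each wall voxel inherits the normal of its closest
   mesh vertex (Euclidean distance in mm, ties to the lowest vertex id).
3. **EAT adjacency.** From each wall-voxel center a ray is cast along the
   outward normal and sampled every 0.5 mm up to 6 mm. Samples falling
   back inside the wall are skipped (intramural voxel centers can sit
   mid-wall), samples off the grid end the ray, and the voxel is flagged
   EAT-adjacent if any sample lands in the EAT mask.
4. **Fibrosis and overlap.** A wall voxel is fibrotic if its water signal
   intensity (SI) exceeds a threshold: either the patient-specific
   mitral-valve threshold `c * mean(SI_MV) + k * SD(SI_MV)` (defaults
   `c = 1`, `k = 0`), or an image-intensity-ratio (IIR) threshold,
   `SI / mean(SI_bloodpool) > τ` with the conventional `τ = 1.2`
   (fibrosis) and `τ = 1.32` (dense scar). Overlap is the voxelwise AND of
   fibrotic and EAT-adjacent. By construction overlap ⊆ fibrosis and
   overlap ⊆ adjacency, so `overlap% ≤ min(fibrosis%, EAT-adjacent%)` on
   every case.
5. **Cohort statistics.** Per metric: one-way ANOVA when Shapiro-Wilk
   (α = 0.05) does not reject normality, otherwise Kruskal-Wallis with an
   independent-samples median test alongside; Wilcoxon signed-rank for the
   paired overlap-vs-fibrosis comparison; a proportional-odds
   cumulative-logit model of AF stage on single predictors (odds ratio
   with Wald 95% CI); and a logistic regression of the LVEF median split.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| ray depth | 6 | mm | the adjacency definition itself; fixed by the method |
| ray step | 0.5 | mm | ≤ half the finest spacing (1.25 mm in-plane); validated against a 0.05 mm exhaustive scan (≥ 99% voxel agreement) |
| mesh pre-smoothing | 1.25 | mm (σ) | see "Numerical choices" |
| MV threshold `c`, `k` | 1, 0 | — | the valve-SI rule is not standardised; threshold = MV mean SI, both knobs exposed |
| IIR thresholds | 1.2, 1.32 | — | conventional fibrosis / dense-scar cutoffs in the LA-LGE literature |
| BSA formula | Mosteller | — | common clinical default; Du Bois available |
| grid | 128×128×56 at 1.25×1.25×2.5 | mm | the reference transverse acquisition footprint at desk scale |

Design choices that were genuinely open, and how they were fixed:

* **Ray datum.** "6 mm out from the LA" does not pin where the ray
  starts; the wall-voxel center is the only per-voxel datum that is
  well defined for an intramural tracing, so depth is measured from it.
  Deep wall voxels under a thick wall plus a large EAT gap can then sit
  more than 6 mm from EAT and legitimately fail to flag — this is the
  6 mm rule operating, not an artifact.
* **Nearest-vertex search over the full two-sheet mesh**, not only the
  epicardial sheet: the method description does not distinguish sheets,
  and the orientation step makes endocardial normals point outward, so
  the inherited directions are consistent either way.
* **Mask lookup along the ray is nearest-neighbor**, matching the binary
  character of the masks; trilinear interpolation of a binary mask would
  manufacture intermediate values the segmentation never asserted.
* **Absolute areas** are `relative% / 100 ×` the mesh-derived single-sided
  wall area, making the two reported representations exactly consistent
  (and testable) rather than independently estimated.
* **LA volume** sums outlined area over transversal slices and includes
  the wall with the cavity (switchable via the `la_cavity` mask), since
  the tracing convention is not stated more precisely.
* **Ordinal regression** uses the three AF groups by default (the staging
  question), with `include_non_af = TRUE` available.
* **Median split**: the subject at the median LVEF goes to the lower
  class; the "above/below" wording does not resolve ties, and a fixed
  rule keeps runs reproducible.

## Numerical choices

**Mesh smoothing.** The raw midpoint isosurface of a *binary* mask is a
staircase; its area overestimates a curved surface systematically (~9% for
a 30 mm digital sphere at 1 mm spacing). A light Gaussian pre-smooth of
the binary field before extraction (σ = 1.25 mm, converted per axis to
voxels) removes nearly all of this bias (< 0.5% error on the same sphere)
while moving vertices by well under a voxel. σ is configurable and 0
disables smoothing; σ much above half the wall thickness would start to
erode thin shells, which is why the default sits at one in-plane voxel.

**Isosurface extraction** is marching tetrahedra (six tetrahedra per grid
cell sharing the main diagonal) with vertices de-duplicated on lattice
edges, so meshes from watertight masks are closed and consistently wound;
triangle winding is fixed against the local inside/outside split, and
degenerate zero-area triangles (iso exactly at a node) are dropped.

**Distance transform** for normal orientation is the exact separable
squared-parabola envelope with anisotropic spacing; its gradient is
sampled trilinearly at vertices with step half the finest spacing.
Vertices with a vanishing gradient (exactly equidistant ridges) fall back
to the direction from the blood-pool centroid.

**Ties and determinism.** Nearest-vertex ties resolve to the lowest
vertex id; fibrosis quota placement orders by (distance to nearest patch
center, voxel linear index); every stochastic step draws from one seeded
generator. Identical configuration and seed reproduce outputs bit for bit.

**Degenerate inputs** (empty EAT, zero fibrosis fraction) run through the
whole chain and yield zero-valued metrics rather than errors; empty wall
or blood-pool masks are rejected at validation with named violations.

## What the synthetic generator emulates — and what it does not

Patient data behind this kind of analysis cannot be shared, so the
package ships a phantom generator that stands in for it. A phantom is an
ellipsoidal wall shell (cavity = blood pool) with:

* exterior **cap-shaped EAT deposits** at a configurable radial gap, whose
  target share of the wall solid angle (`eat_coverage`) is the designed
  EAT-adjacent fraction — for a spherical shell with a polar cap of
  half-angle 60° the analytic value is `(1 − cos 60°)/2 = 0.25`, which the
  full ray-casting chain must recover;
* **quota-exact fibrotic patches** grown around seeded centers, so the
  designed fibrotic fraction is known to one voxel;
* a **colocalization dial** in [−1, 1]: 0 places fibrosis independently of
  EAT (overlap ≈ product of the two fractions), 1 centers every patch
  under a deposit, −1 avoids deposits;
* Gaussian per-voxel SI noise around per-tissue means, with a separate
  mitral-valve ROI mean so the MV threshold is exercised independently.

The default cohort (9/18/10/14 subjects) encodes the study conditions the
statistics stage assumes: LA volume and EAT coverage rising from
paroxysmal to permanent AF (LA volume targets 113/124/159/188 mL, EAT
coverage 0.10/0.10/0.18/0.25), fibrosis fraction flat (~7–9%),
colocalization flat at 0, and LVEF means 52/60/52/48% — so group tests
should detect the EAT and volume trends, and the overlap stays small and
mechanically tied to adjacency.

The phantom deliberately does **not** model: pulmonary-vein antra, the
appendage, or any realistic LA shape; partial-volume and motion effects;
bias fields (an option exists but is off by default — thresholding is
exercised by additive noise alone); or spatially correlated noise. Passing
tests therefore certify the *geometry and logic* of the measurement chain
and the calibration of the statistics on idealised anatomy; they do not
certify segmentation quality or threshold transferability on real scans,
where wall tracing variability dominates.

## Problem sizes used in the shipped checks

Unit tests run on small shells (24³–84³ voxels, 10³–10⁴ wall voxels);
nearest-vertex assignment is verified against an exhaustive all-pairs scan
on shells below 5 000 wall voxels; the statistical calibration uses 1 000
null cohorts at the 9/18/10/14 group sizes plus 400 parameter-recovery
replicates at the cohort scale (n = 42 AF subjects); the end-to-end
determinism check regenerates the full 51-subject default cohort twice.
These sizes were chosen so that each property is measured at the scale the
method actually targets while a complete run stays in the minutes range on
one core.

## Known limitations

* The valve-SI threshold family is configurable but its literature
  variants are not enumerated; `c` and `k` must be set by the user who
  wants a specific published rule.
* Oblique NIfTI orientations are rejected rather than resampled.
* The two isosurface sheets are not labelled endo/epi, so per-sheet
  analyses (e.g. epicardial-only nearest vertex) require the configurable
  search switch rather than a sheet mask.
* The proportional-odds model is fitted per predictor (as in the target
  analysis); no multivariable adjustment is provided.

## A worked example

```{r, eval = FALSE}
library(laoverlap)

# one phantom case with known truth
ph <- generate_la_phantom(phantom_config(seed = 1))
res <- run_case(ph, covariates = list(height_cm = 178, weight_kg = 84,
                                      lvef_pct = 57))
res$record

# the full default synthetic cohort and statistics report
analysis <- la_demo(seed = 1, outdir = "demo_out")
summary(analysis)
```
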