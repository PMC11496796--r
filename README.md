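# laoverlap

Quantifies the **spatial overlap between left atrial (LA) epicardial
adipose tissue (EAT) and LA wall fibrosis** from co-registered 3D
water/fat-separated LGE-MRI segmentations, and runs the cohort statistics
that relate those metrics to the clinical stage of atrial fibrillation
(AF: non-AF < paroxysmal < persistent < permanent).

The package is aimed at cardiac-imaging researchers who have (or want to
simulate) an intramural LA wall segmentation, a blood-pool mask and an EAT
mask on one axis-aligned grid, and need reproducible per-subject overlap
metrics plus the group-level analysis.

## Method

For wall voxel $v$ with water signal intensity $S(v)$:

* **EAT adjacency** — a triangulated wall surface is extracted from the
  binary wall mask; each wall voxel inherits the outward unit normal
  $\hat n_v$ of its closest mesh vertex, and is *EAT-adjacent* iff the ray
  $c_v + t\,\hat n_v$ meets the EAT mask for some $t \le 6$ mm (sampled
  every 0.5 mm; samples inside the wall are skipped).
* **Fibrosis** — either the patient-specific mitral-valve threshold
  $S(v) > c\cdot\overline{S}_{MV} + k\cdot\mathrm{SD}(S_{MV})$ (defaults
  $c=1$, $k=0$), or the image intensity ratio
  $\mathrm{IIR}(v) = S(v)/\overline{S}_{blood} > \tau$ with
  $\tau \in \{1.2, 1.32\}$.
* **Overlap** — fibrotic **and** EAT-adjacent; reported as % of the wall
  and as cm² (fraction × single-sided mesh area), so
  $\text{overlap} \le \min(\text{fibrosis}, \text{EAT-adjacent})$ holds on
  every case by construction.
* **Per-subject metrics** — LA volume (transversal slice-area summation),
  EAT volume, EAT/fibrosis/overlap areas, and BSA-indexed variants
  (Mosteller $\sqrt{hw/3600}$).
* **Statistics** — ANOVA or Kruskal-Wallis (+ independent-samples median
  test) per metric across the four groups, Wilcoxon signed-rank for
  overlap vs total fibrosis, proportional-odds ordinal regression of AF
  stage (OR with Wald 95% CI), and logistic regression against the LVEF
  median split.

Because patient data of this kind cannot be shared, the package includes a
fully deterministic **synthetic LA phantom and cohort generator** with
known ground truth (ellipsoidal wall shell, cap-shaped exterior EAT
deposits, quota-exact fibrotic patches, a colocalization dial); see the
vignette `vignettes/la-eat-fibrosis-overlap.Rmd` for what it does and does
not emulate.

## Worked example

```r
library(laoverlap)

ph  <- generate_la_phantom(phantom_config(seed = 1))   # 128x128x56 phantom
res <- run_case(ph, covariates = list(height_cm = 178, weight_kg = 84,
                                      lvef_pct = 57))
res$record
```

```
<subject_record> case [NA]
  LA volume 183.8 mL | EAT 8.3 mL | wall 143.7 cm^2 | EAT-adjacent 13.7%
  [mvsi] fibrosis 8.01% (11.50 cm^2), overlap 1.67% (2.39 cm^2)
  [iir12] fibrosis 8.00% (11.49 cm^2), overlap 1.67% (2.39 cm^2)
  [iir132] fibrosis 8.00% (11.49 cm^2), overlap 1.67% (2.39 cm^2)
```

The designed fibrosis fraction (8%) is recovered to one voxel by all
three threshold methods (the phantom's tissue means are well separated,
and the small per-voxel noise barely moves the MV-threshold count), the
EAT cap coverage appears as the EAT-adjacent percentage, and the overlap
is of the order of the product of the two fractions because the phantom
places fibrosis independently of EAT. A whole synthetic cohort plus the
statistics report:

```r
analysis <- la_demo(seed = 1, outdir = "demo_out")
summary(analysis)
```

which prints the group-comparison table (EAT and LA-volume trends
significant, fibrosis flat), the paired Wilcoxon result (overlap smaller
than fibrosis, p < 1e-9), and the regression tables. A thin CLI wrapper
with `simulate` / `analyze-case` / `analyze-cohort` / `demo` subcommands
is installed at `inst/cli/laoverlap.R`.

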