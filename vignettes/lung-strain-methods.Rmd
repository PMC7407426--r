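---
title: "Regional lung strain from paired CT: models, phantoms and tests"
author: "lungstrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional lung strain from paired CT: models, phantoms and tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Injured lungs deform heterogeneously. Whole-lung ("global") strain — tidal
volume over end-expiratory lung volume — can look safe while individual
regions are overstretched, and regional overdistension is a candidate
mechanism for the progression of ventilation-induced and patient
self-inflicted lung injury. This package implements an image-based
biomechanical analysis that quantifies *regional* volumetric strain from
paired end-expiration (EE) / end-inspiration (EI) CT volumes acquired at two
time points (T1, T3) in two experimental groups (spontaneously breathing,
SB, and low-tidal-volume mechanically ventilated, MV), and asks whether
regional strain and its heterogeneity progress over time.

The pipeline is: Hounsfield-unit aeration compartments → aerated-lung masks
→ EE↔EI mask registration → tetrahedral mesh of the aerated lung at EI →
per-tetrahedron volumetric strain → 10 × 10 apical–basal (AB) ×
dorsal–ventral (DV) grid of equal-volume regions of interest (ROIs) →
per-ROI indices and nonparametric tests.

## Models and conventions

**Aeration compartments.** Lung voxels are classified by HU into
hyper-aerated `[-1000, -900)`, normally aerated `[-900, -500)`, poorly
aerated `[-500, -100)` and non-aerated `[-100, +100]` compartments. These
are the standard quantitative-CT ranges; they are configurable
(`aeration_thresholds()`) because different scanners and calibrations shift
them. Intervals are half-open and lower-closed so every voxel lands in
exactly one compartment; out-of-range voxels are clamped to the nearest
compartment and counted in a QC report. The *aerated* mask is the union of
the poorly/normally/hyper-aerated compartments: volumetric strain can only
be measured where there is gas to displace, so collapsed tissue is excluded
from the mesh by construction.

**Global metrics.** From the aerated masks, `EELV` and `EILV` are voxel
counts times the voxel volume, normalised per kg body mass;
`Vt = EILV − EELV`, global strain `= Vt/EELV` (reported in %), and
`Vmin = RR × Vt`.

**Registration.** The displacement field is estimated *from the two aerated
masks*, with the EI mask fixed and the EE mask moving, and the backward-map
convention `x_EE = x_EI + u(x_EI)`: the mesh lives at EI, and each node is
pushed to its reference (EE) position. Binary masks give vanishing
sum-of-squared-difference gradients, so both masks are converted to exact
signed Euclidean distance transforms (negative inside). A cubic B-spline
free-form deformation is fitted by minimising the SSD between the fixed SDT
and the warped moving SDT *over a narrow band (±3 voxels) around the fixed
boundary*, plus a bending-energy penalty on the control lattice. The narrow
band matters: away from the boundary, equal distance values are not material
correspondences (iso-distance matching of a small and a large sphere would
compress the interior), so interior data would bias the field. With
boundary-band data only, the interior follows from the smoothness penalty,
whose minimiser reproduces affine deformations exactly — the right prior for
the smooth, low-frequency deformations of a breathing lung. Optimisation is
multiresolution (3 levels, control spacing 4 voxels at the finest level,
exact B-spline subdivision between levels) with a limited-memory BFGS and
Armijo backtracking, so the recorded energy trace is non-increasing by
construction. The Jacobian of the recovered map is checked for positivity
over the eroded fixed mask; a folded field is an error, and non-convergence
within the iteration cap returns the best iterate with a warning.
Externally computed dense fields in the same 4D-NIfTI layout can be injected
instead (`read_displacement_field()`), which is also how the phantom ground
truth enters in validation runs.

**Mesh and strain.** Each aerated EI voxel is split into 6 tetrahedra by the
Kuhn/Freudenthal decomposition along a globally consistent main diagonal:
the split is parity-free, conforms across voxel faces, and partitions the
mask volume exactly (the suite asserts `sum(V_tet) == EILV_raw` to 1e-9
relative). Per tet, with edge matrices `E_EI` and `E_EE` from node 0, the
deformation gradient is `F = E_EI E_EE^{-1}` and the volumetric strain is
`ε = J − 1` with `J = det F = V_EI / V_EE`; inflation gives ε > 0. No
smoothing is applied to per-tet strains. Rigid motions leave ε unchanged
(asserted to 1e-10), and the determinant-of-F and volume-ratio computations
agree to 1e-12.

**ROI grid and indices.** Ten AB slabs and ten DV slabs of approximately
equal tet volume are intersected into 100 ROIs; tets are binned by centroid
with half-open slabs; a cell with no tets is void (no minimum-volume
cutoff). Boundaries are placed between *distinct* centroid coordinates,
since tets sharing a coordinate are an atomic block no boundary can split.
Per occupied cell the strain mean and SD are volume-weighted
(`w = V_EI` per tet; population SD). The two indices are

- `SPI = (1 + mean_T3) / (1 + mean_T1)` — strain progression; 1 means no
  evolution, > 1 amplification;
- `SHI = (1 + SD) / (1 + mean)` — strain heterogeneity.

SHI is described in the source literature as a coefficient of variation of
the strain distribution expressed on the relative-volume `(1 + ε)` scale;
note the printed formula is `(1+SD)/(1+mean)`, not `SD/(1+mean)` — the
printed form is implemented verbatim. ROI correspondence across time uses
positional cell indices (cell (i,j) at T1 ↔ cell (i,j) at T3); the AB/DV
axes are the image header axes.

**Statistics.** Three per-ROI families, each at α = 0.05 on cells occupied
for every subject at both times:

1. *strain*: Wilcoxon signed-rank on subject-level ROI means, T3 vs T1. The
   null distribution is computed by full enumeration of all 2^n sign
   assignments (n ≤ 25; mid-ranks for ties, zero differences dropped), so
   p-values are exact at the study's n = 5.
2. *SPI vs 1*: by default the one-sample exact signed-rank on `SPI − 1`; a
   two-sample rank test against a constant is degenerate, but a
   Mann–Whitney-vs-constant mode (`spi_mode = "utest"`) is provided, with U
   counted directly (ties 1/2) and a tie-corrected normal approximation.
3. *SHI*: the Feltz–Miller asymptotic test for equality of coefficients of
   variation, applied to the per-tet `(1 + ε)` samples pooled across the
   group's subjects within the cell (the test needs within-ROI
   distributions; pooling uses exact moment combination, not resampling).
   With CVs `c_j = s_j/x̄_j`, weights `m_j = n_j − 1` and pooled
   `c̄ = Σm_j c_j / Σm_j`, the statistic
   `D = Σ m_j (c_j − c̄)² / (c̄²(0.5 + c̄²))` is referred to χ² with k − 1
   df. A cell is flagged only when p < α *and* the pooled CV increased.

Sidedness defaults to one-sided ("greater") for the progression hypotheses:
with n = 5 pairs the exact two-sided signed-rank floor is 2/32 = 0.0625, so
two-sided per-ROI calls at p < 0.05 are arithmetically impossible at this
sample size; both modes are exposed. No multiple-testing correction is
applied across the 100 cells by default (per-ROI maps are reported at a
nominal α, as is conventional for these figures); a Benjamini–Hochberg
option (`p_adjust = "BH"`) is available.

## The synthetic cohort

No public imaging accession accompanies the motivating experiment, so
validation runs on phantoms with *analytically known* deformation.

**Geometry.** The lung is a superellipsoid (default exponent 2) with an
oblique DV centreline: the centre of the DV cross-section shifts ventrally
by `dv_shear` (default 0.6 mm/mm) along the AB axis — apex dorsal, base
ventral, like a real lung. Obliquity is what makes corner cells of the
equal-volume ROI grid void (a plain ellipsoid leaves all 100 cells occupied
because equal-volume slabs adapt to any convex body); the default geometry
gives ~88–96 occupied cells. Default extent is 96³ voxels of 100 μm.

**Aeration.** Lung voxels are ranked by ventral-ness and labelled so the
compartment fractions hit their targets to within a voxel; collapse is
therefore ventral-anchored and *nested* over time (the T1 non-aerated region
is a subset of the T3 one). SB presets move the non-aerated fraction from
13.3% (T1) to 37.5% (T3); MV keeps (13%, 16%, 66%, 5%) at both times.
Compartment HU means default to (0, −300, −700, −950) — the centres of the
four threshold ranges, with non-aerated tissue near water — and additive
Gaussian noise with SD 50 HU. With these distances between means and
boundaries, threshold classification recovers the generated fractions to
within 0.02 at SD 50.

**Deformation.** EE → EI is a separable monotone stretch about the lung
centre: a constant factor along DV and factors along AB/LR that grade
linearly with the DV coordinate (more stretch ventrally). The deformation
gradient is triangular, so `J` is the product of the three effective factors
— a closed form evaluated anywhere, with an exact closed-form inverse. The
dense ground-truth field sampled on the EI grid is exact for affine
profiles under trilinear interpolation, which is what makes the
truth-injection recovery test exact to roundoff. Stretch presets are
calibrated to the global-strain scale of the motivating experiment as
measured on aerated masks (SB ~23% at T1 amplifying to ~31–32% at T3 with a
doubled ventral gradient; MV ~20% at both times): base factors 1.051/1.072
(SB T1/T3, gradients 0.06/0.12) and 1.048 (MV, gradient 0.04). Regional
ground-truth strains span roughly 0.15–0.45. Per-subject variability
(semi-axes ±5%, a shared stretch multiplier, collapse-fraction offsets, body
mass, respiratory rate) flows from one master seed through named
sub-streams, so cohorts are bit-reproducible. Because the subject's stretch
multiplier is shared between T1 and T3, the SB amplification holds at every
material point of every subject, and the MV ground truth is *identical* at
both times — the cohort has a designed positive and a designed null.

**What the phantom does not emulate.** Airway trees, cardiac motion, gating
artifacts, scanner-specific noise and reconstruction filters, pleural
mechanics, and anatomically realistic lobar shapes. Passing the phantom
suite shows the *computational* pipeline is correct and calibrated (strain
recovery, conservation, exactness of tests, designed contrasts); it does not
certify segmentation or registration performance on real micro-CT, where
mask quality and non-smooth deformation around atelectasis are the hard
parts.

## Numerical choices and accuracy

- **SDT**: exact Euclidean distance via the Felzenszwalb–Huttenlocher
  3-pass algorithm, with a half-voxel offset so the zero level set sits on
  the mask boundary.
- **Mask cleanup**: threshold classification of noisy CT leaves speckle at
  compartment interfaces; before distance transforms and meshing, the
  aerated masks pass a 3×3×3 majority filter and keep their largest
  6-connected component.
- **Registration accuracy**: on the 128³ isotropic-stretch phantom
  (a = 1.1, true strain 0.331), the interior volume-weighted mean strain is
  recovered within ~3%; per-tet values carry ~±10% local error (96% of tets
  within 10%). The regional analysis is built on volume-weighted ROI means,
  which is where the accuracy lives; per-tet maps are for visualisation.
- **Erosion margin**: recovery is evaluated on the mask eroded by 2 voxels,
  keeping one-sided boundary differences out of the Jacobian check.
- **Degenerate inputs** are first-class: empty masks, all-collapsed lungs,
  single-slab DV distributions, all-zero difference vectors, void cells and
  folded fields all have defined, tested behaviour (error, warning + p = 1,
  or flags, as appropriate).

## Problem sizes

The shipped analysis and the test suite use: 96³ phantoms (5 subjects/group,
20 registrations, ~2.5 min end to end), 128³ for the strain-recovery
benchmark (~25 s), 10⁴ Monte-Carlo replicates for the Feltz–Miller size
check, and 32³–64³ fixtures in the unit tests. The Monte-Carlo size check of the
Feltz–Miller test uses lognormal null populations with CV 0.10 — the scale
of the `(1 + ε)` samples the pipeline feeds it — where the asymptotic test
holds its nominal size (≈ 0.052 at n = 50); for strongly skewed populations
(CV ≈ 0.3) the same test is measurably liberal (size ≈ 0.06–0.067), which
is worth knowing before applying it to high-CV data. These sizes give stable
group-level statistics while keeping a full run on a laptop-class single
core in minutes; the pipeline itself is resolution-agnostic.

## Known limitations

- The HU compartment boundaries in the motivating experiment are not
  printed; the defaults here are the standard ranges and are flagged as
  assumptions.
- SDT-based mask registration carries no intensity information; it cannot
  recover deformation components tangential to the boundary, and its
  interior is regularisation-driven. For the smooth stretch fields of this
  analysis that is adequate (and measured); for sliding or vortical motion
  it would not be.
- The Feltz–Miller family pools tets across subjects within a cell, making
  its effective n very large; with registration noise this yields more
  nominal flags than the subject-level families, and its MV false-positive
  rate is above α. Flags are therefore required to co-occur with a CV
  increase, and the SB-vs-MV *contrast* is the meaningful readout.
- A two-sample Mann–Whitney against the constant 1.0 is degenerate; the
  default SPI test is the one-sample signed-rank, with the U-mode kept for
  fidelity to the original wording.
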