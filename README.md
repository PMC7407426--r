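# lungstrain

Regional volumetric lung strain from paired end-expiration/end-inspiration
CT, for quantitative-imaging and respiratory-mechanics researchers studying
how lung deformation evolves in injured lungs (ventilator-induced and
patient self-inflicted injury).

Whole-lung ("global") strain — tidal volume over end-expiratory lung volume,
`Vt/EELV` — can look safe while individual regions are overstretched. This
package computes strain *regionally*:

1. **Aeration compartments.** Lung voxels are classified by Hounsfield units
   into hyper `[-1000,-900)`, normal `[-900,-500)`, poor `[-500,-100)` and
   non-aerated `[-100,+100]` compartments; the aerated mask (poor ∪ normal ∪
   hyper) defines where strain is measurable.
2. **Registration.** The EE and EI aerated masks are registered with a cubic
   B-spline free-form deformation fitted on their signed distance
   transforms (narrow-band SSD + bending energy, multiresolution L-BFGS),
   giving the backward map `x_EE = x_EI + u(x_EI)`.
3. **Mesh strain.** The aerated lung at EI is split into tetrahedra (6-tet
   Kuhn decomposition, volume-exact); per tet, `F = E_EI E_EE⁻¹`,
   `J = det F = V_EI/V_EE`, volumetric strain `ε = J − 1` (inflation > 0).
4. **ROI grid and indices.** Ten apical–basal × ten dorsal–ventral slabs of
   equal volume intersect into 100 ROIs (void cells allowed); per occupied
   cell the volume-weighted strain mean/SD, the strain progression index
   `SPI = (1 + mean_T3)/(1 + mean_T1)` and the strain heterogeneity index
   `SHI = (1 + SD)/(1 + mean)`.
5. **Statistics.** Per-ROI exact Wilcoxon signed-rank (full 2^n
   enumeration) for T1-vs-T3 strain, an SPI-vs-1 location test, and the
   Feltz–Miller χ² test for equality of coefficients of variation for SHI
   progression.

Because no public imaging accompanies the motivating experiment, the package
ships a **synthetic phantom cohort** generator: oblique superellipsoid lungs
with four-compartment aeration, ventral-anchored progressive collapse, and a
separable monotone stretch whose Jacobian has a closed form — an exact
oracle for every downstream stage. See the methods vignette
(`vignettes/lung-strain-methods.Rmd`) for models, parameters and
limitations.

## Worked example

Generate the default cohort (5 subjects per group, 96³ voxels of 100 μm)
and run the full analysis (~3 min on one core):

```r
library(lungstrain)
coh <- generate_cohort(cohort_config(), seed = 42)
res <- run_cohort(coh, pipeline_config())
for (g in names(res$maps)) {
  mp <- res$maps[[g]]
  cat(sprintf("%s: testable=%d strain=%.1f%% spi=%.1f%% shi=%.1f%%\n",
              g, mp$n_testable, mp$strain$pct_significant,
              mp$spi$pct_significant, mp$shi$pct_significant))
}
```

```
SB: testable=88 strain=100.0% spi=100.0% shi=85.2%
MV: testable=89 strain=4.5% spi=4.5% shi=23.6%
```

Reading: in the spontaneously breathing group every testable ROI shows a
significant strain increase and SPI significantly above 1 (designed
amplification, recovered by the pipeline from the images alone), while the
mechanically ventilated group — whose ground-truth deformation is identical
at both times — flags ≈ α of cells; heterogeneity progression concentrates
in SB. Group physiology follows the designed scale:

```r
aggregate(global_strain_pct ~ group + time, data = res$metrics,
          function(v) round(c(mean = mean(v), sem = sd(v)/sqrt(5)), 1))
```

```
  group time global_strain_pct.mean global_strain_pct.sem
1    MV   T1                   20.1                   0.6
2    SB   T1                   23.0                   0.8
3    MV   T3                   20.1                   0.6
4    SB   T3                   31.1                   0.8
```

and the non-aerated compartment grows from ~13% to ~37% of the lung in SB
only. Per-subject artifacts (aeration maps, displacement fields, VTU strain
meshes, ROI tables, significance maps) are written when an output directory
is passed.

The same analysis is organised as numbered drivers under `analysis/`
(`01_simulate_cohort.R` … `05_group_stats.R`), each a thin script over the
package functions that writes its tables under `results/`.

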