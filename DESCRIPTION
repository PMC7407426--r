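Package: lungstrain
Title: Regional Volumetric Lung Strain from Paired Expiration/Inspiration CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based biomechanical analysis of regional lung strain from
    paired end-expiration/end-inspiration CT volumes. Classifies lung voxels
    into Hounsfield-unit aeration compartments, registers the aerated-lung
    masks with a cubic B-spline free-form deformation of signed distance
    transforms, builds a tetrahedral mesh of the aerated lung at
    end-inspiration, computes per-tetrahedron volumetric strain (Jacobian
    determinant minus one), summarises strain over a 10 x 10
    apical-basal by dorsal-ventral grid of equal-volume regions of interest,
    and evaluates strain-progression (SPI) and strain-heterogeneity (SHI)
    indices with exact Wilcoxon signed-rank, Mann-Whitney and Feltz-Miller
    coefficient-of-variation tests. Includes a synthetic phantom cohort
    generator with analytically known deformation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
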