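# Synthetic phantom cohort with analytically known deformation.
#
# The phantom emulates the study design of a lavage-injury micro-CT
# experiment: two groups (spontaneously breathing SB, mechanically ventilated
# MV), imaged at two times (T1, T3), each time at end-expiration (EE) and
# end-inspiration (EI). The lung is a superellipsoid; voxels carry one of
# four aeration labels; EI is the EE anatomy pushed through a separable
# monotone stretch whose Jacobian has a closed form, so every downstream
# strain estimate can be checked against an exact oracle.

COMPARTMENTS <- c("non", "poor", "normal", "hyper")

#' Phantom specification
#'
#' Defines the geometry, aeration composition, imaging model and deformation
#' of one phantom lung at one time point.
#'
#' @param grid_shape Integer vector of 3 voxel counts (AB, DV, LR).
#' @param spacing Isotropic voxel size in mm (default 0.1 mm, i.e. 100 um).
#' @param lung_semiaxes Superellipsoid semi-axes in mm along AB/DV/LR.
#' @param superellipse_exponent Shape exponent (2 = ellipsoid).
#' @param dv_shear Obliquity of the lung: the centre of the DV cross-section
#'   shifts ventrally by `dv_shear` mm per mm along the apical-basal axis
#'   (apex dorsal, base ventral). The oblique geometry leaves the corner
#'   cells of the equal-volume AB x DV ROI grid void, as for a real lung.
#' @param compartment_fractions Named target fractions for the
#'   non/poorly/normally/hyper-aerated compartments; must sum to 1.
#' @param compartment_hu_means Mean HU per compartment. Defaults are the
#'   centres of the standard quantitative-CT ranges: 0 (non-aerated,
#'   collapsed tissue is near water), -300 (poor), -700 (normal),
#'   -950 (hyper).
#' @param hu_noise_sd Additive Gaussian imaging noise, HU.
#' @param background_hu HU of extra-pulmonary soft tissue.
#' @param strain_profile List with `a` (base stretch factors along AB/DV/LR)
#'   and `dv_gradient` (per-axis linear modulation of the stretch along the
#'   dorsal-ventral coordinate; the DV axis itself must have zero gradient so
#'   the Jacobian keeps its closed form). A gradient g grades the stretch
#'   linearly from its base value at the dorsal lung edge to base*(1+g) at
#'   the ventral edge.
#' @param seed Integer seed for the imaging noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         spacing = 0.1,
                         lung_semiaxes = c(3.6, 2.2, 2.6),
                         superellipse_exponent = 2,
                         dv_shear = 0.6,
                         compartment_fractions = c(non = 0.133, poor = 0.17,
                                                   normal = 0.647, hyper = 0.05),
                         compartment_hu_means = c(non = 0, poor = -300,
                                                  normal = -700, hyper = -950),
                         hu_noise_sd = 50,
                         background_hu = 40,
                         strain_profile = list(a = c(1, 1, 1),
                                               dv_gradient = c(0, 0, 0)),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            spacing > 0, length(lung_semiaxes) == 3, all(lung_semiaxes > 0),
            superellipse_exponent > 0, hu_noise_sd >= 0)
  fr <- compartment_fractions[COMPARTMENTS]
  if (anyNA(fr)) stop("compartment_fractions must be named non/poor/normal/hyper")
  if (any(fr < 0)) stop("compartment fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) stop("compartment fractions must sum to 1")
  hu <- compartment_hu_means[COMPARTMENTS]
  if (anyNA(hu)) stop("compartment_hu_means must be named non/poor/normal/hyper")
  if (length(strain_profile$dv_gradient) == 1) {
    strain_profile$dv_gradient <- c(strain_profile$dv_gradient, 0,
                                    strain_profile$dv_gradient)
  }
  stopifnot(length(strain_profile$a) == 3, length(strain_profile$dv_gradient) == 3)
  if (strain_profile$dv_gradient[2] != 0) {
    stop("the DV axis cannot carry a DV gradient (Jacobian would lose its closed form)")
  }
  if (any(strain_profile$a <= 0)) stop("stretch factors must be positive")
  spec <- structure(list(grid_shape = grid_shape, spacing = spacing,
                         lung_semiaxes = lung_semiaxes,
                         superellipse_exponent = superellipse_exponent,
                         dv_shear = dv_shear,
                         compartment_fractions = fr,
                         compartment_hu_means = hu,
                         hu_noise_sd = hu_noise_sd,
                         background_hu = background_hu,
                         strain_profile = strain_profile,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  # positivity of the graded stretch over the whole grid
  jr <- warp_factor_range(spec)
  if (any(jr <= 0)) stop("strain profile yields non-positive Jacobian on the grid")
  spec
}

# lung centre in mm (grid centre)
lung_centre <- function(spec) spec$grid_shape * spec$spacing / 2

# normalised DV coordinate: 0 at the dorsal lung edge, 1 at the ventral edge
dv_t <- function(spec, y) {
  c2 <- lung_centre(spec)[2]
  L2 <- spec$lung_semiaxes[2]
  (y - (c2 - L2)) / (2 * L2)
}

# range of the per-axis effective stretch factors over the full grid
warp_factor_range <- function(spec) {
  a <- spec$strain_profile$a
  g <- spec$strain_profile$dv_gradient
  tr <- dv_t(spec, c(0, spec$grid_shape[2] * spec$spacing))
  out <- numeric(0)
  for (i in 1:3) out <- c(out, a[i] * (1 + g[i] * tr))
  out
}

#' Superellipsoid lung mask
#'
#' Builds the whole-lung mask of a phantom: voxels whose centres satisfy
#' `sum(|p_i - c_i| / L_i)^e <= 1`. The mask must fit inside the grid with at
#' least a 2-voxel margin on every face, which guarantees void corner cells
#' in the downstream apical-basal x dorsal-ventral ROI grid.
#'
#' @param spec A [phantom_spec].
#' @return A [binary_mask].
#' @export
make_lung_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$spacing
  L <- spec$lung_semiaxes
  if (any(L < 2 * h)) stop("degenerate lung semi-axes (< 2 voxels)")
  half_extent <- spec$grid_shape * h / 2
  s <- spec$dv_shear
  reach <- c(L[1], sqrt(L[2]^2 + (s * L[1])^2), L[3])
  if (any(reach + 2 * h > half_extent)) {
    stop("lung semi-axes too large for the grid (need a >= 2 voxel margin)")
  }
  ctr <- lung_centre(spec)
  e <- spec$superellipse_exponent
  cx <- voxel_centers(spec$grid_shape[1], h)
  cy <- voxel_centers(spec$grid_shape[2], h)
  cz <- voxel_centers(spec$grid_shape[3], h)
  ax <- (abs(cx - ctr[1]) / L[1])^e
  az <- (abs(cz - ctr[3]) / L[3])^e
  # oblique DV centreline: cross-section centre shifts ventrally toward the base
  ay <- (abs(outer(cy, ctr[2] + s * (cx - ctr[1]), `-`)) / L[2])^e # [DV, AB]
  r <- array(ax, spec$grid_shape) + array(rep(t(ay), 1), spec$grid_shape) +
    array(rep(az, each = prod(spec$grid_shape[1:2])), spec$grid_shape)
  binary_mask(r <= 1, h)
}

#' Aeration compartment layout of a phantom
#'
#' Assigns each lung voxel one of the four aeration labels so that the label
#' fractions match the spec targets to within one voxel, with collapse
#' anchored ventrally: the most ventral fraction of voxels is non-aerated,
#' followed dorsally by the poorly aerated shell, the normally aerated bulk
#' and a hyper-aerated dorsal cap. Because the ordering is a fixed function
#' of position, growing the non-aerated fraction between time points relabels
#' a ventral-anchored sub-region and nests the earlier collapse inside the
#' later one.
#'
#' @param mask Whole-lung [binary_mask].
#' @param spec A [phantom_spec] (supplies the target fractions).
#' @return Integer 3D array: 0 background, 1 non, 2 poor, 3 normal, 4 hyper.
#' @export
compartment_layout <- function(mask, spec) {
  stopifnot(inherits(mask, "binary_mask"), inherits(spec, "phantom_spec"))
  idx <- which(mask$data)
  n <- length(idx)
  if (n == 0) stop("empty lung mask")
  dims <- dim(mask$data)
  ai <- arrayInd(idx, dims)
  # ventral-ness score with deterministic tie-breaks
  ord <- order(-ai[, 2], ai[, 1], ai[, 3])
  fr <- spec$compartment_fractions
  counts <- diff(round(cumsum(c(0, fr)) * n))
  labels <- rep.int(1:4, counts)
  length(labels) <- n # guard against rounding drift
  labels[is.na(labels)] <- 4L
  layout <- array(0L, dims)
  layout[idx[ord]] <- labels
  layout
}

#' Simulate a CT image from a compartment layout
#'
#' Forward imaging model: lung voxels draw HU from a Gaussian centred on
#' their compartment mean; background voxels are set to a soft-tissue
#' constant plus the same noise. Reproducible under a fixed seed.
#'
#' @param layout Integer label array from [compartment_layout()] (0 background,
#'   1 non, 2 poor, 3 normal, 4 hyper).
#' @param spec A [phantom_spec].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return A [ct_image].
#' @export
make_ct_from_labels <- function(layout, spec, seed = spec$seed) {
  stopifnot(is.array(layout), length(dim(layout)) == 3)
  labs <- unique(as.vector(layout))
  if (!all(labs %in% 0:4)) stop("unknown compartment label in layout")
  means <- c(spec$background_hu, unname(spec$compartment_hu_means))
  hu <- means[as.vector(layout) + 1L]
  if (spec$hu_noise_sd > 0) {
    set.seed(as.integer(seed))
    hu <- hu + rnorm(length(hu), 0, spec$hu_noise_sd)
  }
  ct_image(array(hu, dim(layout)), spec$spacing)
}

#' Analytic separable stretch with closed-form Jacobian
#'
#' The deformation maps end-expiration (EE) to end-inspiration (EI) by a
#' separable monotone stretch about the lung centre: the DV axis stretches by
#' a constant factor, while the AB and LR factors may grade linearly along
#' the DV coordinate (more stretch ventrally). The deformation gradient is
#' triangular, so the Jacobian is the product of the three effective factors
#' and is known in closed form everywhere.
#'
#' @param spec A [phantom_spec]; uses its `strain_profile`.
#' @return An object of class `ground_truth` with closures:
#'   `forward(p)` EE -> EI positions, `backward(p)` EI -> EE,
#'   `displacement(p)` backward displacement on the EI grid (`x_EE - x_EI`),
#'   `jacobian_ee(p)` J at EE material points, `jacobian_ei(p)` J at EI
#'   points. Points are n x 3 matrices in mm.
#' @export
make_separable_warp <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  a <- spec$strain_profile$a
  g <- spec$strain_profile$dv_gradient
  if (any(a <= 0)) stop("stretch factors must be positive")
  ctr <- lung_centre(spec)
  tfun <- function(y) dv_t(spec, y)
  eff <- function(tv) cbind(a[1] * (1 + g[1] * tv), a[2], a[3] * (1 + g[3] * tv))

  forward <- function(p) {
    p <- rbind3(p)
    tv <- tfun(p[, 2])
    ae <- eff(tv)
    sweep_about(p, ctr, ae)
  }
  backward <- function(p) {
    p <- rbind3(p)
    y <- ctr[2] + (p[, 2] - ctr[2]) / a[2]
    tv <- tfun(y)
    ae <- eff(tv)
    out <- p
    out[, 1] <- ctr[1] + (p[, 1] - ctr[1]) / ae[, 1]
    out[, 2] <- y
    out[, 3] <- ctr[3] + (p[, 3] - ctr[3]) / ae[, 3]
    out
  }
  jac_ee <- function(p) {
    p <- rbind3(p)
    tv <- tfun(p[, 2])
    a[1] * (1 + g[1] * tv) * a[2] * a[3] * (1 + g[3] * tv)
  }
  structure(list(
    forward = forward,
    backward = backward,
    displacement = function(p) backward(p) - rbind3(p),
    jacobian_ee = jac_ee,
    jacobian_ei = function(p) jac_ee(backward(p)),
    params = spec$strain_profile
  ), class = "ground_truth")
}

rbind3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  p
}

sweep_about <- function(p, ctr, ae) {
  out <- p
  out[, 1] <- ctr[1] + ae[, 1] * (p[, 1] - ctr[1])
  out[, 2] <- ctr[2] + ae[, 2] * (p[, 2] - ctr[2])
  out[, 3] <- ctr[3] + ae[, 3] * (p[, 3] - ctr[3])
  out
}

#' Dense ground-truth displacement field on the EI grid
#'
#' Samples the analytic backward map of a [make_separable_warp()] ground
#' truth at every voxel centre, producing a [displacement_field] that can be
#' injected into the pipeline in place of the estimated registration.
#'
#' @param gt A `ground_truth` object.
#' @param spec The [phantom_spec] defining the grid.
#' @return A [displacement_field] on the EI grid.
#' @export
ground_truth_field <- function(gt, spec) {
  dims <- spec$grid_shape
  h <- spec$spacing
  cx <- voxel_centers(dims[1], h)
  cy <- voxel_centers(dims[2], h)
  cz <- voxel_centers(dims[3], h)
  pts <- cbind(rep(cx, times = dims[2] * dims[3]),
               rep(rep(cy, each = dims[1]), times = dims[3]),
               rep(cz, each = dims[1] * dims[2]))
  u <- gt$displacement(pts)
  displacement_field(array(u, c(dims, 3)), h,
                     meta = list(source = "analytic ground truth"))
}

# Group/time presets. Stretch factors are calibrated so the volume-averaged
# Jacobian matches the global-strain scale of the study design (SB ~23% at
# T1 amplifying to ~32% at T3 with ventral-dominant grading; MV ~19% at both
# times), and collapse fractions so the non-aerated compartment grows from
# ~13.3% to ~37.5% in SB only.
group_preset <- function(group, time) {
  key <- paste(group, time, sep = ".")
  presets <- list(
    SB.T1 = list(fractions = c(non = 0.133, poor = 0.17, normal = 0.647, hyper = 0.05),
                 a = c(1.051, 1.051, 1.051), g = 0.06),
    SB.T3 = list(fractions = c(non = 0.375, poor = 0.22, normal = 0.375, hyper = 0.03),
                 a = c(1.072, 1.072, 1.072), g = 0.12),
    MV.T1 = list(fractions = c(non = 0.13, poor = 0.16, normal = 0.66, hyper = 0.05),
                 a = c(1.048, 1.048, 1.048), g = 0.04),
    MV.T3 = list(fractions = c(non = 0.13, poor = 0.16, normal = 0.66, hyper = 0.05),
                 a = c(1.048, 1.048, 1.048), g = 0.04)
  )
  p <- presets[[key]]
  if (is.null(p)) stop("unknown group/time preset: ", key)
  p
}

# Per-subject randomisation shared across time points: geometry jitter, a
# stretch multiplier applied to both times (preserving the T3 > T1 ordering
# in SB and exact T1 == T3 equality in MV), a collapse-fraction offset, body
# mass and respiratory rate. Everything flows from one subject seed.
subject_specs <- function(group, subject_seed, grid_shape = c(96L, 96L, 96L),
                          spacing = 0.1, hu_noise_sd = 50) {
  set.seed(as.integer(subject_seed))
  # lung size proportional to the grid extent (default 9.6 mm -> 3.6/2.2/2.6)
  extent <- grid_shape * spacing
  semi <- c(0.375, 0.229, 0.271) * extent * runif(3, 0.95, 1.05)
  stretch_mult <- exp(rnorm(1, 0, 0.006))
  non_offset <- rnorm(1, 0, 0.008)
  poor_offset <- rnorm(1, 0, 0.005)
  body_mass_g <- max(2, rnorm(1, 2.9, 0.2))
  rr <- list(SB = c(T1 = round(rnorm(1, 117, 10)), T3 = round(rnorm(1, 129, 13))),
             MV = c(T1 = 90, T3 = 90))[[group]]

  specs <- lapply(c(T1 = "T1", T3 = "T3"), function(time) {
    p <- group_preset(group, time)
    fr <- p$fractions
    fr["non"] <- max(0.01, fr["non"] + non_offset)
    fr["poor"] <- max(0.01, fr["poor"] + poor_offset)
    fr["normal"] <- 1 - fr["non"] - fr["poor"] - fr["hyper"]
    phantom_spec(grid_shape = grid_shape, spacing = spacing,
                 lung_semiaxes = semi,
                 compartment_fractions = fr,
                 hu_noise_sd = hu_noise_sd,
                 strain_profile = list(a = p$a * stretch_mult,
                                       dv_gradient = c(p$g, 0, p$g)),
                 seed = derive_seed(subject_seed, time))
  })
  list(specs = specs, body_mass_g = body_mass_g, rr_per_min = rr)
}

#' Generate one phantom subject at one time point
#'
#' Builds the EE anatomy from the spec, images it, pushes it through the
#' analytic stretch to get the EI anatomy (imaged with independent noise),
#' and returns both phases together with the ground truth. The non-aerated
#' region carries no strain ground truth downstream because the mesh is
#' built on the aerated mask only.
#'
#' @param group `"SB"` or `"MV"` (spontaneous breathing / mechanical
#'   ventilation presets).
#' @param time `"T1"` or `"T3"`.
#' @param spec A [phantom_spec]; defaults to the group/time preset at 96^3.
#' @param seed Integer seed for the imaging noise streams.
#' @return List with `ee`/`ei` ([ct_image]), `ee_mask`/`ei_mask`
#'   (whole-lung [binary_mask]), `ee_layout`/`ei_layout` (label arrays),
#'   `truth` (`ground_truth`), and `spec`.
#' @export
generate_subject <- function(group = c("SB", "MV"), time = c("T1", "T3"),
                             spec = NULL, seed = 1L) {
  group <- match.arg(group)
  time <- match.arg(time)
  if (is.null(spec)) {
    p <- group_preset(group, time)
    spec <- phantom_spec(compartment_fractions = p$fractions,
                         strain_profile = list(a = p$a, dv_gradient = c(p$g, 0, p$g)),
                         seed = seed)
  }
  ee_mask <- make_lung_mask(spec)
  ee_layout <- compartment_layout(ee_mask, spec)
  ee <- make_ct_from_labels(ee_layout, spec, seed = derive_seed(seed, "ee"))
  truth <- make_separable_warp(spec)

  # EI layout: pull back each EI voxel centre to EE and take the nearest label
  dims <- spec$grid_shape
  h <- spec$spacing
  pts <- cbind(rep(voxel_centers(dims[1], h), times = dims[2] * dims[3]),
               rep(rep(voxel_centers(dims[2], h), each = dims[1]), times = dims[3]),
               rep(voxel_centers(dims[3], h), each = dims[1] * dims[2]))
  src <- truth$backward(pts)
  iv <- pmin(pmax(round(src / h + 0.5), 1), matrix(rep(dims, each = nrow(src)), ncol = 3))
  inside <- src[, 1] >= 0 & src[, 2] >= 0 & src[, 3] >= 0 &
    src[, 1] <= dims[1] * h & src[, 2] <= dims[2] * h & src[, 3] <= dims[3] * h
  lin <- iv[, 1] + dims[1] * (iv[, 2] - 1) + dims[1] * dims[2] * (iv[, 3] - 1)
  ei_lab <- integer(nrow(pts))
  ei_lab[inside] <- as.vector(ee_layout)[lin[inside]]
  ei_layout <- array(ei_lab, dims)
  ei <- make_ct_from_labels(ei_layout, spec, seed = derive_seed(seed, "ei"))

  list(ee = ee, ei = ei,
       ee_mask = binary_mask(ee_layout > 0, h),
       ei_mask = binary_mask(ei_layout > 0, h),
       ee_layout = ee_layout, ei_layout = ei_layout,
       truth = truth, spec = spec, group = group, time = time)
}

#' Cohort configuration
#'
#' @param n_per_group Subjects per group (default 5).
#' @param grid_shape Phantom grid (default 96^3 voxels).
#' @param spacing Voxel size in mm.
#' @param hu_noise_sd Imaging noise, HU.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 5L, grid_shape = c(96L, 96L, 96L),
                          spacing = 0.1, hu_noise_sd = 50) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  structure(list(n_per_group = as.integer(n_per_group),
                 grid_shape = as.integer(grid_shape), spacing = spacing,
                 hu_noise_sd = hu_noise_sd,
                 groups = c("SB", "MV"), times = c("T1", "T3")),
            class = "cohort_config")
}

#' Generate a phantom cohort
#'
#' Generates `n_per_group` subjects for each of the SB and MV groups at both
#' time points. Per-subject seeds derive deterministically from the master
#' seed, so the same `config` + `seed` regenerates the cohort bit for bit.
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed.
#' @param out_dir Optional output directory; when given, CT volumes and
#'   whole-lung masks are written as NIfTI-1 (.nii.gz) plus a manifest CSV.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return List with `subjects` (nested by subject id then time) and
#'   `manifest` (data frame: subject_id, group, time, phase, path,
#'   body_mass_g, rr_per_min).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            out_dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  write <- !is.null(out_dir)
  if (write) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
      stop("output directory exists and is non-empty; pass overwrite = TRUE")
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  subjects <- list()
  rows <- list()
  for (group in config$groups) {
    for (s in seq_len(config$n_per_group)) {
      sid <- sprintf("%s%02d", group, s)
      sseed <- derive_seed(seed, sid)
      sub <- subject_specs(group, sseed, grid_shape = config$grid_shape,
                           spacing = config$spacing,
                           hu_noise_sd = config$hu_noise_sd)
      subjects[[sid]] <- list(group = group, body_mass_g = sub$body_mass_g,
                              rr_per_min = sub$rr_per_min, times = list())
      for (time in config$times) {
        dat <- generate_subject(group, time, spec = sub$specs[[time]],
                                seed = derive_seed(sseed, paste0("img", time)))
        subjects[[sid]]$times[[time]] <- dat
        for (phase in c("EE", "EI")) {
          path <- NA_character_
          if (write) {
            base <- sprintf("%s_%s_%s", sid, time, phase)
            path <- file.path(out_dir, paste0("ct_", base, ".nii.gz"))
            img <- if (phase == "EE") dat$ee else dat$ei
            msk <- if (phase == "EE") dat$ee_mask else dat$ei_mask
            write_nifti_volume(img$data, img$spacing, path)
            write_nifti_volume(msk$data * 1L, msk$spacing,
                               file.path(out_dir, paste0("mask_", base, ".nii.gz")))
          }
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = sid, group = group, time = time, phase = phase,
            path = path, body_mass_g = sub$body_mass_g,
            rr_per_min = unname(sub$rr_per_min[time]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (write) write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  list(subjects = subjects, manifest = manifest, config = config, seed = seed)
}
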