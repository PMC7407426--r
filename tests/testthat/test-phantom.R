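test_that("lung mask matches analytic geometry and respects margins", {
  spec <- sphere_spec(48, r = 2.0)
  m <- make_lung_mask(spec)
  expect_lt(abs(mask_volume(m) - 4 / 3 * pi * 2^3) / (4 / 3 * pi * 2^3), 0.02)

  # no voxels on the boundary faces of the grid, for any spec shape
  for (sp in list(spec, phantom_spec())) {
    mm <- make_lung_mask(sp)$data
    d <- dim(mm)
    expect_false(any(mm[c(1, d[1]), , ]) || any(mm[, c(1, d[2]), ]) ||
                   any(mm[, , c(1, d[3])]))
  }

  # semi-axis larger than the grid is rejected, as are degenerate semi-axes
  expect_error(make_lung_mask(sphere_spec(48, r = 2.5)), "semi-axes too large")
  expect_error(make_lung_mask(sphere_spec(48, r = 0.15)), "degenerate")
})

test_that("compartment layout hits target fractions and nests collapse ventrally", {
  spec <- sphere_spec(40, r = 1.6,
                      compartment_fractions = c(non = 0.13, poor = 0.17,
                                                normal = 0.65, hyper = 0.05))
  m <- make_lung_mask(spec)
  lay <- compartment_layout(m, spec)
  fr <- compartment_fractions(lay)
  expect_lt(max(abs(fr - c(0.13, 0.17, 0.65, 0.05))), 4 / sum(m$data))

  # non-aerated voxels are the most ventral ones
  dv_idx <- arrayInd(which(lay > 0), dim(lay))[, 2]
  labs <- lay[lay > 0]
  expect_gt(min(dv_idx[labs == 1]), max(dv_idx[labs == 4]) - 1)

  # growing the non fraction relabels a superset (nested collapse)
  spec3 <- sphere_spec(40, r = 1.6,
                       compartment_fractions = c(non = 0.37, poor = 0.22,
                                                 normal = 0.38, hyper = 0.03))
  lay3 <- compartment_layout(m, spec3)
  expect_true(all(lay3[lay == 1] == 1))
})

test_that("CT imaging model is exact at zero noise and reproducible", {
  spec <- sphere_spec(24, r = 0.9, compartment_fractions = c(non = 0, poor = 0,
                                                             normal = 1, hyper = 0))
  m <- make_lung_mask(spec)
  lay <- compartment_layout(m, spec)
  ct <- make_ct_from_labels(lay, spec)
  expect_true(all(ct$data[lay == 3] == -700))
  expect_true(all(ct$data[lay == 0] == spec$background_hu))

  spec_n <- sphere_spec(24, r = 0.9)
  spec_n$hu_noise_sd <- 50
  ct1 <- make_ct_from_labels(lay, spec_n, seed = 99)
  ct2 <- make_ct_from_labels(lay, spec_n, seed = 99)
  expect_identical(ct1$data, ct2$data)

  bad <- lay
  bad[5, 5, 5] <- 9L
  expect_error(make_ct_from_labels(bad, spec), "unknown")
})

test_that("separable warp has the closed-form Jacobian", {
  id <- make_separable_warp(sphere_spec(24, r = 0.9))
  p <- matrix(runif(30, 0.8, 1.6), ncol = 3)
  expect_equal(id$jacobian_ee(p), rep(1, 10))
  expect_equal(max(abs(id$displacement(p))), 0)

  iso <- make_separable_warp(sphere_spec(24, r = 0.9,
           strain_profile = list(a = c(1.1, 1.1, 1.1), dv_gradient = c(0, 0, 0))))
  expect_equal(iso$jacobian_ee(p), rep(1.1^3, 10))

  # one axis graded linearly along DV from 1.0 to 1.2, others 1.05:
  # at mid-DV the graded factor is 1.1 and J = 1.05^2 * 1.1
  spec <- sphere_spec(48, r = 2.0,
            strain_profile = list(a = c(1.05, 1.05, 1.0), dv_gradient = c(0, 0, 0.2)))
  gt <- make_separable_warp(spec)
  mid <- lungstrain:::lung_centre(spec)
  expect_equal(gt$jacobian_ee(matrix(mid, ncol = 3)), 1.05^2 * 1.1)

  expect_error(phantom_spec(strain_profile = list(a = c(1, -0.2, 1),
                                                  dv_gradient = c(0, 0, 0))),
               "positive")
  expect_error(phantom_spec(strain_profile = list(a = c(1, 1, 1),
                                                  dv_gradient = c(0, 0.1, 0))),
               "DV axis")
})

test_that("displacement closure is consistent with the analytic Jacobian", {
  spec <- sphere_spec(48, r = 2.0,
            strain_profile = list(a = c(1.06, 1.05, 1.04), dv_gradient = c(0.1, 0, 0.08)))
  gt <- make_separable_warp(spec)
  set.seed(5)
  ctr <- lungstrain:::lung_centre(spec)
  p <- sweep(matrix(runif(3000, -1, 1), ncol = 3) * 1.2, 2, ctr, `+`)
  eps <- 1e-4
  jac_fd <- vapply(seq_len(nrow(p)), function(k) {
    F <- matrix(0, 3, 3)
    for (d in 1:3) {
      hp <- p[k, ]; hm <- p[k, ]
      hp[d] <- hp[d] + eps; hm[d] <- hm[d] - eps
      F[, d] <- (gt$forward(hp) - gt$forward(hm)) / (2 * eps)
    }
    det(F)
  }, 0)
  expect_lt(max(abs(jac_fd - gt$jacobian_ee(p)) / gt$jacobian_ee(p)), 1e-3)

  # backward inverts forward
  fw <- gt$forward(p)
  expect_equal(gt$backward(fw), p, tolerance = 1e-10)
})

test_that("noisy classification recovers generator fractions within 0.02", {
  spec <- sphere_spec(64, r = 2.6,
                      compartment_fractions = c(non = 0.13, poor = 0.17,
                                                normal = 0.65, hyper = 0.05))
  spec$hu_noise_sd <- 50
  m <- make_lung_mask(spec)
  lay <- compartment_layout(m, spec)
  ct <- make_ct_from_labels(lay, spec, seed = 3)
  am <- classify_aeration(ct, m)
  fr <- compartment_fractions(am)
  expect_lt(max(abs(fr - c(0.13, 0.17, 0.65, 0.05))), 0.02)
})

test_that("group presets build subjects with the designed contrasts", {
  # MV: identical ground truth at T1 and T3 by construction
  sub <- lungstrain:::subject_specs("MV", 7, grid_shape = c(40L, 40L, 40L))
  s1 <- sub$specs$T1; s3 <- sub$specs$T3
  expect_identical(s1$strain_profile, s3$strain_profile)
  expect_identical(s1$compartment_fractions, s3$compartment_fractions)

  # SB: ground-truth Jacobian amplifies everywhere in the lung (SPI > 1)
  sb <- lungstrain:::subject_specs("SB", 7, grid_shape = c(40L, 40L, 40L))
  g1 <- make_separable_warp(sb$specs$T1)
  g3 <- make_separable_warp(sb$specs$T3)
  m <- make_lung_mask(sb$specs$T1)
  pts <- lungstrain:::mask_coords(m$data, sb$specs$T1$spacing)
  pts <- pts[seq(1, nrow(pts), by = 17), ]
  expect_true(all(g3$jacobian_ee(pts) > g1$jacobian_ee(pts)))

  # non-aerated fraction grows ventrally between times in SB only
  expect_gt(sb$specs$T3$compartment_fractions["non"],
            sb$specs$T1$compartment_fractions["non"] + 0.15)
})

test_that("cohort generation writes files deterministically", {
  cfg <- cohort_config(n_per_group = 5, grid_shape = c(32L, 32L, 32L))
  dir1 <- file.path(tempdir(), "coh1")
  unlink(dir1, recursive = TRUE)
  coh <- generate_cohort(cfg, seed = 5, out_dir = dir1)
  cts <- list.files(dir1, pattern = "^ct_.*nii\\.gz$")
  expect_length(cts, 40) # 5 subjects x 2 groups x 2 times x 2 phases
  expect_equal(nrow(coh$manifest), 40)

  # same master seed regenerates identical volumes
  dir2 <- file.path(tempdir(), "coh2")
  unlink(dir2, recursive = TRUE)
  generate_cohort(cfg, seed = 5, out_dir = dir2)
  md5 <- function(d) unname(tools::md5sum(file.path(d, sort(list.files(d, pattern = "nii.gz$")))))
  expect_identical(md5(dir1), md5(dir2))

  # refuse to clobber, reject empty cohorts
  expect_error(generate_cohort(cfg, seed = 5, out_dir = dir1), "overwrite")
  expect_error(cohort_config(n_per_group = 0), "n_per_group")
  unlink(c(dir1, dir2), recursive = TRUE)
})
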