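test_that("Kuhn split partitions voxels exactly", {
  h <- 0.5
  m1 <- tetrahedralize_mask(binary_mask(array(TRUE, c(1, 1, 1)), h))
  expect_equal(nrow(m1$tets), 6)
  expect_equal(nrow(m1$nodes), 8)
  met <- lungstrain:::tet_metrics_cpp(m1$nodes, m1$nodes, m1$tets)
  expect_equal(met$v_cur, rep(h^3 / 6, 6))

  m2 <- tetrahedralize_mask(binary_mask(array(TRUE, c(2, 2, 2)), 1))
  expect_equal(nrow(m2$tets), 48)
  expect_equal(nrow(m2$nodes), 27)

  # total mesh volume equals voxel count times voxel volume, exactly
  spec <- sphere_spec(32, r = 1.2)
  mk <- make_lung_mask(spec)
  mesh <- tetrahedralize_mask(mk)
  met <- lungstrain:::tet_metrics_cpp(mesh$nodes, mesh$nodes, mesh$tets)
  expect_lt(abs(sum(met$v_cur) - mask_volume(mk)) / mask_volume(mk), 1e-9)
  expect_true(all(met$v_cur > 0)) # consistent positive orientation

  expect_error(tetrahedralize_mask(binary_mask(array(FALSE, c(3, 3, 3)), 1)),
               "empty")
})

test_that("signed tetrahedron volume behaves like the determinant", {
  p0 <- c(0, 0, 0); p1 <- c(1, 0, 0); p2 <- c(0, 1, 0); p3 <- c(0, 0, 1)
  expect_equal(signed_tet_volume(p0, p1, p2, p3), 1 / 6)
  expect_equal(signed_tet_volume(p0, p1, p2, c(1, 1, 0)), 0) # coplanar
  expect_equal(signed_tet_volume(p0, p2, p1, p3), -1 / 6)    # swap flips sign
})

test_that("mesh warping is exact for constant and linear fields", {
  mk <- binary_mask(array(TRUE, c(4, 4, 4)), 0.5)
  mesh <- tetrahedralize_mask(mk)
  dims <- c(4, 4, 4)

  zero <- displacement_field(array(0, c(dims, 3)), 0.5)
  expect_equal(warp_mesh_to_reference(mesh, zero), mesh$nodes)

  unif <- displacement_field(array(rep(c(0.3, 0, 0), each = 64), c(dims, 3)), 0.5)
  expect_equal(warp_mesh_to_reference(mesh, unif),
               sweep(mesh$nodes, 2, c(0.3, 0, 0), `+`))

  # linear field u = A x reproduced exactly by trilinear interpolation
  A <- matrix(c(0.05, 0.02, 0, 0.01, -0.03, 0, 0, 0.02, 0.04), 3, 3)
  cx <- lungstrain:::voxel_centers(4, 0.5)
  pts <- as.matrix(expand.grid(cx, cx, cx))[, 1:3]
  colnames(pts) <- NULL
  u <- t(A %*% t(pts))
  lin <- displacement_field(array(u, c(dims, 3)), 0.5)
  inner <- mesh$nodes[apply(mesh$nodes, 1, function(p) all(p > 0.2 & p < 1.8)), ]
  got <- sample_displacement(lin, inner)
  expect_equal(got, t(A %*% t(inner)), tolerance = 1e-12)
})

test_that("sample_displacement interpolates and refuses extrapolation", {
  dims <- c(4, 4, 4)
  u <- array(rnorm(prod(dims) * 3), c(dims, 3))
  f <- displacement_field(u, 0.5, meta = list(source = "test"))
  # voxel-centre query returns the stored vector
  expect_equal(as.vector(sample_displacement(f, c(0.75, 1.25, 0.25))),
               u[2, 3, 1, ])
  expect_error(sample_displacement(f, c(-0.2, 1, 1)), "outside")
})

test_that("volumetric strain is exact for identity and uniform dilation", {
  spec <- sphere_spec(32, r = 1.2)
  mesh <- tetrahedralize_mask(make_lung_mask(spec))
  sf0 <- volumetric_strain(mesh, mesh$nodes)
  expect_equal(max(abs(sf0$strain)), 0)

  # EE obtained by shrinking EI isotropically by 1/1.1 -> strain = 0.331
  ctr <- lungstrain:::lung_centre(spec)
  ref <- sweep(sweep(mesh$nodes, 2, ctr) / 1.1, 2, ctr, `+`)
  sf <- volumetric_strain(mesh, ref)
  expect_equal(sf$strain, rep(1.1^3 - 1, nrow(sf)), tolerance = 1e-12)

  # determinant-of-F equals the volume-ratio J
  expect_lt(max(abs(attr(sf, "j_det") - sf$j)), 1e-12)

  # inverted reference configuration is an error naming tets
  bad <- mesh$nodes
  bad[, 1] <- -bad[, 1] # reflection makes every reference tet negative
  expect_error(volumetric_strain(mesh, bad), "non-positive reference")
})

test_that("strain is invariant to rigid motion of both configurations", {
  spec <- sphere_spec(24, r = 0.9)
  mesh <- tetrahedralize_mask(make_lung_mask(spec))
  ctr <- lungstrain:::lung_centre(spec)
  ref <- sweep(sweep(mesh$nodes, 2, ctr) / 1.08, 2, ctr, `+`)
  sf <- volumetric_strain(mesh, ref)

  theta <- 0.4
  R <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  tr <- c(0.7, -0.3, 1.1)
  rot <- function(x) sweep(t(R %*% t(x)), 2, tr, `+`)
  mesh_r <- mesh
  mesh_r$nodes <- rot(mesh$nodes)
  sf_r <- volumetric_strain(mesh_r, rot(ref))
  expect_lt(max(abs(sf_r$strain - sf$strain)), 1e-10)
})

test_that("ground-truth injection recovers the DV-graded strain per band", {
  spec <- sphere_spec(48, r = 1.8,
            strain_profile = list(a = c(1.05, 1.06, 1.04), dv_gradient = c(0.1, 0, 0.1)))
  gt <- make_separable_warp(spec)
  mesh <- tetrahedralize_mask(make_lung_mask(spec))
  sf <- volumetric_strain(mesh, warp_mesh_to_reference(mesh, ground_truth_field(gt, spec)))
  jt <- gt$jacobian_ei(as.matrix(sf[, c("ab", "dv", "lr")]))
  # volume-weighted mean per DV band within 5% of the analytic band mean
  bands <- cut(sf$dv, breaks = quantile(sf$dv, 0:5 / 5), include.lowest = TRUE)
  for (b in levels(bands)) {
    sel <- bands == b
    est <- weighted.mean(sf$strain[sel], sf$v_ei[sel])
    ana <- weighted.mean(jt[sel] - 1, sf$v_ei[sel])
    expect_lt(abs(est - ana) / ana, 0.05)
  }
})
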