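test_that("equal-volume slabs land on the deciles of a uniform box", {
  sf <- box_strain_field(c(20, 20, 4), spacing = 0.5)
  b <- axis_partition(sf, "AB", 10)
  # uniform density: boundaries at deciles of the 10 mm extent, +/- a voxel
  expect_equal(b[2:10], seq(1, 9), tolerance = 0.5)
  # uniform box: slabs are exactly equal (boundaries fall between voxel layers)
  g <- build_roi_grid(sf, b, axis_partition(sf, "DV", 10))
  vol <- tapply(sf$v_ei, g$cell[, "i"], sum)
  expect_lt(max(abs(vol - sum(sf$v_ei) / 10)), 1e-9)

  # distinct centroid coordinates: slabs within one tet volume of total/n
  set.seed(3)
  sfr <- toy_strain_field(ab = runif(500), dv = runif(500),
                          v = runif(500, 0.5, 2), strain = rnorm(500))
  br <- axis_partition(sfr, "AB", 10)
  gr <- build_roi_grid(sfr, br, c(0, 1))
  volr <- tapply(sfr$v_ei, gr$cell[, "i"], sum)
  expect_lt(max(abs(volr - sum(sfr$v_ei) / 10)), max(sfr$v_ei) + 1e-12)
  expect_error(axis_partition(sf, "AB", 1), "at least 2")
})

test_that("degenerate coordinate distributions are flagged", {
  sf <- toy_strain_field(ab = rep(1, 20), dv = runif(20), v = rep(1, 20),
                         strain = runif(20))
  expect_warning(b <- axis_partition(sf, "AB", 10), "degenerate")
  expect_true(attr(b, "degenerate"))
})

test_that("ROI grid occupancy follows the mesh geometry", {
  # axis-aligned box intersects all 100 cells
  sf <- box_strain_field(c(20, 20, 4), spacing = 0.5)
  g <- build_roi_grid(sf, axis_partition(sf, "AB"), axis_partition(sf, "DV"))
  expect_equal(g$n_occupied, 100)

  # oblique lung-shaped phantom leaves corner cells void
  spec <- phantom_spec(grid_shape = c(64L, 64L, 64L), hu_noise_sd = 0,
                       lung_semiaxes = c(2.4, 1.45, 1.75))
  mk <- make_lung_mask(spec)
  lay <- compartment_layout(mk, spec)
  mesh <- tetrahedralize_mask(binary_mask(lay >= 2, spec$spacing))
  sfl <- volumetric_strain(mesh, mesh$nodes)
  ab <- axis_partition(sfl, "AB"); dv <- axis_partition(sfl, "DV")
  gl <- build_roi_grid(sfl, ab, dv)
  expect_lt(gl$n_occupied, 100)
  corners <- c(gl$occupied[1, 1], gl$occupied[1, 10], gl$occupied[10, 10])
  expect_false(all(corners))

  # voxel-level binning oracle agrees on which cells are occupied
  vox <- lungstrain:::mask_coords(lay >= 2, spec$spacing)
  # tets of a voxel stay inside it, so centroid binning == voxel binning
  iv <- findInterval(vox[, 1], ab, all.inside = TRUE)
  jv <- findInterval(vox[, 2], dv, all.inside = TRUE)
  occ_vox <- matrix(FALSE, 10, 10)
  occ_vox[cbind(iv, jv)] <- TRUE
  expect_identical(gl$occupied, occ_vox)

  # moving a boundary below all centroids empties the first row
  b2 <- c(min(sfl$ab) - 2, min(sfl$ab) - 1, ab[3:11])
  g2 <- build_roi_grid(sfl, b2, dv)
  expect_false(any(g2$occupied[1, ]))
})

test_that("volume-weighted ROI statistics match hand and brute-force values", {
  # two tets, volumes 1 and 3, strains 0.1 and 0.3 -> mean 0.25
  sf <- toy_strain_field(ab = c(0.2, 0.2), dv = c(0.5, 0.5), v = c(1, 3),
                         strain = c(0.1, 0.3))
  g <- build_roi_grid(sf, c(0, 1), c(0, 1))
  st <- roi_weighted_stats(sf, g)
  expect_equal(st$mean, 0.25)
  expect_equal(st$sd, sqrt((1 * 0.15^2 + 3 * 0.05^2) / 4))

  # constant strain: mean c, SD 0
  sfc <- toy_strain_field(ab = runif(50), dv = runif(50), v = runif(50),
                          strain = rep(0.2, 50))
  stc <- roi_weighted_stats(sfc, build_roi_grid(sfc, c(0, 1), c(0, 1)))
  expect_equal(stc$mean, 0.2)
  expect_equal(stc$sd, 0)

  # random cells against independent brute-force recomputation
  set.seed(42)
  sfr <- toy_strain_field(ab = runif(400), dv = runif(400),
                          v = runif(400, 0.5, 2), strain = rnorm(400, 0.3, 0.1))
  ab <- axis_partition(sfr, "AB", 4); dv <- axis_partition(sfr, "DV", 4)
  gr <- build_roi_grid(sfr, ab, dv)
  str <- roi_weighted_stats(sfr, gr)
  for (k in sample(which(str$occupied), 5)) {
    sel <- gr$cell[, "i"] == str$i[k] & gr$cell[, "j"] == str$j[k]
    w <- sfr$v_ei[sel]; e <- sfr$strain[sel]
    expect_equal(str$mean[k], sum(w * e) / sum(w))
    expect_equal(str$sd[k], sqrt(sum(w * (e - sum(w * e) / sum(w))^2) / sum(w)))
  }

  # occupied-cell volumes sum to the mesh volume; grand mean is exact
  expect_equal(sum(str$volume, na.rm = TRUE), sum(sfr$v_ei), tolerance = 1e-12)
  grand <- sum(str$volume * str$mean, na.rm = TRUE) / sum(str$volume, na.rm = TRUE)
  expect_equal(grand, weighted.mean(sfr$strain, sfr$v_ei), tolerance = 1e-12)

  # void cells carry NA, not zero
  expect_true(all(is.na(str$mean[!str$occupied])))
})

test_that("SPI and SHI follow the printed formulas", {
  expect_equal(spi(0.2, 0.2), 1)
  expect_equal(spi(0.2, 0.5), 1.5 / 1.2)
  expect_lt(spi(0.3, 0.2), 1)
  expect_error(spi(-1.2, 0.1), "undefined")

  expect_equal(shi(0, 0), 1)
  expect_equal(shi(0.25, 0.10), 1.10 / 1.25)
  expect_equal(shi(0.4, 0.4), 1) # SD == mean -> 1 for any mean
  expect_error(shi(-1.5, 0.1), "undefined")
  expect_error(shi(0.2, -0.1), "negative")

  # shifting all strains by c moves (mean, sd) -> (mean + c, sd) and SHI
  # changes exactly as the formula predicts
  set.seed(1)
  e <- rnorm(200, 0.3, 0.08); w <- runif(200, 0.5, 2); cc <- 0.12
  m0 <- weighted.mean(e, w)
  s0 <- sqrt(sum(w * (e - m0)^2) / sum(w))
  m1 <- weighted.mean(e + cc, w)
  s1 <- sqrt(sum(w * (e + cc - m1)^2) / sum(w))
  expect_equal(m1, m0 + cc)
  expect_equal(s1, s0)
  expect_equal(shi(m1, s1), (1 + s0) / (1 + m0 + cc))
})

test_that("percentage of significant ROIs uses half-up rounding", {
  expect_equal(percentage_significant(38, 87), 43.7)
  expect_equal(percentage_significant(1, 84), 1.2)
  expect_equal(percentage_significant(0, 100), 0)
  expect_equal(percentage_significant(91, 91), 100)
  expect_equal(percentage_significant(24, 91), 26.4)
  expect_equal(percentage_significant(rep(c(TRUE, FALSE), c(38, 49)), 87), 43.7)
  expect_error(percentage_significant(3, 0), "occupied")
})
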