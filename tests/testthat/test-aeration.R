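make_uniform_ct <- function(hu, dims = c(6, 6, 6), spacing = 0.1) {
  ct_image(array(hu, dims), spacing)
}

test_that("classification respects the half-open HU intervals", {
  mask <- binary_mask(array(TRUE, c(6, 6, 6)), 0.1)
  lab_of <- function(hu) {
    am <- classify_aeration(make_uniform_ct(hu), mask)
    unique(as.vector(am$labels))
  }
  expect_equal(lab_of(-950), 4L) # hyper
  expect_equal(lab_of(-900), 3L) # boundary goes to the upper compartment
  expect_equal(lab_of(-700), 3L)
  expect_equal(lab_of(-300), 2L)
  expect_equal(lab_of(-100), 1L) # non-aerated under [-100, +100]
  expect_equal(lab_of(50), 1L)

  # out-of-range voxels are clamped and counted
  am <- classify_aeration(make_uniform_ct(-1050), mask)
  expect_equal(unique(as.vector(am$labels)), 4L)
  expect_equal(unname(am$qc["clamped_below"]), 216)

  # grid mismatch is an error
  small <- binary_mask(array(TRUE, c(5, 6, 6)), 0.1)
  expect_error(classify_aeration(make_uniform_ct(-700), small), "different grids")

  # invalid thresholds rejected
  expect_error(aeration_thresholds(c(-1000, -500, -900, -100, 100)), "increasing")
})

test_that("zero-noise phantom classification agrees with the generated layout", {
  spec <- sphere_spec(32, r = 1.2)
  m <- make_lung_mask(spec)
  lay <- compartment_layout(m, spec)
  ct <- make_ct_from_labels(lay, spec)
  am <- classify_aeration(ct, m)
  expect_identical(am$labels, lay)
})

test_that("compartment fractions partition the lung", {
  lab <- array(0L, c(4, 4, 4))
  lab[1:4, 1:4, 1] <- 3L
  expect_equal(compartment_fractions(lab),
               c(non = 0, poor = 0, normal = 1, hyper = 0))
  lab[, , 1:4] <- rep(1:4, each = 16)
  expect_equal(unname(compartment_fractions(lab)), rep(0.25, 4))
  expect_equal(sum(compartment_fractions(lab)), 1, tolerance = 1e-12)
  expect_error(compartment_fractions(array(0L, c(2, 2, 2))), "empty")
})

test_that("aerated mask excludes exactly the non-aerated compartment", {
  spec <- sphere_spec(32, r = 1.2)
  m <- make_lung_mask(spec)
  lay <- compartment_layout(m, spec)
  am <- classify_aeration(make_ct_from_labels(lay, spec), m)
  aer <- aerated_mask(am)
  expect_identical(aer$data, lay >= 2)
  expect_equal(mask_volume(aer),
               mask_volume(m) * (1 - compartment_fractions(am)[["non"]]))

  # no non-aerated voxels -> aerated mask equals whole mask
  spec_all <- sphere_spec(24, r = 0.9, compartment_fractions = c(
    non = 0, poor = 0.2, normal = 0.75, hyper = 0.05))
  m2 <- make_lung_mask(spec_all)
  lay2 <- compartment_layout(m2, spec_all)
  am2 <- classify_aeration(make_ct_from_labels(lay2, spec_all), m2)
  expect_identical(aerated_mask(am2)$data, m2$data)

  # all-collapsed lung -> empty aerated mask with a warning
  lay3 <- lay2
  lay3[lay3 > 0] <- 1L
  am3 <- classify_aeration(make_ct_from_labels(lay3, spec_all), m2)
  expect_warning(aer3 <- aerated_mask(am3), "empty")
  expect_true(isTRUE(attr(aer3, "empty")))
})

test_that("dorso-ventral split balances volumes to within one slab", {
  m <- make_lung_mask(sphere_spec(48, r = 2.0))
  sp <- dorsoventral_split(m)
  expect_identical(sp$dorsal$data | sp$ventral$data, m$data)
  expect_false(any(sp$dorsal$data & sp$ventral$data))
  slab_max <- max(apply(m$data, 2, sum))
  expect_lte(abs(sum(sp$dorsal$data) - sum(sp$ventral$data)), slab_max)
  # symmetric sphere: plane at the centre +/- 1 voxel
  expect_lte(abs(sp$plane - 24), 1)

  # all mass in a single DV slab cannot be balanced
  one <- array(FALSE, c(8, 8, 8)); one[, 4, ] <- TRUE
  expect_warning(spd <- dorsoventral_split(binary_mask(one, 0.1)), "degenerate")
  expect_true(spd$degenerate)
  expect_error(dorsoventral_split(binary_mask(array(FALSE, c(4, 4, 4)), 0.1)),
               "empty")
})

test_that("global metrics follow the volume/ventilation formulas", {
  # 1000 voxels at 0.1 mm spacing = 1 mm^3 = 0.001 ml raw volume
  m1 <- binary_mask(array(TRUE, c(10, 10, 10)), 0.1)
  expect_equal(mask_volume(m1), 1)

  # EELV 20, EILV 25 ml/kg -> Vt 5, global strain 25%
  ee <- binary_mask(array(TRUE, c(20, 10, 10)), 0.1)   # 2 mm^3
  ei <- binary_mask(array(TRUE, c(25, 10, 10)), 0.1)   # 2.5 mm^3
  gm <- global_metrics(ee, ei, body_mass_kg = 1e-4, rr_per_min = 90)
  expect_equal(gm$EELV, 20)
  expect_equal(gm$EILV, 25)
  expect_equal(gm$Vt, 5)
  expect_equal(gm$global_strain_pct, 25)
  expect_equal(gm$Vmin, 450)

  expect_error(global_metrics(ee, ei, body_mass_kg = 0, rr_per_min = 90),
               "positive")
})

test_that("metrics are invariant to image translation", {
  spec <- sphere_spec(40, r = 1.2)
  m <- make_lung_mask(spec)
  shifted <- array(FALSE, dim(m$data))
  shifted[4:40, , ] <- m$data[1:37, , ]
  ms <- binary_mask(shifted, m$spacing)
  gm1 <- global_metrics(m, m, 0.003, 90)
  gm2 <- global_metrics(ms, ms, 0.003, 90)
  expect_equal(gm1$EELV, gm2$EELV)
  expect_equal(gm1$global_strain_pct, gm2$global_strain_pct)
})
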