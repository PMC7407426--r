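# Small analytic fixtures shared across test files. Everything is generated
# in code; sizes are kept small so the full suite stays fast.

# spherical phantom without obliquity, for analytic-geometry checks
sphere_spec <- function(n = 48, r = 2.0, spacing = 0.1, ...) {
  phantom_spec(grid_shape = c(n, n, n), spacing = spacing,
               lung_semiaxes = c(r, r, r), dv_shear = 0, hu_noise_sd = 0, ...)
}

# paired EE/EI masks for an isotropic stretch of a sphere
stretch_pair <- function(n = 48, r = 1.6, a = 1.1) {
  ee <- make_lung_mask(sphere_spec(n, r))
  ei <- make_lung_mask(sphere_spec(n, r * a))
  list(ee = ee, ei = ei, strain = a^3 - 1)
}

# small box mesh with uniform density
box_strain_field <- function(dims = c(10, 10, 4), spacing = 0.5) {
  mesh <- tetrahedralize_mask(binary_mask(array(TRUE, dims), spacing))
  volumetric_strain(mesh, mesh$nodes) # zero strain, identity reference
}

# hand-built strain field data frame (bypasses meshing) for ROI unit tests
toy_strain_field <- function(ab, dv, v, strain) {
  sf <- data.frame(tet = seq_along(ab), ab = ab, dv = dv, lr = 0,
                   v_ei = v, v_ee = v, j = 1 + strain, strain = strain)
  class(sf) <- c("strain_field", "data.frame")
  sf
}

# brute-force exact signed-rank p by enumerating sign matrices (R oracle,
# independent of the C++ Gray-code path)
signed_rank_brute <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  switch(alternative,
         greater = mean(w_all >= w_obs - 1e-9),
         less = mean(w_all <= w_obs + 1e-9),
         two.sided = min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)))
}

# constructed per-cell group stats: `effect` added to T3 means of cell (1,1),
# cell (2,1) is null; enough subjects/cells for the map tests
toy_group_stats <- function(n_subj = 5, effect = 0.2, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subj)) {
    base <- c(0.2, 0.25) + rnorm(2, 0, 0.005)
    for (tm in c("T1", "T3")) {
      mn <- base + if (tm == "T3") c(effect, 0) else c(0, 0)
      mn <- mn + rnorm(2, 0, 1e-4)
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("S%02d", s), time = tm, i = c(1, 2), j = 1,
        occupied = TRUE, mean = mn, sd = c(0.05, 0.05),
        raw_n = 200, raw_mean = 1 + mn, raw_sd = c(0.05, 0.05) * (1 + (tm == "T3") * (mn > 0.3)))
    }
  }
  do.call(rbind, rows)
}
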