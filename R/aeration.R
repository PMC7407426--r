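# Aeration compartments and global volume/ventilation metrics.
#
# Lung voxels are classified into four compartments from their Hounsfield
# units. The study that motivates this package cites the standard
# quantitative-CT ranges without printing them, so the boundaries are
# configurable with the conventional defaults: hyper-aerated [-1000, -900),
# normally aerated [-900, -500), poorly aerated [-500, -100), non-aerated
# [-100, +100]. Intervals are half-open, lower-closed, so every HU value
# lands in exactly one compartment.

#' Aeration thresholds
#'
#' @param boundaries Strictly increasing HU boundaries partitioning
#'   `[-1000, +100]` into hyper / normal / poor / non compartments
#'   (5 values: lower edge, three cut points, upper edge).
#' @return An `aeration_thresholds` object.
#' @export
aeration_thresholds <- function(boundaries = c(-1000, -900, -500, -100, 100)) {
  if (length(boundaries) != 5 || any(diff(boundaries) <= 0)) {
    stop("boundaries must be 5 strictly increasing HU values")
  }
  structure(list(boundaries = as.numeric(boundaries)), class = "aeration_thresholds")
}

#' Classify lung voxels into aeration compartments
#'
#' Each masked voxel gets exactly one label: 1 non, 2 poor, 3 normal,
#' 4 hyper (background 0). Voxels outside the classification range are
#' clamped to the nearest compartment and counted in the QC attribute.
#'
#' @param ct A [ct_image].
#' @param whole_mask Whole-lung [binary_mask] on the same grid.
#' @param thresholds An [aeration_thresholds()].
#' @return An `aeration_map`: list with `labels` (integer array), `spacing`,
#'   and `qc` (count of clamped voxels below/above range).
#' @export
classify_aeration <- function(ct, whole_mask, thresholds = aeration_thresholds()) {
  stopifnot(inherits(ct, "ct_image"), inherits(whole_mask, "binary_mask"),
            inherits(thresholds, "aeration_thresholds"))
  assert_same_grid(ct, whole_mask, "CT and mask")
  if (abs(ct$spacing - whole_mask$spacing) > 1e-9) stop("CT and mask spacing differ")
  b <- thresholds$boundaries
  hu <- ct$data[whole_mask$data]
  n_below <- sum(hu < b[1])
  n_above <- sum(hu > b[5])
  hu <- pmin(pmax(hu, b[1]), b[5])
  # findInterval with lower-closed bins; bin 1..4 = hyper..non, remap to
  # labels 1 non .. 4 hyper
  bin <- findInterval(hu, b, rightmost.closed = TRUE)
  labels <- array(0L, dim(ct$data))
  labels[whole_mask$data] <- 5L - as.integer(bin)
  structure(list(labels = labels, spacing = ct$spacing, axes = LUNG_AXES,
                 qc = c(clamped_below = n_below, clamped_above = n_above)),
            class = "aeration_map")
}

#' @export
print.aeration_map <- function(x, ...) {
  fr <- compartment_fractions(x)
  cat(sprintf("<aeration_map> %s voxels; non %.1f%%, poor %.1f%%, normal %.1f%%, hyper %.1f%%\n",
              paste(dim(x$labels), collapse = "x"),
              100 * fr["non"], 100 * fr["poor"], 100 * fr["normal"], 100 * fr["hyper"]))
  invisible(x)
}

#' Compartment volume fractions
#'
#' @param am An `aeration_map` (or a raw integer label array with labels
#'   0..4).
#' @return Named fractions (non, poor, normal, hyper) of total lung volume;
#'   they sum to 1.
#' @export
compartment_fractions <- function(am) {
  labels <- if (inherits(am, "aeration_map")) am$labels else am
  n <- tabulate(labels[labels > 0L], nbins = 4L)
  if (sum(n) == 0) stop("empty aeration map: no lung voxels")
  setNames(n / sum(n), COMPARTMENTS)
}

#' Aerated-lung mask
#'
#' The aerated mask is the union of the poorly, normally and hyper-aerated
#' compartments; non-aerated regions are excluded. An attribute flags the
#' degenerate all-collapsed case.
#'
#' @param am An `aeration_map`.
#' @return A [binary_mask] with attribute `empty` if no aerated voxels exist.
#' @export
aerated_mask <- function(am) {
  stopifnot(inherits(am, "aeration_map"))
  m <- binary_mask(am$labels >= 2L, am$spacing)
  if (!any(m$data)) {
    warning("aerated mask is empty (all lung voxels non-aerated)")
    attr(m, "empty") <- TRUE
  }
  m
}

#' Split a mask into equal-volume dorsal and ventral halves
#'
#' Chooses the dorso-ventral plane so the two halves differ by at most one
#' DV voxel slab; their union is the input mask. Increasing DV index is
#' ventral by package convention.
#'
#' @param mask A [binary_mask].
#' @return List with `dorsal` and `ventral` masks, the `plane` index (last
#'   DV slab included in the dorsal half) and a `degenerate` flag when an
#'   equal split is impossible (all mass in one slab).
#' @export
dorsoventral_split <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("empty mask")
  slab <- apply(mask$data, 2, sum)
  total <- sum(slab)
  cum <- cumsum(slab)
  plane <- which.min(abs(cum - total / 2))
  dorsal <- mask$data
  dorsal[, seq_len(dim(mask$data)[2]) > plane, ] <- FALSE
  ventral <- mask$data & !dorsal
  imbalance <- abs(2 * cum[plane] - total)
  # equal split impossible: one half empty or imbalance beyond one slab
  degenerate <- cum[plane] == 0 || cum[plane] == total || imbalance > max(slab)
  if (degenerate) warning("dorso-ventral split is degenerate: halves cannot be balanced")
  list(dorsal = binary_mask(dorsal, mask$spacing),
       ventral = binary_mask(ventral, mask$spacing),
       plane = plane, imbalance_voxels = imbalance, degenerate = degenerate)
}

#' Global lung volumes and ventilation metrics
#'
#' Volumes are aerated-mask voxel counts times the voxel volume, normalised
#' per kg body mass: `Vt = EILV - EELV`, global strain `= Vt / EELV`
#' (reported as %), minute ventilation `Vmin = RR * Vt`.
#'
#' @param aerated_ee Aerated [binary_mask] at end-expiration.
#' @param aerated_ei Aerated [binary_mask] at end-inspiration.
#' @param body_mass_kg Body mass in kg.
#' @param rr_per_min Respiratory rate (1/min).
#' @return A `global_metrics` list: EELV, EILV, Vt (ml/kg), global_strain_pct,
#'   Vmin (ml/(min kg)), raw volumes in mm^3.
#' @export
global_metrics <- function(aerated_ee, aerated_ei, body_mass_kg, rr_per_min) {
  stopifnot(inherits(aerated_ee, "binary_mask"), inherits(aerated_ei, "binary_mask"))
  if (body_mass_kg <= 0) stop("body mass must be positive")
  v_ee <- mask_volume(aerated_ee) # mm^3 == 1e-3 ml
  v_ei <- mask_volume(aerated_ei)
  if (v_ee == 0) stop("EELV is zero: global strain undefined")
  if (v_ei == 0) stop("EILV is zero")
  eelv <- v_ee / 1000 / body_mass_kg
  eilv <- v_ei / 1000 / body_mass_kg
  vt <- eilv - eelv
  structure(list(EELV = eelv, EILV = eilv, Vt = vt,
                 global_strain_pct = 100 * vt / eelv,
                 Vmin = rr_per_min * vt, rr_per_min = rr_per_min,
                 body_mass_kg = body_mass_kg,
                 raw_volume_ee_mm3 = v_ee, raw_volume_ei_mm3 = v_ei),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf("<global_metrics> EELV %.2f, EILV %.2f, Vt %.2f ml/kg; strain %.1f%%; Vmin %.0f ml/(min kg)\n",
              x$EELV, x$EILV, x$Vt, x$global_strain_pct, x$Vmin))
  invisible(x)
}

#' Clean a binary mask for registration and meshing
#'
#' Threshold classification of a noisy CT leaves salt-and-pepper speckle at
#' compartment interfaces; the signed-distance transform and the mesh both
#' need a coherent solid. A 3x3x3 majority filter removes speckle and the
#' largest 6-connected component drops detached islands.
#'
#' @param mask A [binary_mask].
#' @param majority_iterations Passes of the majority filter (default 1).
#' @return A cleaned [binary_mask].
#' @export
clean_mask <- function(mask, majority_iterations = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  m <- majority_filter_cpp(as.vector(mask$data), d, as.integer(majority_iterations))
  m <- largest_component_cpp(m, d)
  binary_mask(array(m, d), mask$spacing)
}
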