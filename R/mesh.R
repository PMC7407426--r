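# Tetrahedral mesh of the aerated lung and per-tet volumetric strain.
#
# Each masked voxel is split into 6 tetrahedra by the Kuhn/Freudenthal
# decomposition along a globally consistent main diagonal, so the mesh
# conforms across voxel faces and partitions the mask volume exactly. Strain
# is the relative volume change of each tetrahedron between the
# end-inspiration configuration (where the mesh is built) and its
# end-expiration image under the displacement field: epsilon = J - 1 with
# J = det F > 0, inflation giving epsilon > 0.

#' Tetrahedralize a binary mask
#'
#' @param mask A [binary_mask] (typically the aerated lung at EI).
#' @return A `tet_mesh`: `nodes` (n x 3 mm), `tets` (m x 4 node indices,
#'   positively oriented), `owner` (1-based linear voxel index per tet, for
#'   provenance/QC), `spacing`.
#' @export
tetrahedralize_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  res <- tetrahedralize_mask_cpp(as.vector(mask$data), dim(mask$data), mask$spacing)
  structure(list(nodes = res$nodes, tets = res$tets, owner = res$owner,
                 spacing = mask$spacing, dims = dim(mask$data)),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tets, total volume %.4g mm^3\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$tets) / 6 * x$spacing^3))
  invisible(x)
}

#' Signed volume of a tetrahedron
#'
#' `det[p1 - p0, p2 - p0, p3 - p0] / 6`; positive for positively oriented
#' vertices, zero for coplanar points, sign flips when two vertices swap.
#'
#' @param p0,p1,p2,p3 Length-3 coordinate vectors (mm).
#' @return Signed volume in mm^3.
#' @export
signed_tet_volume <- function(p0, p1, p2, p3) {
  det(cbind(p1 - p0, p2 - p0, p3 - p0)) / 6
}

#' Warp mesh nodes to the reference (EE) configuration
#'
#' Applies the backward map `x_EE = x_EI + u(x_EI)` to every node by
#' trilinear interpolation of the dense displacement field. Nodes outside
#' the field grid raise an error (no extrapolation).
#'
#' @param mesh A [tet_mesh] built at EI.
#' @param field A [displacement_field] on the EI grid.
#' @return n x 3 matrix of reference node coordinates (mm).
#' @export
warp_mesh_to_reference <- function(mesh, field) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(field, "displacement_field"))
  u <- interp_field_cpp(as.vector(field$u), dim(field$u)[1:3], mesh$nodes,
                        field$spacing)
  mesh$nodes + u
}

#' Sample a displacement field at arbitrary points
#'
#' Trilinear interpolation of the dense field; exact at voxel centres and
#' for fields linear in the coordinates. Out-of-bounds points are an error.
#'
#' @param field A [displacement_field].
#' @param points n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of displacement vectors (mm).
#' @export
sample_displacement <- function(field, points) {
  stopifnot(inherits(field, "displacement_field"))
  points <- rbind3(points)
  interp_field_cpp(as.vector(field$u), dim(field$u)[1:3], points, field$spacing)
}

#' Per-tetrahedron volumetric strain
#'
#' For each tet the deformation gradient is `F = E_EI %*% solve(E_EE)` with
#' `E_*` the 3 x 3 edge matrices from node 0; `J = det F = V_EI / V_EE` and
#' the volumetric strain is `epsilon = J - 1` (inspiration relative to
#' expiration, inflation positive).
#'
#' @param mesh A [tet_mesh] at EI.
#' @param reference_nodes Reference (EE) node coordinates from
#'   [warp_mesh_to_reference()].
#' @return A `strain_field` data frame: tet id, EI centroid (mm), `v_ei` and
#'   `v_ee` volumes (mm^3), `j`, `strain`. Attribute `j_det` keeps the
#'   determinant-of-F cross-check.
#' @export
volumetric_strain <- function(mesh, reference_nodes) {
  stopifnot(inherits(mesh, "tet_mesh"),
            identical(dim(reference_nodes), dim(mesh$nodes)))
  met <- tet_metrics_cpp(mesh$nodes, reference_nodes, mesh$tets)
  bad <- which(met$v_ref <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive reference volume in %d tets (first ids: %s)",
                 length(bad), paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(met$v_cur <= 0)) stop("non-positive EI tet volume: mesh is corrupt")
  sf <- data.frame(tet = seq_along(met$v_cur),
                   ab = met$centroid[, 1], dv = met$centroid[, 2],
                   lr = met$centroid[, 3],
                   v_ei = met$v_cur, v_ee = met$v_ref,
                   j = met$j_ratio, strain = met$j_ratio - 1)
  attr(sf, "j_det") <- met$j_det
  attr(sf, "spacing") <- mesh$spacing
  class(sf) <- c("strain_field", "data.frame")
  sf
}

#' Jacobian map of a displacement field
#'
#' Central-difference Jacobian determinant of the induced map
#' `x -> x + u(x)` on the voxel grid; used to verify that a registration is
#' orientation-preserving over the mask.
#'
#' @param field A [displacement_field].
#' @return 3D array of Jacobian determinants (one-sided differences on the
#'   grid border).
#' @export
field_jacobian <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  u <- field$u
  h <- field$spacing
  d <- dim(u)[1:3]
  grad <- function(comp, axis) {
    arr <- u[, , , comp]
    g <- array(NA_real_, d)
    idx <- seq_len(d[axis])
    lo <- pmax(idx - 1L, 1L)
    hi <- pmin(idx + 1L, d[axis])
    denom <- (hi - lo) * h
    if (axis == 1) g <- (arr[hi, , ] - arr[lo, , ]) / denom
    if (axis == 2) g <- aperm(apply(arr, c(1, 3), function(v) (v[hi] - v[lo]) / denom), c(2, 1, 3))
    if (axis == 3) g <- aperm(apply(arr, c(1, 2), function(v) (v[hi] - v[lo]) / denom), c(2, 3, 1))
    g
  }
  # deformation gradient F = I + du/dx
  F11 <- 1 + grad(1, 1); F12 <- grad(1, 2); F13 <- grad(1, 3)
  F21 <- grad(2, 1); F22 <- 1 + grad(2, 2); F23 <- grad(2, 3)
  F31 <- grad(3, 1); F32 <- grad(3, 2); F33 <- 1 + grad(3, 3)
  F11 * (F22 * F33 - F23 * F32) - F12 * (F21 * F33 - F23 * F31) +
    F13 * (F21 * F32 - F22 * F31)
}
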