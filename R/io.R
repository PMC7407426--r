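# On-disk formats: NIfTI-1 volumes (via RNifti), mesh + per-tet strain as
# ASCII VTU for visualisation, tables as CSV.

#' Write a 3D volume as NIfTI-1
#'
#' @param data 3D array.
#' @param spacing Isotropic voxel spacing in mm (stored in the header).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_nifti_volume <- function(data, spacing, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep(spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return List with `data` (3D array) and `spacing` (mm); errors on
#'   anisotropic voxels or a corrupt header.
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0)) stop("invalid voxel dimensions in ", path)
  if (diff(range(pd)) > 1e-6 * pd[1]) {
    stop("anisotropic voxels are not supported: ", paste(signif(pd, 4), collapse = " x "))
  }
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3D volume in ", path)
  attributes(arr) <- list(dim = dim(arr))
  list(data = arr, spacing = as.numeric(pd[1]))
}

#' Write a dense displacement field as 4D NIfTI-1
#'
#' Three mm-valued components on the EI grid, backward-map convention
#' (`x_EE = x_EI + u`). The same layout is accepted on import, so externally
#' computed fields can be injected into the pipeline.
#'
#' @param field A [displacement_field].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  img <- RNifti::asNifti(field$u)
  RNifti::pixdim(img) <- c(rep(field$spacing, 3), 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a dense displacement field from 4D NIfTI-1
#' @param path Path to a 4D (x,y,z,3) NIfTI volume, mm components.
#' @return A [displacement_field].
#' @export
read_displacement_field <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4 || dim(arr)[4] != 3) {
    stop("expected a 4D (x,y,z,3) displacement volume in ", path)
  }
  pd <- RNifti::pixdim(img)[1:3]
  attributes(arr) <- list(dim = dim(arr))
  displacement_field(arr, as.numeric(pd[1]),
                     meta = list(source = paste("imported from", path)))
}

#' Export a tetrahedral mesh with per-tet strain as ASCII VTU
#'
#' Minimal VTK XML unstructured-grid writer (linear tetrahedra, one cell
#' scalar field), sufficient for ParaView-style visualisation of strain maps.
#'
#' @param mesh A [tet_mesh].
#' @param strain Per-tet scalar (e.g. volumetric strain), length `nrow(tets)`.
#' @param path Output `.vtu` path.
#' @param name Name of the cell data field.
#' @return The path, invisibly.
#' @export
write_strain_vtu <- function(mesh, strain, path, name = "volumetric_strain") {
  stopifnot(inherits(mesh, "tet_mesh"), length(strain) == nrow(mesh$tets))
  np <- nrow(mesh$nodes)
  nc <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', np, nc)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, function(r) paste(format(r, digits = 10), collapse = " ")), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$tets - 1L, 1, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(nc) * 4L), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("10", nc), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('      <CellData Scalars="%s">', name)
  w('        <DataArray type="Float64" Name="%s" format="ascii">', name)
  writeLines(format(strain, digits = 10), con)
  w('        </DataArray>')
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
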