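#' @useDynLib lungstrain, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd pchisq pnorm setNames
#' @importFrom utils write.csv read.csv
NULL

# Axis convention used throughout: array dimension 1 is apical-basal (AB),
# dimension 2 is dorsal-ventral (DV, increasing index = more ventral),
# dimension 3 is left-right (LR). Voxel (i,j,k) has its center at
# ((i-0.5)*spacing, ...) mm, so voxel corners lie on multiples of the spacing.

LUNG_AXES <- c("AB", "DV", "LR")

#' CT image container
#'
#' A 3D scalar grid of Hounsfield units with isotropic spacing. Axes follow
#' the package convention: apical-basal, dorsal-ventral (increasing index is
#' ventral), left-right.
#'
#' @param data 3D numeric array of HU values.
#' @param spacing Isotropic voxel spacing in mm.
#' @return An object of class `ct_image` with fields `data`, `spacing`, `axes`.
#' @export
ct_image <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3, is.numeric(spacing),
            length(spacing) == 1, spacing > 0)
  structure(list(data = data, spacing = as.numeric(spacing), axes = LUNG_AXES),
            class = "ct_image")
}

#' Binary mask container
#'
#' @param data 3D logical array of voxel membership.
#' @param spacing Isotropic voxel spacing in mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3, spacing > 0)
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing = as.numeric(spacing), axes = LUNG_AXES),
            class = "binary_mask")
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %s voxels, %.4g mm spacing, HU range [%.0f, %.0f]\n",
              paste(dim(x$data), collapse = "x"), x$spacing,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %.4g mm spacing, %d in mask (%.1f%%)\n",
              paste(dim(x$data), collapse = "x"), x$spacing, sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

#' Mask volume in mm^3
#' @param mask A [binary_mask].
#' @return Total volume of TRUE voxels in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * mask$spacing^3
}

#' Dense displacement field container
#'
#' Per-voxel 3-vectors (mm) on the end-inspiration (EI) grid using the
#' backward-map convention `x_EE = x_EI + u(x_EI)`: the field carries each EI
#' point to its end-expiration position.
#'
#' @param u 4D numeric array with dims `c(grid_dims, 3)`.
#' @param spacing Isotropic voxel spacing in mm.
#' @param meta Optional list of provenance metadata (registration parameters,
#'   convergence diagnostics, field origin).
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(u, spacing, meta = list()) {
  stopifnot(is.array(u), length(dim(u)) == 4, dim(u)[4] == 3, spacing > 0)
  if (!all(is.finite(u))) stop("displacement field contains non-finite values")
  structure(list(u = u, spacing = as.numeric(spacing), axes = LUNG_AXES,
                 meta = meta),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %s voxels, max |u| = %.3f mm (%s)\n",
              paste(dim(x$u)[1:3], collapse = "x"),
              sqrt(max(rowSums(matrix(x$u, ncol = 3)^2))),
              if (length(x$meta)) x$meta$source %||% "unspecified" else "unspecified"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# voxel-center coordinates (mm) along one axis
voxel_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

# grid of voxel-center coordinates for the TRUE voxels of a 3D array
mask_coords <- function(mask_data, spacing) {
  idx <- which(mask_data, arr.ind = TRUE)
  (idx - 0.5) * spacing
}

assert_same_grid <- function(a, b, what = "inputs") {
  da <- dim(if (is.list(a)) a$data else a)
  db <- dim(if (is.list(b)) b$data else b)
  if (!identical(da, db)) {
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  }
  invisible(TRUE)
}

# Deterministic child seeds below 2^31 from a master seed and a stream label.
derive_seed <- function(master, label) {
  h <- utils::head(utf8ToInt(paste0(label)), 32)
  s <- as.double(master %% 2147483647L)
  for (ch in h) s <- (s * 31 + ch) %% 2147483563
  as.integer(s %% 2147483647)
}
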