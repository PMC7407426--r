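# 10 x 10 apical-basal x dorsal-ventral ROI grid and the regional indices.
#
# The lung is cut into ten apical-basal slabs of approximately equal tet
# volume and ten dorsal-ventral slabs likewise; intersecting them gives 100
# ROIs, some of which are void for a lung-shaped mesh (its corners do not
# reach the extreme slabs of both axes simultaneously). Per-ROI statistics
# are volume-weighted over the member tetrahedra. Two scalar indices track
# time evolution and dispersion on the relative-volume (1 + strain) scale:
#   SPI = (1 + mean strain at T3) / (1 + mean strain at T1)
#   SHI = (1 + strain SD) / (1 + strain mean)

AXIS_COLUMNS <- c(AB = "ab", DV = "dv", LR = "lr")

#' Equal-volume slab boundaries along an axis
#'
#' Boundaries are placed on the cumulative tet-volume distribution of the
#' centroid coordinate, so each slab holds total volume / n up to one tet's
#' volume. Slabs are half-open, lower-closed; the last is closed.
#'
#' @param strain_field A `strain_field` from [volumetric_strain()].
#' @param axis `"AB"` or `"DV"`.
#' @param n Number of slabs (default 10).
#' @return Numeric vector of n + 1 boundaries (mm); attribute `degenerate`
#'   flags coordinate distributions that cannot be split (all volume at one
#'   coordinate).
#' @export
axis_partition <- function(strain_field, axis = c("AB", "DV"), n = 10L) {
  axis <- match.arg(axis)
  if (n < 2) stop("need at least 2 slabs")
  if (nrow(strain_field) == 0) stop("empty strain field")
  coord <- strain_field[[AXIS_COLUMNS[axis]]]
  w <- strain_field$v_ei
  # tets sharing a coordinate are an atomic block a boundary cannot split
  u <- sort(unique(coord))
  cw <- cumsum(rowsum(w, coord)[, 1]) # rowsum orders by sort(unique(coord))
  total <- cw[length(cw)]
  targets <- total * seq_len(n - 1) / n
  # boundary after the unique value whose cumulative volume is closest to
  # each target; consecutive boundaries may coincide only in degenerate cases
  inner <- vapply(targets, function(tg) {
    m <- which.min(abs(cw - tg))
    if (m >= length(u)) u[length(u)] + 1e-9 else (u[m] + u[m + 1]) / 2
  }, 0)
  b <- c(u[1] - 1e-9, cummax(inner), u[length(u)] + 1e-9)
  degenerate <- any(diff(b) <= 0)
  if (degenerate) warning("axis partition is degenerate: equal-volume slabs impossible")
  attr(b, "degenerate") <- degenerate
  b
}

#' Build the ROI grid
#'
#' Bins tets into cells of the AB x DV grid by centroid (half-open slabs,
#' ties to the lower slab). Cells without tets are void.
#'
#' @param strain_field A `strain_field`.
#' @param ab_bounds,dv_bounds Slab boundaries from [axis_partition()].
#' @return An `roi_grid`: `cell` (per-tet cell index matrix columns i = AB
#'   slab, j = DV slab), `n_ab`, `n_dv`, `occupied` (logical matrix),
#'   `n_occupied`.
#' @export
build_roi_grid <- function(strain_field, ab_bounds, dv_bounds) {
  n_ab <- length(ab_bounds) - 1L
  n_dv <- length(dv_bounds) - 1L
  i <- findInterval(strain_field$ab, ab_bounds, all.inside = TRUE)
  j <- findInterval(strain_field$dv, dv_bounds, all.inside = TRUE)
  occupied <- matrix(FALSE, n_ab, n_dv)
  occupied[cbind(i, j)] <- TRUE
  structure(list(cell = cbind(i = i, j = j), n_ab = n_ab, n_dv = n_dv,
                 ab_bounds = ab_bounds, dv_bounds = dv_bounds,
                 occupied = occupied, n_occupied = sum(occupied)),
            class = "roi_grid")
}

#' @export
print.roi_grid <- function(x, ...) {
  cat(sprintf("<roi_grid> %d x %d, %d occupied cells (%d void)\n",
              x$n_ab, x$n_dv, x$n_occupied, x$n_ab * x$n_dv - x$n_occupied))
  invisible(x)
}

#' Volume-weighted ROI statistics
#'
#' Per occupied cell: volume-weighted mean strain
#' (`sum(w * e) / sum(w)` with `w` = tet EI volume), frequency-weighted
#' population SD, total volume, tet count and SHI. Void cells carry NA, not
#' zero. Unweighted moments of (1 + strain) are kept alongside for the
#' coefficient-of-variation test, which works on the per-tet sample.
#'
#' @param strain_field A `strain_field`.
#' @param grid An `roi_grid` from [build_roi_grid()].
#' @return Data frame with one row per cell (i, j, occupied, n_tets, volume,
#'   mean, sd, shi, raw_n, raw_mean, raw_sd).
#' @export
roi_weighted_stats <- function(strain_field, grid) {
  stopifnot(inherits(grid, "roi_grid"))
  cell_id <- (grid$cell[, "j"] - 1L) * grid$n_ab + grid$cell[, "i"]
  ncell <- grid$n_ab * grid$n_dv
  w <- strain_field$v_ei
  e <- strain_field$strain
  sw <- tab_sum(w, cell_id, ncell)
  swe <- tab_sum(w * e, cell_id, ncell)
  mean_ <- ifelse(sw > 0, swe / sw, NA_real_)
  swe2 <- tab_sum(w * e^2, cell_id, ncell)
  var_ <- ifelse(sw > 0, pmax(swe2 / sw - mean_^2, 0), NA_real_)
  n_tets <- tab_sum(rep(1, length(w)), cell_id, ncell)
  # unweighted per-tet moments of (1 + strain)
  x <- 1 + e
  sx <- tab_sum(x, cell_id, ncell)
  sx2 <- tab_sum(x^2, cell_id, ncell)
  raw_mean <- ifelse(n_tets > 0, sx / n_tets, NA_real_)
  raw_var <- ifelse(n_tets > 1, pmax((sx2 - sx^2 / n_tets) / (n_tets - 1), 0), NA_real_)
  out <- data.frame(
    i = rep(seq_len(grid$n_ab), times = grid$n_dv),
    j = rep(seq_len(grid$n_dv), each = grid$n_ab),
    occupied = n_tets > 0,
    n_tets = n_tets,
    volume = ifelse(n_tets > 0, sw, NA_real_),
    mean = mean_,
    sd = sqrt(var_),
    raw_n = n_tets,
    raw_mean = raw_mean,
    raw_sd = sqrt(raw_var))
  out$shi <- ifelse(out$occupied, shi(out$mean, out$sd), NA_real_)
  out
}

tab_sum <- function(x, id, n) {
  out <- numeric(n)
  agg <- rowsum(x, id)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Strain progression index
#'
#' `SPI = (1 + mean strain at T3) / (1 + mean strain at T1)`. SPI = 1 means
#' no evolution of regional strain, SPI > 1 temporal amplification, SPI < 1
#' reduction.
#'
#' @param mean_t1,mean_t3 ROI-mean strains (each > -1); vectorised.
#' @return SPI value(s).
#' @export
spi <- function(mean_t1, mean_t3) {
  if (any(mean_t1 <= -1, na.rm = TRUE) || any(mean_t3 <= -1, na.rm = TRUE)) {
    stop("mean strain <= -1: SPI undefined")
  }
  (1 + mean_t3) / (1 + mean_t1)
}

#' Strain heterogeneity index
#'
#' `SHI = (1 + ROI strain SD) / (1 + ROI strain mean)`, the dispersion
#' measure of the within-ROI strain distribution expressed on the relative
#' volume-change scale.
#'
#' @param mean ROI-mean strain (> -1); vectorised.
#' @param sd ROI strain SD (>= 0).
#' @return SHI value(s).
#' @export
shi <- function(mean, sd) {
  if (any(mean <= -1, na.rm = TRUE)) stop("mean strain <= -1: SHI undefined")
  if (any(sd < 0, na.rm = TRUE)) stop("negative SD")
  (1 + sd) / (1 + mean)
}

#' Percentage of significant ROIs
#'
#' `100 * significant / occupied`, rounded half-up to one decimal (so 38 of
#' 87 prints as 43.7).
#'
#' @param flags Logical vector of per-cell significance, or a single count.
#' @param occupied_count Number of occupied (testable) cells.
#' @return Percentage rounded half-up to one decimal.
#' @export
percentage_significant <- function(flags, occupied_count) {
  if (occupied_count < 1) stop("no occupied cells")
  n_sig <- if (is.logical(flags)) sum(flags, na.rm = TRUE) else flags
  floor(1000 * n_sig / occupied_count + 0.5) / 10
}

#' Arrange a per-cell column as the 10 x 10 ROI matrix
#'
#' @param stats Data frame from [roi_weighted_stats()].
#' @param column Column to arrange (default `"mean"`).
#' @return Matrix (AB x DV) with NA in void cells.
#' @export
roi_matrix <- function(stats, column = "mean") {
  n_ab <- max(stats$i)
  n_dv <- max(stats$j)
  m <- matrix(NA_real_, n_ab, n_dv)
  m[cbind(stats$i, stats$j)] <- stats[[column]]
  m
}
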