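# Aerated-mask registration.
#
# Binary masks give vanishing SSD gradients, so both masks are converted to
# signed distance transforms (SDT) and a cubic B-spline free-form
# deformation is fitted by minimising the SSD between the fixed (EI) SDT and
# the warped moving (EE) SDT over a narrow band around the fixed boundary,
# plus a bending-energy penalty on the control lattice. Matching only the
# narrow band avoids the interior bias of iso-distance correspondence (deep
# inside a stretched organ, equal SDT values are not material
# correspondences); the interior field follows from the smoothness penalty,
# which reproduces affine deformations exactly. The backend is pluggable:
# externally computed dense fields can be injected through
# read_displacement_field().

#' Signed distance transform of a mask
#'
#' Exact Euclidean distance (mm), negative inside, positive outside, with a
#' half-voxel offset so the zero level set sits on the mask boundary and
#' boundary voxels satisfy `|sdt| <= spacing / 2`.
#'
#' @param mask A non-empty [binary_mask].
#' @return 3D numeric array of signed distances (mm).
#' @export
mask_to_sdt <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  m <- as.vector(mask$data)
  if (!any(m)) stop("empty mask has no signed distance transform")
  d_in <- sqrt(edt_sq_cpp(m, d))    # distance to nearest mask voxel (0 inside)
  d_out <- sqrt(edt_sq_cpp(!m, d))  # distance to nearest background voxel
  sdt <- (d_in - d_out) * mask$spacing + ifelse(m, mask$spacing / 2, -mask$spacing / 2)
  array(sdt, d)
}

#' Registration parameters
#'
#' @param levels Pyramid levels (coarse to fine by factors of 2).
#' @param control_spacing Control-point spacing in voxels at the finest level.
#' @param bend_weight Bending-energy weight (dimensionless, on the
#'   normalised cost).
#' @param band Half-width of the SSD band around the fixed boundary, in
#'   voxels of each level.
#' @param max_iter L-BFGS iterations per level (recycled across levels).
#' @param tol Relative cost-decrease convergence tolerance.
#' @return A `reg_params` list.
#' @export
reg_params <- function(levels = 3L, control_spacing = 4, bend_weight = 0.1,
                       band = 3, max_iter = c(200L, 150L, 100L), tol = 1e-6) {
  stopifnot(levels >= 1, control_spacing >= 1, bend_weight >= 0, band >= 1)
  structure(list(levels = as.integer(levels), control_spacing = control_spacing,
                 bend_weight = bend_weight, band = band,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "reg_params")
}

# block-mean downsampling of a logical mask by a factor of 2 per axis
downsample_mask <- function(data, spacing, factor) {
  if (factor == 1) return(list(data = data, spacing = spacing))
  d <- dim(data)
  nd <- ceiling(d / factor)
  acc <- array(0, nd)
  cnt <- array(0, nd)
  idx1 <- (seq_len(d[1]) - 1L) %/% factor + 1L
  idx2 <- (seq_len(d[2]) - 1L) %/% factor + 1L
  idx3 <- (seq_len(d[3]) - 1L) %/% factor + 1L
  # accumulate by grouped sums along each axis successively
  red1 <- rowsum(matrix(as.numeric(data), d[1]), idx1)
  red1 <- array(red1, c(nd[1], d[2], d[3]))
  red2 <- aperm(red1, c(2, 1, 3))
  red2 <- rowsum(matrix(red2, d[2]), idx2)
  red2 <- aperm(array(red2, c(nd[2], nd[1], d[3])), c(2, 1, 3))
  red3 <- aperm(red2, c(3, 1, 2))
  red3 <- rowsum(matrix(red3, d[3]), idx3)
  red3 <- aperm(array(red3, c(nd[3], nd[1], nd[2])), c(2, 3, 1))
  nper <- outer(outer(tabulate(idx1, nd[1]), tabulate(idx2, nd[2])), tabulate(idx3, nd[3]))
  list(data = red3 / nper >= 0.5, spacing = spacing * factor)
}

# L-BFGS (two-loop recursion) with Armijo backtracking. Accepted iterates
# have strictly non-increasing cost by construction; the trace is recorded.
lbfgs_armijo <- function(x0, fn_gr, max_iter, tol, memory = 8) {
  x <- x0
  fg <- fn_gr(x)
  f <- fg$cost
  g <- fg$grad
  trace <- f
  S <- list(); Y <- list(); rho <- numeric(0)
  for (it in seq_len(max_iter)) {
    # two-loop recursion
    q <- g
    m <- length(S)
    alpha <- numeric(m)
    if (m > 0) {
      for (i in m:1) {
        alpha[i] <- rho[i] * sum(S[[i]] * q)
        q <- q - alpha[i] * Y[[i]]
      }
      gamma <- sum(S[[m]] * Y[[m]]) / sum(Y[[m]] * Y[[m]])
      q <- gamma * q
      for (i in 1:m) {
        beta <- rho[i] * sum(Y[[i]] * q)
        q <- q + (alpha[i] - beta) * S[[i]]
      }
    } else {
      q <- q / max(sqrt(sum(q^2)), 1e-12)
    }
    p <- -q
    gp <- sum(g * p)
    if (gp > 0) { # not a descent direction; restart steepest
      p <- -g / max(sqrt(sum(g^2)), 1e-12)
      gp <- sum(g * p)
      S <- list(); Y <- list(); rho <- numeric(0)
    }
    step <- 1
    accepted <- FALSE
    for (ls in 1:25) {
      xn <- x + step * p
      fgn <- fn_gr(xn)
      if (is.finite(fgn$cost) && fgn$cost <= f + 1e-4 * step * gp) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    s <- xn - x
    y <- fgn$grad - g
    sy <- sum(s * y)
    if (sy > 1e-12) {
      S <- c(S, list(s)); Y <- c(Y, list(y)); rho <- c(rho, 1 / sy)
      if (length(S) > memory) { S <- S[-1]; Y <- Y[-1]; rho <- rho[-1] }
    }
    rel <- (f - fgn$cost) / max(abs(f), 1e-12)
    x <- xn; f <- fgn$cost; g <- fgn$grad
    trace <- c(trace, f)
    if (rel < tol) break
  }
  list(par = x, value = f, trace = trace, iterations = length(trace) - 1)
}

#' Free-form B-spline registration of two masks
#'
#' Estimates the dense backward displacement field (`x_EE = x_EI + u`) that
#' carries the fixed end-inspiration mask onto the moving end-expiration
#' mask, by multiresolution B-spline FFD on the signed distance transforms.
#' The Jacobian of the recovered map is checked for positivity over the
#' (eroded) fixed mask; a folded field is an error.
#'
#' @param fixed Fixed (EI) [binary_mask].
#' @param moving Moving (EE) [binary_mask] on the same grid.
#' @param params A [reg_params()].
#' @return A [displacement_field] on the EI grid with convergence metadata
#'   (`meta$energy` per level, `meta$converged`).
#' @export
register_ffd <- function(fixed, moving, params = reg_params()) {
  stopifnot(inherits(fixed, "binary_mask"), inherits(moving, "binary_mask"))
  assert_same_grid(fixed, moving, "fixed and moving masks")
  h <- fixed$spacing
  dims <- dim(fixed$data)
  L <- params$levels
  max_iter <- rep_len(params$max_iter, L)

  phi <- NULL
  nc_prev <- NULL
  energy <- list()
  converged <- TRUE
  for (lev in seq_len(L)) {
    factor <- 2^(L - lev)
    fx <- downsample_mask(fixed$data, h, factor)
    mv <- downsample_mask(moving$data, h, factor)
    hs <- fx$spacing
    fsdt <- mask_to_sdt(binary_mask(fx$data, hs))
    msdt <- mask_to_sdt(binary_mask(mv$data, hs))
    mg <- sdt_gradient(msdt, hs)
    ld <- dim(fx$data)
    ext <- ld * hs
    s <- params$control_spacing * h * 2^(L - lev) # mm, halves every level
    nc <- as.integer(floor(ext / s) + 4)

    if (is.null(phi)) {
      phi <- numeric(prod(nc) * 3)
    } else {
      phi <- as.numeric(bspline_refine_cpp(phi, nc_prev, nc))
    }
    nc_prev <- nc

    band_idx <- which(abs(fsdt) <= params$band * hs)
    ai <- arrayInd(band_idx, ld)
    pts <- (ai - 0.5) * hs
    fvals <- fsdt[band_idx]

    fn_gr <- function(p) {
      ffd_cost_grad_cpp(p, nc, s, pts, fvals, as.vector(msdt),
                        as.vector(mg$gx), as.vector(mg$gy), as.vector(mg$gz),
                        ld, hs, params$bend_weight)
    }
    opt <- lbfgs_armijo(phi, fn_gr, max_iter[lev], params$tol)
    phi <- opt$par
    energy[[lev]] <- opt$trace
    if (opt$iterations >= max_iter[lev]) converged <- FALSE
  }
  if (!converged) warning("registration did not converge within max_iter; returning best iterate")

  s_fine <- params$control_spacing * h
  u <- array(ffd_dense_field_cpp(phi, nc_prev, s_fine, dims, h), c(dims, 3))
  field <- displacement_field(u, h, meta = list(
    source = "ffd_sdt_registration", params = params, energy = energy,
    converged = converged,
    convention = "fixed = EI, moving = EE, x_EE = x_EI + u(x_EI)"))
  check_field_unfolded(field, fixed)
  field
}

sdt_gradient <- function(sdt, spacing) {
  d <- dim(sdt)
  cd <- function(axis) {
    idx <- seq_len(d[axis])
    lo <- pmax(idx - 1L, 1L)
    hi <- pmin(idx + 1L, d[axis])
    den <- (hi - lo) * spacing
    if (axis == 1) (sdt[hi, , ] - sdt[lo, , ]) / den
    else if (axis == 2) aperm(apply(sdt, c(1, 3), function(v) (v[hi] - v[lo]) / den), c(2, 1, 3))
    else aperm(apply(sdt, c(1, 2), function(v) (v[hi] - v[lo]) / den), c(2, 3, 1))
  }
  list(gx = cd(1), gy = cd(2), gz = cd(3))
}

# Orientation check: Jacobian of x + u must stay positive over the eroded
# fixed mask (2-voxel margin keeps one-sided boundary differences out).
check_field_unfolded <- function(field, fixed_mask, margin = 2L) {
  jac <- field_jacobian(field)
  m <- as.vector(fixed_mask$data)
  d <- dim(fixed_mask$data)
  er <- sqrt(edt_sq_cpp(!m, d)) > margin
  core <- er & m & is.finite(as.vector(jac))
  if (any(as.vector(jac)[core] <= 0)) {
    stop("registration produced a folded field (Jacobian <= 0 on the mask)")
  }
  invisible(TRUE)
}

# eroded version of a binary mask (distance-to-background > margin voxels)
erode_mask <- function(mask, margin = 2L) {
  d <- dim(mask$data)
  er <- sqrt(edt_sq_cpp(!as.vector(mask$data), d)) > margin
  binary_mask(array(er & as.vector(mask$data), d), mask$spacing)
}
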