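# Structure-tensor orientation estimation.
#
# Membrane-stained tissue carries its intensity gradients on cell
# boundaries, all of which are perpendicular to the cell long axis. The
# windowed outer product of Gaussian-derivative gradients (the structure
# tensor) therefore has its *least* variation along the long axis: the
# eigenvector of the eigenvalue with smallest magnitude is the per-voxel
# axial orientation estimate.

#' Compute the per-voxel 3D structure tensor
#'
#' \eqn{J(x) = G_{\sigma_w} * (\nabla I \nabla I^T)} with gradients from
#' Gaussian-derivative filtering at `sigma_gradient_um` and component-wise
#' window smoothing at `sigma_window_um`. J is symmetric positive
#' semidefinite up to numerical rounding.
#'
#' @param vol `volume3d` (at least 5 voxels per axis).
#' @param sigma_gradient_um gradient (inner) scale, um.
#' @param sigma_window_um window (outer) scale, um; of the order of half a
#'   myocyte width.
#' @return a `tensor_field`: array `[y, x, z, 6]` with channel order
#'   `(xx, xy, xz, yy, yz, zz)` plus scale attributes.
#' @export
compute_structure_tensor <- function(vol, sigma_gradient_um = 2,
                                     sigma_window_um = 8) {
  stopifnot(inherits(vol, "volume3d"), sigma_gradient_um > 0, sigma_window_um > 0)
  d <- dim(vol)
  if (any(d < 5)) stop("volume must be at least 5 voxels per axis")
  vs <- voxel_size(vol)
  sg <- sigma_gradient_um / vs
  sw <- sigma_window_um / vs
  if (sg < 0.5 || sw < 0.5)
    warning("smoothing scale below half a voxel: aliasing risk")
  g <- gauss_gradient3(bare_array(vol), sg)
  tf <- array(0, c(d, 6L))
  tf[, , , 1] <- gauss_smooth3(g$x * g$x, sw)
  tf[, , , 2] <- gauss_smooth3(g$x * g$y, sw)
  tf[, , , 3] <- gauss_smooth3(g$x * g$z, sw)
  tf[, , , 4] <- gauss_smooth3(g$y * g$y, sw)
  tf[, , , 5] <- gauss_smooth3(g$y * g$z, sw)
  tf[, , , 6] <- gauss_smooth3(g$z * g$z, sw)
  structure(tf, voxel_size_um = vs, sigma_gradient_um = sigma_gradient_um,
            sigma_window_um = sigma_window_um, class = "tensor_field")
}

# flatten a tensor_field to a 6 x N matrix plus dims
tensor_matrix <- function(tf) {
  d <- dim(tf)
  stopifnot(length(d) == 4L, d[4] == 6L)
  t(matrix(unclass(tf), prod(d[1:3]), 6L))
}

# batched eigendecomposition (ascending values) of a tensor_field
tensor_eigen <- function(tf) {
  .eigen3x3_batch(tensor_matrix(tf))
}

#' Per-voxel axial orientation from a structure tensor field
#'
#' Selects, at every voxel, the eigenvector of the tensor eigenvalue with
#' smallest magnitude (sorting by `|lambda|`, which for PSD tensors is the
#' smallest eigenvalue). Voxels with fractional anisotropy below
#' `fa_floor`, with a near-degenerate smallest eigen-pair, or with a
#' near-zero tensor are flagged invalid rather than erroring. Vector signs
#' are canonicalized (first nonzero component positive); all consumers
#' must still treat the field axially (v and -v equivalent).
#'
#' @param tf a `tensor_field`.
#' @param fa_floor minimum fractional anisotropy for validity.
#' @param degeneracy_tol voxel invalid when
#'   `(|lambda|_mid - |lambda|_min) / |lambda|_max` falls below this.
#' @param trace_floor voxels whose largest eigenvalue is below this
#'   fraction of the field-wide maximum are flagged invalid: their
#'   tensors are numerical dust (flat background), not structure.
#' @return an `orientation_field`: array `[y, x, z, 3]` of unit (x, y, z)
#'   vectors (NA where invalid) with attributes `valid` (logical array),
#'   `margin` (relative separation `(|lambda|_mid - |lambda|_min) /
#'   |lambda|_max` of the smallest eigen-pair — near zero the eigenvector
#'   is ill-determined) and `voxel_size_um`.
#' @export
smallest_eigenvector_field <- function(tf, fa_floor = 0.1, degeneracy_tol = 0.05,
                                       trace_floor = 1e-9) {
  d <- dim(tf)[1:3]
  eg <- tensor_eigen(tf)
  lam <- eg$values                      # 3 x N ascending
  vec <- eg$vectors                     # 9 x N
  alam <- abs(lam)
  N <- ncol(lam)
  at <- t(alam)
  i_min <- max.col(-at, ties.method = "first")   # smallest |lambda|
  i_max <- max.col(at, ties.method = "last")
  i_mid <- 6L - i_min - i_max
  pick <- (i_min - 1L) * 3L
  v <- rbind(vec[cbind(pick + 1L, seq_len(N))],
             vec[cbind(pick + 2L, seq_len(N))],
             vec[cbind(pick + 3L, seq_len(N))])
  amin <- alam[cbind(i_min, seq_len(N))]
  amid <- alam[cbind(i_mid, seq_len(N))]
  amax <- alam[cbind(i_max, seq_len(N))]
  fa <- fa_from_lambda(lam)
  margin <- (amid - amin) / pmax(amax, 1e-300)
  valid <- is.finite(fa) & fa >= fa_floor & margin >= degeneracy_tol &
    amax > trace_floor * max(amax, 0, na.rm = TRUE)
  v <- canonical_sign(v)
  v[, !valid] <- NA_real_
  field <- array(t(v), c(d, 3L))
  structure(field, valid = array(valid, d), margin = array(margin, d),
            voxel_size_um = voxel_size(tf), class = "orientation_field")
}

# make first nonzero component of each column positive
canonical_sign <- function(v, tol = 1e-12) {
  lead <- ifelse(abs(v[1, ]) > tol, sign(v[1, ]),
                 ifelse(abs(v[2, ]) > tol, sign(v[2, ]), sign(v[3, ])))
  lead[lead == 0] <- 1
  sweep(v, 2L, lead, "*")
}

# FA from a 3 x N matrix of eigenvalues
fa_from_lambda <- function(lam) {
  mu <- colMeans(lam)
  num <- sqrt((lam[1, ] - mu)^2 + (lam[2, ] - mu)^2 + (lam[3, ] - mu)^2)
  den <- sqrt(colSums(lam^2))
  fa <- sqrt(1.5) * num / den
  fa[den == 0] <- 0
  fa
}

#' Fractional anisotropy map of a tensor field
#'
#' \eqn{FA = \sqrt{3/2}\,\lVert\lambda - \bar\lambda\rVert / \lVert\lambda\rVert}
#' over the three eigenvalues; 0 for the zero tensor. Values lie in [0, 1].
#'
#' @param tf a `tensor_field`.
#' @return array `[y, x, z]` of FA scores with `voxel_size_um` attribute.
#' @export
fractional_anisotropy <- function(tf) {
  d <- dim(tf)[1:3]
  fa <- fa_from_lambda(tensor_eigen(tf)$values)
  structure(array(fa, d), voxel_size_um = voxel_size(tf), class = "anisotropy_map")
}

#' Coarsen a tensor field by element-wise block averaging
#'
#' Emulates low-resolution acquisition: each output tensor is the
#' element-wise mean of the tensors in its block, and downstream eigen
#' analysis applies unchanged. A block of 250 at 2 um voxels corresponds
#' to ~500 um (DT-MRI-scale) resolution.
#'
#' @param tf a `tensor_field`.
#' @param block integer downsampling factor per axis (recycled to 3).
#' @param mask optional logical array: only contributing voxels inside the
#'   mask are averaged (blocks without any become zero tensors).
#' @return a coarser `tensor_field` (voxel size scaled by `block`).
#' @export
coarsen_tensor_field <- function(tf, block, mask = NULL) {
  d <- dim(tf)[1:3]
  block <- pmin(rep_len(as.integer(block), 3L), d)
  stopifnot(all(block >= 1))
  nb <- ceiling(d / block)
  idx <- lapply(1:3, function(ax) rep(seq_len(nb[ax]), each = block[ax])[seq_len(d[ax])])
  fac <- (idx[[1]][slice.index(array(0, d), 1)] - 1L) +
         nb[1] * (idx[[2]][slice.index(array(0, d), 2)] - 1L) +
         nb[1] * nb[2] * (idx[[3]][slice.index(array(0, d), 3)] - 1L)
  w <- if (is.null(mask)) rep(1, prod(d)) else as.numeric(mask)
  wsum <- rowsum_safe(w, fac, prod(nb))
  out <- array(0, c(nb, 6L))
  for (ch in 1:6) {
    comp <- as.numeric(unclass(tf)[, , , ch]) * w
    s <- rowsum_safe(comp, fac, prod(nb))
    out[, , , ch] <- array(s / pmax(wsum, 1), nb)
  }
  structure(out, voxel_size_um = voxel_size(tf) * block[1],
            sigma_gradient_um = attr(tf, "sigma_gradient_um"),
            sigma_window_um = attr(tf, "sigma_window_um"),
            block = block, class = "tensor_field")
}

rowsum_safe <- function(x, fac, nlev) {
  out <- numeric(nlev)
  s <- rowsum(x, fac)
  out[as.integer(rownames(s)) + 1L] <- s
  out
}

#' Replicate a coarse field back onto a fine grid
#'
#' Nearest (block-constant) upsampling of a coarsened orientation field or
#' map so it can be compared voxel-for-voxel with fine-scale results.
#'
#' @param coarse array whose first three dims are the coarse grid (an
#'   `orientation_field`, `tensor_field` or scalar map).
#' @param block the block factor used for coarsening.
#' @param dims_fine target fine-grid dims (length 3).
#' @return array on the fine grid (extra channel dims preserved).
#' @export
expand_blocks <- function(coarse, block, dims_fine) {
  block <- rep_len(as.integer(block), 3L)
  dc <- dim(coarse)
  idx <- lapply(1:3, function(ax) pmin(rep(seq_len(dc[ax]), each = block[ax]),
                                       dc[ax])[seq_len(dims_fine[ax])])
  out <- if (length(dc) == 3L) {
    unclass(coarse)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    unclass(coarse)[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  }
  attrs <- attributes(coarse)
  attrs$dim <- dim(out)
  attrs$valid <- NULL
  attributes(out) <- attrs
  if (!is.null(attr(coarse, "voxel_size_um")))
    attr(out, "voxel_size_um") <- attr(coarse, "voxel_size_um") / block[1]
  out
}

#' Pseudo low-resolution orientation field
#'
#' Emulates coarse-voxel (DT-MRI-scale) acquisition on the fine grid:
#' tensors are block-averaged element-wise ([coarsen_tensor_field()]),
#' eigen-decomposed at the coarse scale, and the resulting orientations
#' are replicated back onto the fine grid so they can be profiled and
#' compared voxel-for-voxel against the micron-scale result.
#'
#' @param tf a fine-scale `tensor_field`.
#' @param block coarsening factor in voxels (250 at 2 um voxels ~ 500 um).
#' @param mask optional logical array restricting the block averages.
#' @param fa_floor passed to [smallest_eigenvector_field()].
#' @return an `orientation_field` on the fine grid.
#' @export
pseudo_lowres_orientation <- function(tf, block, mask = NULL, fa_floor = 0.1) {
  dims <- dim(tf)[1:3]
  ctf <- coarsen_tensor_field(tf, block, mask = mask)
  cof <- smallest_eigenvector_field(ctf, fa_floor = fa_floor)
  fine <- expand_blocks(unclass(cof), attr(ctf, "block"), dims)
  structure(fine, valid = array(is.finite(fine[, , , 1]), dims),
            voxel_size_um = voxel_size(tf), class = "orientation_field")
}

#' Angular error between two axial orientation fields
#'
#' Per-voxel acute angle `acos(|<v_est, v_true>|)` in degrees (0-90; the
#' axial equivalence v = -v is built in), summarized over a mask.
#'
#' @param est,truth orientation arrays `[y, x, z, 3]`.
#' @param mask logical array of voxels to evaluate; defaults to voxels
#'   where both fields are finite.
#' @return `list(mean_deg, sd_deg, map)` where `map` is the per-voxel
#'   error (NA outside the mask).
#' @export
angular_error <- function(est, truth, mask = NULL) {
  stopifnot(identical(dim(est)[1:3], dim(truth)[1:3]))
  d <- dim(est)[1:3]
  dotp <- channel(est, 1) * channel(truth, 1) +
          channel(est, 2) * channel(truth, 2) +
          channel(est, 3) * channel(truth, 3)
  ang <- acos(pmin(abs(dotp), 1)) * 180 / pi
  if (is.null(mask)) mask <- is.finite(ang)
  else mask <- mask & is.finite(ang)
  if (!any(mask)) stop("empty evaluation mask")
  map <- array(NA_real_, d)
  map[mask] <- ang[mask]
  list(mean_deg = mean(ang[mask]), sd_deg = stats::sd(ang[mask]), map = map)
}

#' Long-axis of a segmented cell from its voxel mask
#'
#' Principal eigenvector (largest eigenvalue) of the second-moment
#' (coordinate covariance) matrix of foreground voxel positions — the
#' standard ground-truth axis for a hand-segmented myocyte.
#'
#' @param cell_mask logical/0-1 3D array.
#' @return `list(axis = unit (x,y,z) vector, degenerate = flag)`;
#'   `degenerate` is TRUE for near-spherical masks whose axis is
#'   meaningless.
#' @export
cell_axis_from_mask <- function(cell_mask) {
  idx <- which(cell_mask != 0)
  if (length(idx) < 2L) stop("mask must contain at least two voxels")
  d <- dim(cell_mask)
  co <- arrayInd(idx, d)                      # (y, x, z)
  P <- cbind(x = co[, 2], y = co[, 1], z = co[, 3])
  C <- stats::cov(P)
  eg <- eigen(C, symmetric = TRUE)
  axis <- eg$vectors[, 1]
  axis <- axis / sqrt(sum(axis^2))
  if (axis[which(abs(axis) > 1e-12)[1]] < 0) axis <- -axis
  degenerate <- (eg$values[1] - eg$values[2]) / max(eg$values[1], 1e-300) < 0.05
  list(axis = axis, degenerate = degenerate)
}

#' Rotate a volume or vector field by 90 degrees about a grid axis
#'
#' Exact lattice rotation used for equivariance checks. `axis` names the
#' rotation axis in (x, y, z) terms; positive sense is right-handed.
#'
#' @param a 3D array (`[y,x,z]`) or 4D array with trailing (x,y,z)
#'   component channel.
#' @param axis `"x"`, `"y"`, or `"z"`.
#' @return rotated array; vector components are rotated too when present.
#' @export
rotate90 <- function(a, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  has_ch <- length(dim(a)) == 4L
  flip_axis <- function(a, ax) {
    idx <- rep(list(quote(expr = )), length(dim(a)))
    idx[[ax]] <- rev(seq_len(dim(a)[ax]))
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  rot_idx <- function(arr) {
    switch(axis,
      # right-handed +90 about z: (x,y) -> (-y, x)
      z = {
        p <- if (has_ch) c(2L, 1L, 3L, 4L) else c(2L, 1L, 3L)
        flip_axis(aperm(arr, p), 2L)
      },
      # +90 about x: (y,z) -> (-z, y)
      x = {
        p <- if (has_ch) c(3L, 2L, 1L, 4L) else c(3L, 2L, 1L)
        flip_axis(aperm(arr, p), 1L)
      },
      # +90 about y: (z,x) -> (-x, z)
      y = {
        p <- if (has_ch) c(1L, 3L, 2L, 4L) else c(1L, 3L, 2L)
        flip_axis(aperm(arr, p), 3L)
      })
  }
  out <- rot_idx(unclass(a))
  if (has_ch) {
    vx <- out[, , , 1]; vy <- out[, , , 2]; vz <- out[, , , 3]
    rot <- switch(axis,
      z = list(-vy, vx, vz),
      x = list(vx, -vz, vy),
      y = list(vz, vy, -vx))
    out[, , , 1] <- rot[[1]]; out[, , , 2] <- rot[[2]]; out[, , , 3] <- rot[[3]]
  }
  out
}
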