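# Visualization primitives: sub-sampled orientation glyphs and
# bidirectional, mask-bounded streamlines through the axial field.

#' Sub-sample an orientation field into glyphs
#'
#' Takes every `stride`-th voxel on a regular grid (valid voxels only);
#' if the result would exceed `max_vertices`, the stride is increased
#' minimally until it fits. The color scalar is the elevation angle
#' `phi = acos(|v_z|)` expressed in degrees, matching the convention of
#' coloring proportionally to the out-of-plane angle.
#'
#' @param field an `orientation_field` (array `[y,x,z,3]` with a `valid`
#'   attribute).
#' @param stride sampling stride in voxels (>= 1).
#' @param max_vertices hard cap on emitted glyphs.
#' @return a `glyph_set` data.frame: positions `x, y, z` (um), axial
#'   directions `dx, dy, dz`, `phi_deg`; attributes `stride_used`,
#'   `glyph_length_um`.
#' @export
sample_glyphs <- function(field, stride = 12, max_vertices = 75000) {
  stopifnot(stride >= 1)
  d <- dim(field)[1:3]
  vs <- voxel_size(field)
  valid <- attr(field, "valid")
  if (is.null(valid)) valid <- is.finite(unclass(field)[, , , 1])
  stride <- as.integer(stride)
  repeat {
    iy <- seq(1L, d[1], by = stride); ix <- seq(1L, d[2], by = stride); iz <- seq(1L, d[3], by = stride)
    sub_valid <- valid[iy, ix, iz, drop = FALSE]
    count <- sum(sub_valid)
    if (count <= max_vertices) break
    stride <- stride + 1L
  }
  if (count == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      dx = numeric(0), dy = numeric(0), dz = numeric(0),
                      phi_deg = numeric(0))
    return(structure(out, stride_used = stride, glyph_length_um = stride * vs * 0.8,
                     class = c("glyph_set", "data.frame")))
  }
  grid <- as.matrix(expand.grid(y = iy, x = ix, z = iz, KEEP.OUT.ATTRS = FALSE))
  keep <- which(as.logical(sub_valid))
  g <- grid[keep, , drop = FALSE]
  f <- unclass(field)
  lin <- (g[, 3] - 1) * d[1] * d[2] + (g[, 2] - 1) * d[1] + g[, 1]
  nvox <- prod(d)
  dx <- f[lin]; dy <- f[lin + nvox]; dz <- f[lin + 2 * nvox]
  out <- data.frame(x = g[, 2] * vs, y = g[, 1] * vs, z = g[, 3] * vs,
                    dx = dx, dy = dy, dz = dz,
                    phi_deg = acos(pmin(abs(dz), 1)) * 180 / pi)
  structure(out, stride_used = stride, glyph_length_um = stride * vs * 0.8,
            class = c("glyph_set", "data.frame"))
}

# trilinear (or nearest) interpolation of an axial field with sign
# alignment against reference directions. P: m x 3 voxel coords (y,x,z),
# Dref: m x 3 (x,y,z) unit vectors. Returns m x 3 vectors (zero rows where
# no valid support).
interp_axial <- function(field, valid, P, Dref, mode = "trilinear") {
  d <- dim(field)[1:3]
  f <- unclass(field)
  nvox <- prod(d)
  m <- nrow(P)
  out <- matrix(0, m, 3)
  gather <- function(iy, ix, iz) {
    ok <- iy >= 1 & iy <= d[1] & ix >= 1 & ix <= d[2] & iz >= 1 & iz <= d[3]
    v <- matrix(0, m, 3); vv <- logical(m)
    if (any(ok)) {
      lin <- (iz[ok] - 1) * d[1] * d[2] + (ix[ok] - 1) * d[1] + iy[ok]
      vx <- f[lin]; vy <- f[lin + nvox]; vz <- f[lin + 2 * nvox]
      good <- is.finite(vx) & valid[lin]
      v[ok, 1] <- ifelse(good, vx, 0)
      v[ok, 2] <- ifelse(good, vy, 0)
      v[ok, 3] <- ifelse(good, vz, 0)
      vv[ok] <- good
    }
    list(v = v, ok = vv)
  }
  if (mode == "nearest") {
    g <- gather(round(P[, 1]), round(P[, 2]), round(P[, 3]))
    sgn <- sign(rowSums(g$v * Dref)); sgn[sgn == 0] <- 1
    return(g$v * sgn)
  }
  f0 <- floor(P)
  t <- P - f0
  for (cy in 0:1) for (cx in 0:1) for (cz in 0:1) {
    w <- (cy * t[, 1] + (1 - cy) * (1 - t[, 1])) *
         (cx * t[, 2] + (1 - cx) * (1 - t[, 2])) *
         (cz * t[, 3] + (1 - cz) * (1 - t[, 3]))
    g <- gather(f0[, 1] + cy, f0[, 2] + cx, f0[, 3] + cz)
    sgn <- sign(rowSums(g$v * Dref)); sgn[sgn == 0] <- 1
    out <- out + g$v * (sgn * w)
  }
  out
}

#' Trace bidirectional streamlines through an axial orientation field
#'
#' Seeds are drawn uniformly (seeded RNG) from valid voxels inside the
#' mask. From each seed the field is integrated with a fixed step both
#' along and against the seed orientation; at every step the local axial
#' vectors are sign-aligned with the previous direction before advancing
#' (the continuity rule for axial data). A line terminates on leaving the
#' mask, entering an invalid region, exceeding `max_points` per
#' direction, or turning more than `angle_limit_deg` in one step. The two
#' half-lines are merged into a single polyline per seed, colored by the
#' elevation angle phi at the seed.
#'
#' @param field an `orientation_field`.
#' @param mask logical 3D array (boundary condition), same grid.
#' @param n_seeds number of seeds (capped at 25000).
#' @param step_um integration step (default: one voxel).
#' @param max_points cap on points per direction.
#' @param seed RNG seed.
#' @param mode `"trilinear"` (default) or `"nearest"` field lookup.
#' @param angle_limit_deg termination turning angle.
#' @return a `streamline_set`: `lines` (list of k x 3 matrices, (x,y,z)
#'   um), `seed_idx` (linear voxel index), `phi_deg` per line, `step_um`.
#' @export
trace_streamlines <- function(field, mask, n_seeds = 2000, step_um = NULL,
                              max_points = 500, seed = 1L,
                              mode = c("trilinear", "nearest"),
                              angle_limit_deg = 60) {
  mode <- match.arg(mode)
  d <- dim(field)[1:3]
  stopifnot(identical(dim(mask), d))
  vs <- voxel_size(field)
  if (is.null(step_um)) step_um <- vs
  stopifnot(step_um > 0)
  n_seeds <- min(n_seeds, 25000L)
  valid <- attr(field, "valid")
  if (is.null(valid)) valid <- is.finite(unclass(field)[, , , 1])
  pool <- which(valid & (mask != 0))
  if (!length(pool)) stop("no valid seed voxels inside the mask")
  seeds <- with_seed(seed, {
    if (length(pool) <= n_seeds) pool else sort(sample(pool, n_seeds))
  })
  co <- arrayInd(seeds, d)                     # (y, x, z)
  f <- unclass(field)
  nvox <- prod(d)
  v0 <- cbind(f[seeds], f[seeds + nvox], f[seeds + 2 * nvox])
  step_vox <- step_um / vs
  mask_l <- as.logical(mask)

  march <- function(dir0) {
    m <- nrow(co)
    pts <- array(NA_real_, c(m, max_points, 3))
    P <- co + 0.0
    D <- dir0
    npts <- integer(m)
    active <- rep(TRUE, m)
    coslim <- cos(angle_limit_deg * pi / 180)
    for (k in seq_len(max_points)) {
      if (!any(active)) break
      ia <- which(active)
      V <- interp_axial(field, valid, P[ia, , drop = FALSE], D[ia, , drop = FALSE], mode)
      nn <- sqrt(rowSums(V^2))
      okv <- nn > 1e-6
      V <- V / pmax(nn, 1e-12)
      if (mode == "trilinear") {
        # midpoint (RK2) update: plain Euler spirals outward on curved
        # fields by ~step^2/(2 r) per step, enough to leave a thin wall
        Pm <- P[ia, , drop = FALSE] + 0.5 * step_vox * V[, c(2, 1, 3), drop = FALSE]
        V2 <- interp_axial(field, valid, Pm, V, mode)
        n2 <- sqrt(rowSums(V2^2))
        use2 <- n2 > 1e-6
        V[use2, ] <- V2[use2, , drop = FALSE] / n2[use2]
      }
      turn_ok <- rowSums(V * D[ia, , drop = FALSE]) >= coslim
      # advance: displacement in voxel units, V is (x,y,z) -> P is (y,x,z)
      Pnew <- P[ia, , drop = FALSE] + step_vox * V[, c(2, 1, 3), drop = FALSE]
      iy <- round(Pnew[, 1]); ix <- round(Pnew[, 2]); iz <- round(Pnew[, 3])
      inside <- iy >= 1 & iy <= d[1] & ix >= 1 & ix <= d[2] & iz >= 1 & iz <= d[3]
      inmask <- rep(FALSE, length(ia))
      if (any(inside)) {
        lin <- (iz[inside] - 1) * d[1] * d[2] + (ix[inside] - 1) * d[1] + iy[inside]
        inmask[inside] <- mask_l[lin]
      }
      keep <- okv & turn_ok & inmask
      stopi <- ia[!keep]
      active[stopi] <- FALSE
      ga <- ia[keep]
      if (length(ga)) {
        P[ga, ] <- Pnew[keep, , drop = FALSE]
        D[ga, ] <- V[keep, , drop = FALSE]
        npts[ga] <- npts[ga] + 1L
        pts[cbind(rep(ga, 3), npts[ga], rep(1:3, each = length(ga)))] <-
          c(Pnew[keep, 2], Pnew[keep, 1], Pnew[keep, 3])  # store (x, y, z)
      }
    }
    list(pts = pts, npts = npts)
  }

  fw <- march(v0)
  bw <- march(-v0)
  lines <- vector("list", nrow(co))
  for (i in seq_len(nrow(co))) {
    nb <- bw$npts[i]; nf <- fw$npts[i]
    back <- if (nb) bw$pts[i, nb:1, , drop = FALSE] else NULL
    fwd <- if (nf) fw$pts[i, seq_len(nf), , drop = FALSE] else NULL
    seed_pt <- matrix(c(co[i, 2], co[i, 1], co[i, 3]), 1, 3)
    pl <- rbind(if (!is.null(back)) matrix(back, nb, 3), seed_pt,
                if (!is.null(fwd)) matrix(fwd, nf, 3))
    lines[[i]] <- pl * vs
  }
  phi <- acos(pmin(abs(v0[, 3]), 1)) * 180 / pi
  structure(list(lines = lines, seed_idx = seeds, phi_deg = phi,
                 step_um = step_um, voxel_size_um = vs),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  len <- vapply(x$lines, nrow, integer(1))
  cat(sprintf("<streamline_set> %d lines, %d-%d points, step %g um\n",
              length(x$lines), min(len), max(len), x$step_um))
  invisible(x)
}

#' Parula-like perceptual colormap
#'
#' Interpolated from the control points shipped in
#' `inst/extdata/parula_control_points.csv` (an approximation of the
#' familiar blue-to-yellow perceptual map).
#'
#' @param n number of colors.
#' @return character vector of hex colors.
#' @export
parula_colors <- function(n = 64) {
  path <- system.file("extdata", "parula_control_points.csv", package = "cardiofiber")
  cp <- utils::read.csv(path)
  ramp <- grDevices::colorRamp(grDevices::rgb(cp$r, cp$g, cp$b))
  cols <- ramp(seq(0, 1, length.out = n)) / 255
  grDevices::rgb(cols[, 1], cols[, 2], cols[, 3])
}
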