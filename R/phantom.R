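#' Phantom specification
#'
#' Bundles the geometric and imaging parameters of a synthetic
#' membrane-stained phantom. The defaults describe the annular
#' "ventricle wall" phantom used throughout the package's validation:
#' 2 um isotropic voxels, a 200 um thick wall (a scaled-down ventricle),
#' 12 um diameter fiber-aligned tubes whose bright membranes (2 um
#' thick, the only high-gradient structures) mimic a membrane-binding
#' stain, and a transmural helix-angle course running linearly from
#' -60 deg at the outer wall to +60 deg at the inner wall.
#'
#' `alpha_profile` maps normalized transmural depth d in [0, 1]
#' (0 = outer boundary) to helix angle in degrees; it may be a function
#' or a two-column matrix (depth, angle) interpolated linearly. When
#' `outer_layer` is set, the outermost `thickness_um` of the wall is
#' overridden with the constant `alpha_deg`, and the profile is mapped
#' over the remaining depth.
#'
#' @param shape integer grid dims `(ny, nx, nz)`.
#' @param voxel_size_um voxel edge length (um).
#' @param geometry `"helical_annulus"` or `"straight_bundle"`.
#' @param cell_radius_um tube (myocyte) radius; membrane spacing is twice this.
#' @param membrane_thickness_um bright-shell thickness; must be below
#'   `cell_radius_um`.
#' @param alpha_profile helix-angle course over normalized depth (see above).
#' @param outer_layer optional `list(thickness_um=, alpha_deg=)` constant band.
#' @param outer_radius_um,wall_thickness_um annulus geometry (um).
#' @param background,amplitude intensity plateau inside cells and membrane
#'   peak height above it.
#' @param rng_seed integer seed governing all stochastic degradation.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(320L, 320L, 48L),
                         voxel_size_um = 2,
                         geometry = c("helical_annulus", "straight_bundle"),
                         cell_radius_um = 6,
                         membrane_thickness_um = 2,
                         alpha_profile = function(d) -60 + 120 * d,
                         outer_layer = NULL,
                         outer_radius_um = 300,
                         wall_thickness_um = 200,
                         background = 10,
                         amplitude = 100,
                         rng_seed = 1L) {
  geometry <- match.arg(geometry)
  shape <- as.integer(rep_len(shape, 3L))
  stopifnot(all(shape > 0), membrane_thickness_um < cell_radius_um,
            wall_thickness_um < outer_radius_um)
  if (is.matrix(alpha_profile)) {
    tab <- alpha_profile
    alpha_profile <- stats::approxfun(tab[, 1], tab[, 2], rule = 2)
  }
  stopifnot(is.function(alpha_profile))
  av <- alpha_profile(seq(0, 1, length.out = 101))
  if (any(!is.finite(av)) || any(av < -90 - 1e-9) || any(av > 90 + 1e-9))
    stop("alpha_profile must map [0,1] to angles within [-90, 90] degrees")
  if (!is.null(outer_layer)) {
    stopifnot(is.list(outer_layer), !is.null(outer_layer$thickness_um),
              !is.null(outer_layer$alpha_deg),
              outer_layer$thickness_um < wall_thickness_um,
              abs(outer_layer$alpha_deg) <= 90)
  }
  structure(list(shape = shape, voxel_size_um = voxel_size_um,
                 geometry = geometry, cell_radius_um = cell_radius_um,
                 membrane_thickness_um = membrane_thickness_um,
                 alpha_profile = alpha_profile, outer_layer = outer_layer,
                 outer_radius_um = outer_radius_um,
                 wall_thickness_um = wall_thickness_um,
                 background = background, amplitude = amplitude,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# helix angle (deg) at transmural depth (um) under a spec, honoring the
# constant outer band when present
phantom_alpha_at_depth <- function(spec, depth_um) {
  wt <- spec$wall_thickness_um
  if (is.null(spec$outer_layer)) {
    a <- spec$alpha_profile(pmin(pmax(depth_um / wt, 0), 1))
  } else {
    t0 <- spec$outer_layer$thickness_um
    d <- pmin(pmax((depth_um - t0) / (wt - t0), 0), 1)
    a <- spec$alpha_profile(d)
    a[depth_um < t0] <- spec$outer_layer$alpha_deg
  }
  a
}

#' Helical annulus phantom
#'
#' Renders a cylindrical annulus (axis = z) in which the fiber direction at
#' normalized depth d is the local circumferential direction rotated by
#' `alpha_profile(d)` within the wall tangent plane. Membranes are drawn as
#' two families of bright sheets enclosing fiber-aligned tubes: concentric
#' cylindrical shells (always parallel to the fibers) and helical sheets
#' whose normals are perpendicular to the local fiber direction. The helical
#' family uses an integer azimuthal wavenumber per one-voxel radial shell so
#' the pattern is single-valued in the azimuth; inter-shell phase seams only
#' produce radial intensity gradients, which are perpendicular to the fiber
#' axis and therefore do not bias orientation recovery.
#'
#' @param spec a [phantom_spec()] with `geometry = "helical_annulus"`.
#' @return `list(volume = volume3d, truth = ground_truth)` where
#'   `ground_truth` holds `orientation` (`[y,x,z,3]`, unit (x,y,z) vectors),
#'   `mask` (in-wall logical), `alpha_true` (deg), `depth_um`, and the
#'   analytic frame used to prescribe the fibers.
#' @export
make_helical_annulus <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$geometry == "helical_annulus")
  vs <- spec$voxel_size_um
  d <- spec$shape
  r_out <- spec$outer_radius_um / vs
  wall_vox <- spec$wall_thickness_um / vs
  r_in <- r_out - wall_vox
  if (wall_vox < 4 * spec$cell_radius_um / vs)
    stop("wall thinner than two cell diameters: transmural profile unresolvable")
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  yy <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  xx <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  zz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  rr <- sqrt((xx - cx)^2 + (yy - cy)^2)
  phi <- atan2(yy - cy, xx - cx)
  inwall <- rr >= r_in & rr <= r_out
  depth_vox <- r_out - rr
  depth_um <- depth_vox * vs

  alpha <- array(NA_real_, d)
  alpha[inwall] <- phantom_alpha_at_depth(spec, depth_um[inwall])
  arad <- alpha * pi / 180

  # analytic wall frame: R inward, L = +z, C = L x R (right-handed C,L,R)
  # C = (sin phi, -cos phi, 0)
  orient <- array(NA_real_, c(d, 3L))
  ca <- cos(arad); sa <- sin(arad)
  orient[, , , 1] <- ca * sin(phi)
  orient[, , , 2] <- ca * -cos(phi)
  orient[, , , 3] <- sa

  spacing <- 2 * spec$cell_radius_um / vs        # membrane-to-membrane, voxels
  sig_m <- spec$membrane_thickness_um / vs / 2.355  # FWHM -> sigma
  cfreq <- 2 * pi / spacing

  # family 1: concentric shells at depth multiples of the tube spacing
  ph1 <- depth_vox %% spacing
  dist1 <- pmin(ph1, spacing - ph1)
  m1 <- exp(-dist1^2 / (2 * sig_m^2))

  # family 2: helical sheets, per-1-voxel-shell integer azimuthal wavenumber
  shell <- pmax(0L, pmin(as.integer(floor(depth_vox)), as.integer(ceiling(wall_vox))))
  shell[!inwall] <- NA_integer_
  m2 <- array(0, d)
  shells <- sort(unique(shell[!is.na(shell)]))
  # cells are not radially registered: each shell gets an independent
  # (seeded) azimuthal phase so sheet positions decorrelate across depth
  phases <- with_seed(spec$rng_seed,
                      stats::runif(length(shells), 0, 2 * pi))
  for (si in seq_along(shells)) {
    j <- shells[si]
    sel <- which(shell == j)
    r_sh <- r_out - (j + 0.5)
    a_sh <- phantom_alpha_at_depth(spec, (j + 0.5) * vs) * pi / 180
    # fiber u = cos(a) C + sin(a) L with C = -e_phi; a sheet normal
    # w = sin(a) e_phi + cos(a) e_z is perpendicular to u, giving
    # grad(psi) = (m/r) e_phi + q e_z with m ~ +c r sin(a)
    m_int <- round(cfreq * r_sh * sin(a_sh))
    if (m_int == 0) {
      q <- cfreq * cos(a_sh)   # sheets normal to z; exact once sin(a) ~ 0
    } else {
      q <- (m_int / r_sh) * cos(a_sh) / sin(a_sh)  # exact fiber-perpendicularity
    }
    psi <- m_int * phi[sel] + q * zz[sel] + phases[si]
    gnorm2 <- (m_int / r_sh)^2 + q^2           # |grad psi|^2, voxels^-2
    kappa <- 1 / (sig_m^2 * max(gnorm2, 1e-12))  # spatial sheet sigma = sig_m
    m2[sel] <- exp(kappa * (cos(psi) - 1))
  }

  img <- array(spec$background, d)
  memb <- pmax(m1, m2)
  img[inwall] <- spec$background + spec$amplitude * memb[inwall]

  truth <- structure(list(orientation = orient, mask = inwall,
                          alpha_true = alpha, depth_um = depth_um,
                          centroid_vox = c(y = cy, x = cx, z = (d[3] + 1) / 2),
                          geometry = "helical_annulus", spec = spec),
                     class = "ground_truth")
  list(volume = as_volume(img, vs), truth = truth)
}

#' Straight tube-bundle phantom
#'
#' Hexagonally packed hollow tubes along an arbitrary axis: dark interiors,
#' bright membranes where adjacent tube boundaries meet. The ground-truth
#' orientation equals the tube axis everywhere.
#'
#' @param spec a [phantom_spec()] with `geometry = "straight_bundle"`.
#' @param direction tube axis as an (x, y, z) vector (any norm > 0).
#' @return as [make_helical_annulus()].
#' @export
make_straight_bundle <- function(spec, direction = c(0, 0, 1)) {
  stopifnot(inherits(spec, "phantom_spec"), spec$geometry == "straight_bundle")
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("tube direction must have nonzero norm")
  u <- direction / nrm
  vs <- spec$voxel_size_um
  d <- spec$shape
  # orthonormal basis perpendicular to u
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p <- ref - sum(ref * u) * u; p <- p / sqrt(sum(p^2))
  q <- c(u[2] * p[3] - u[3] * p[2], u[3] * p[1] - u[1] * p[3], u[1] * p[2] - u[2] * p[1])

  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  yy <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d) - cy
  xx <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d) - cx
  zz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d) - cz
  a <- xx * p[1] + yy * p[2] + zz * p[3]
  b <- xx * q[1] + yy * q[2] + zz * q[3]

  s <- 2 * spec$cell_radius_um / vs            # center spacing, voxels
  # hex lattice basis e1 = (s, 0), e2 = (s/2, s*sqrt(3)/2)
  h <- s * sqrt(3) / 2
  n2 <- b / h
  n1 <- (a - n2 * s / 2) / s
  dist <- array(Inf, d)
  f1 <- floor(n1); f2 <- floor(n2)
  for (o1 in 0:1) for (o2 in 0:1) {
    k1 <- f1 + o1; k2 <- f2 + o2
    ca <- k1 * s + k2 * s / 2
    cb <- k2 * h
    dist <- pmin(dist, sqrt((a - ca)^2 + (b - cb)^2))
  }
  r_cell <- spec$cell_radius_um / vs
  sig_m <- spec$membrane_thickness_um / vs / 2.355
  img <- spec$background + spec$amplitude * exp(-(dist - r_cell)^2 / (2 * sig_m^2))

  orient <- array(NA_real_, c(d, 3L))
  orient[, , , 1] <- u[1]; orient[, , , 2] <- u[2]; orient[, , , 3] <- u[3]
  mask <- array(TRUE, d)
  truth <- structure(list(orientation = orient, mask = mask,
                          alpha_true = array(NA_real_, d), depth_um = NULL,
                          centroid_vox = c(y = cy, x = cx, z = cz),
                          geometry = "straight_bundle", spec = spec),
                     class = "ground_truth")
  list(volume = as_volume(img, vs), truth = truth)
}

#' Parametric Gaussian point spread function
#'
#' @param sigma_um per-axis standard deviation (x, y, z) in um (recycled).
#' @param voxel_size_um sampling pitch.
#' @param radius_vox half-size of the kernel (defaults to 3 sigma).
#' @return a `psf` object: odd-sized 3D array, nonnegative, unit sum.
#' @export
gaussian_psf <- function(sigma_um, voxel_size_um = 2, radius_vox = NULL) {
  s <- rep_len(sigma_um, 3L) / voxel_size_um
  if (is.null(radius_vox)) radius_vox <- pmax(1L, ceiling(3 * s))
  radius_vox <- rep_len(as.integer(radius_vox), 3L)
  # kernel stored [y, x, z]; sigma given (x, y, z)
  ky <- exp(-(seq(-radius_vox[2], radius_vox[2]))^2 / (2 * s[2]^2))
  kx <- exp(-(seq(-radius_vox[1], radius_vox[1]))^2 / (2 * s[1]^2))
  kz <- exp(-(seq(-radius_vox[3], radius_vox[3]))^2 / (2 * s[3]^2))
  k <- outer(outer(ky, kx), kz)
  k <- k / sum(k)
  structure(k, voxel_size_um = voxel_size_um, class = "psf")
}

#' Identity (delta) point spread function
#' @param voxel_size_um sampling pitch.
#' @export
identity_psf <- function(voxel_size_um = 2) {
  k <- array(0, c(3, 3, 3)); k[2, 2, 2] <- 1
  structure(k, voxel_size_um = voxel_size_um, class = "psf")
}

#' Apply imaging degradations to a clean phantom
#'
#' Blur by a PSF, attenuate with depth, then corrupt with Poisson shot
#' noise and additive Gaussian read noise. The attenuation is linear in z
#' from 1 at the shallowest slice to `attenuation_floor` at the deepest,
#' emulating signal loss at the deep end of a stack. Photon counting is
#' simulated by scaling the volume so its maximum maps to
#' `photons_at_peak` expected photons. All randomness is governed by
#' `seed`; the global RNG state is left untouched.
#'
#' @param vol a `volume3d`.
#' @param psf a `psf` or `NULL` (no blur). Normalized to unit sum.
#' @param photons_at_peak expected photon count at the brightest voxel
#'   (`Inf` disables shot noise).
#' @param read_noise_sd additive Gaussian sigma in input intensity units
#'   (0 disables).
#' @param attenuation_floor multiplicative factor at the deepest slice,
#'   in (0, 1].
#' @param seed integer seed.
#' @return degraded `volume3d`.
#' @export
degrade_volume <- function(vol, psf = NULL, photons_at_peak = 100,
                           read_noise_sd = 2, attenuation_floor = 1,
                           seed = 1L) {
  stopifnot(inherits(vol, "volume3d"))
  if (photons_at_peak <= 0 || read_noise_sd < 0)
    stop("noise parameters must be nonnegative (photons_at_peak > 0)")
  stopifnot(attenuation_floor > 0, attenuation_floor <= 1)
  a <- bare_array(vol)
  if (!is.null(psf)) {
    k <- unclass(psf)
    if (sum(k) <= 0) stop("PSF must have positive total weight")
    a <- conv3d_fft(a, k / sum(k))
    a[a < 0] <- 0
  }
  nz <- dim(a)[3]
  if (attenuation_floor < 1 && nz > 1) {
    f <- 1 + (attenuation_floor - 1) * (seq_len(nz) - 1) / (nz - 1)
    a <- sweep(a, 3L, f, "*")
  }
  if (is.finite(photons_at_peak) || read_noise_sd > 0) {
    a <- with_seed(seed, {
      out <- a
      if (is.finite(photons_at_peak)) {
        sc <- photons_at_peak / max(out)
        out <- stats::rpois(length(out), lambda = pmax(out * sc, 0)) / sc
        dim(out) <- dim(a)
      }
      if (read_noise_sd > 0)
        out <- out + array(stats::rnorm(length(out), sd = read_noise_sd), dim(a))
      out
    })
  }
  as_volume(a, voxel_size(vol))
}

#' Split a volume into overlapping tiles
#'
#' Emulates mosaic acquisition: tiles cover the volume with at least the
#' requested per-axis overlap between neighbors, and the true integer
#' offsets are recorded so stitching can be validated.
#'
#' @param vol a `volume3d`.
#' @param tile_shape integer `(ny, nx, nz)` tile dims; `NA` means the full
#'   extent along that axis.
#' @param overlap_fraction fraction of tile extent shared by neighbors,
#'   in (0, 0.9].
#' @return a `tile_set`: `tiles` (list of `volume3d`), `offsets`
#'   (N x 3 integer, 0-based `(y, x, z)` voxel positions), `full_dim`,
#'   `overlap_fraction`.
#' @export
tile_volume <- function(vol, tile_shape, overlap_fraction = 0.25) {
  stopifnot(inherits(vol, "volume3d"),
            overlap_fraction > 0, overlap_fraction <= 0.9)
  d <- dim(vol)
  tile_shape <- rep_len(as.integer(tile_shape), 3L)
  tile_shape[is.na(tile_shape)] <- d[is.na(tile_shape)]
  if (any(tile_shape > d)) {
    warning("tile larger than volume along some axis; emitting a single tile")
    tile_shape <- pmin(tile_shape, d)
  }
  starts_axis <- function(n, t) {
    if (t >= n) return(0L)
    stride <- max(1L, as.integer(floor(t * (1 - overlap_fraction))))
    s <- seq.int(0L, n - t, by = stride)
    if (s[length(s)] != n - t) s <- c(s, n - t)
    as.integer(s)
  }
  sy <- starts_axis(d[1], tile_shape[1])
  sx <- starts_axis(d[2], tile_shape[2])
  sz <- starts_axis(d[3], tile_shape[3])
  offs <- as.matrix(expand.grid(y = sy, x = sx, z = sz, KEEP.OUT.ATTRS = FALSE))
  a <- bare_array(vol)
  tiles <- lapply(seq_len(nrow(offs)), function(i) {
    o <- offs[i, ]
    as_volume(a[o[1] + seq_len(tile_shape[1]),
                o[2] + seq_len(tile_shape[2]),
                o[3] + seq_len(tile_shape[3]), drop = FALSE], voxel_size(vol))
  })
  structure(list(tiles = tiles, offsets = offs, tile_shape = tile_shape,
                 full_dim = d, overlap_fraction = overlap_fraction),
            class = "tile_set")
}
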