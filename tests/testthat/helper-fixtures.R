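# Shared fixtures. Heavy objects (the default-scale phantom pipelines used
# by the acceptance checks) are computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small annulus spec for fast unit tests (wall 26 voxels = 52 um)
small_annulus_spec <- function(...) {
  phantom_spec(shape = c(96L, 96L, 24L), outer_radius_um = 80,
               wall_thickness_um = 52, ...)
}

# default-conditions noisy linear-profile phantom, full orientation pipeline
acc_linear <- function() fixture("acc_linear", function() {
  spec <- phantom_spec(rng_seed = 1L)
  ph <- make_helical_annulus(spec)
  noisy <- degrade_volume(ph$volume, psf = gaussian_psf(2, spec$voxel_size_um),
                          photons_at_peak = 100, read_noise_sd = 2,
                          attenuation_floor = 0.6, seed = 1L)
  tf <- compute_structure_tensor(noisy)
  of <- smallest_eigenvector_field(tf)
  fa <- fractional_anisotropy(tf)
  frame <- build_wall_frame(ph$truth$mask, spec$voxel_size_um)
  ah <- compute_helix_angle(of, frame)
  m <- evaluation_mask(ph$truth, 6L) & attr(of, "valid") & ah$valid
  list(spec = spec, ph = ph, tf = tf, of = of, fa = fa, frame = frame,
       ah = ah, mask = m)
})

# default-conditions noisy phantom with the 50 um / 80 deg outer band
acc_banded <- function() fixture("acc_banded", function() {
  spec <- phantom_spec(outer_layer = list(thickness_um = 50, alpha_deg = 80),
                       rng_seed = 1L)
  ph <- make_helical_annulus(spec)
  noisy <- degrade_volume(ph$volume, psf = gaussian_psf(2, spec$voxel_size_um),
                          photons_at_peak = 100, read_noise_sd = 2,
                          attenuation_floor = 0.6, seed = 1L)
  tf <- compute_structure_tensor(noisy)
  of <- smallest_eigenvector_field(tf)
  frame <- build_wall_frame(ph$truth$mask, spec$voxel_size_um)
  ah <- compute_helix_angle(of, frame)
  m <- evaluation_mask(ph$truth, 6L) & attr(of, "valid") & ah$valid
  pooled <- sector_profile(list(alpha_h_deg = ifelse(m, ah$alpha_h_deg, NA), valid = m),
                           frame, sector_spec(wedge_width_deg = 360, wedges_combined = 1))
  list(spec = spec, ph = ph, tf = tf, of = of, frame = frame, ah = ah,
       mask = m, pooled = pooled)
})

# axial (mod-180) angular distance in degrees
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# independent brute-force eigensolver for symmetric 3x3 matrices:
# characteristic-polynomial roots (polyroot + Newton polish), eigenvectors
# from cross products of rows of (M - lambda I)
eig3_bruteforce <- function(M) {
  tr <- M[1, 1] + M[2, 2] + M[3, 3]
  m2 <- (M[1, 1] * M[2, 2] - M[1, 2]^2) + (M[1, 1] * M[3, 3] - M[1, 3]^2) +
        (M[2, 2] * M[3, 3] - M[2, 3]^2)
  dt <- det(M)
  # det(M - l I) = -l^3 + tr l^2 - m2 l + dt
  roots <- sort(Re(polyroot(c(dt, -m2, tr, -1))))
  p <- function(l) -l^3 + tr * l^2 - m2 * l + dt
  dp <- function(l) -3 * l^2 + 2 * tr * l - m2
  for (i in 1:3) for (it in 1:3) {
    if (abs(dp(roots[i])) > 1e-300) roots[i] <- roots[i] - p(roots[i]) / dp(roots[i])
  }
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  vecs <- sapply(roots, function(l) {
    A <- M - l * diag(3)
    cand <- list(cross(A[1, ], A[2, ]), cross(A[1, ], A[3, ]), cross(A[2, ], A[3, ]))
    nn <- vapply(cand, function(x) sum(x^2), numeric(1))
    v <- cand[[which.max(nn)]]
    v / sqrt(sum(v^2))
  })
  list(values = roots, vectors = vecs)
}

# circumferential (-sin phi, cos phi, 0) field on an annulus mask
circ_field <- function(dims = c(64L, 64L, 8L), r_in = 20, r_out = 28,
                       voxel_size_um = 2) {
  yy <- array(rep(seq_len(dims[1]), dims[2] * dims[3]), dims)
  xx <- array(rep(rep(seq_len(dims[2]), each = dims[1]), dims[3]), dims)
  cy <- (dims[1] + 1) / 2; cx <- (dims[2] + 1) / 2
  rr <- sqrt((xx - cx)^2 + (yy - cy)^2)
  phi <- atan2(yy - cy, xx - cx)
  f <- array(0, c(dims, 3L))
  f[, , , 1] <- -sin(phi); f[, , , 2] <- cos(phi)
  of <- structure(f, valid = array(TRUE, dims), voxel_size_um = voxel_size_um,
                  class = "orientation_field")
  list(field = of, mask = rr >= r_in & rr <= r_out, center = c(cx, cy),
       rr = rr)
}

uniform_field <- function(dims = c(30L, 30L, 30L), v = c(1, 0, 0),
                          voxel_size_um = 2) {
  f <- array(0, c(dims, 3L))
  f[, , , 1] <- v[1]; f[, , , 2] <- v[2]; f[, , , 3] <- v[3]
  structure(f, valid = array(TRUE, dims), voxel_size_um = voxel_size_um,
            class = "orientation_field")
}
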