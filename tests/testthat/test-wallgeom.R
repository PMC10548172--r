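make_annulus_mask <- function(d = c(64, 64, 8), r_in = 12, r_out = 26,
                              ab = c(1, 1)) {
  yy <- array(rep(seq_len(d[1]), d[2] * d[3]), d)
  xx <- array(rep(rep(seq_len(d[2]), each = d[1]), d[3]), d)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  rr <- sqrt(((xx - cx) / ab[1])^2 + ((yy - cy) / ab[2])^2)
  list(mask = rr >= r_in & rr <= r_out, xx = xx, yy = yy, cx = cx, cy = cy)
}

test_that("centroid estimation is exact and translation-equivariant", {
  disk <- make_annulus_mask(r_in = 0, r_out = 20)
  ce <- estimate_centroid(disk$mask, 2)
  expect_equal(unname(ce$vox[c("y", "x")]), c(32.5, 32.5), tolerance = 1e-9)
  # two off-centre blobs: weighted midpoint
  m <- array(FALSE, c(20, 20, 1))
  m[2:3, 2:3, 1] <- TRUE                      # 4 voxels at (2.5, 2.5)
  m[10:13, 14:17, 1] <- TRUE                  # 16 voxels at (11.5, 15.5)
  ce2 <- estimate_centroid(m, 2)
  expect_equal(unname(ce2$vox["y"]), (4 * 2.5 + 16 * 11.5) / 20)
  expect_equal(unname(ce2$vox["x"]), (4 * 2.5 + 16 * 15.5) / 20)
  # translation by (2, 3) voxels shifts the centroid by exactly that
  m2 <- array(FALSE, c(20, 20, 1)); m2[(2:3) + 2, (2:3) + 3, 1] <- TRUE
  m1 <- array(FALSE, c(20, 20, 1)); m1[2:3, 2:3, 1] <- TRUE
  expect_equal(estimate_centroid(m2, 2)$vox - estimate_centroid(m1, 2)$vox,
               c(y = 2, x = 3, z = 0))
  expect_error(estimate_centroid(array(FALSE, c(4, 4, 1))), "empty")
})

test_that("wall frames are orthonormal with inward penetration vectors", {
  an <- make_annulus_mask()
  fr <- build_wall_frame(an$mask, 2)
  v <- fr$valid
  expect_gt(sum(v), 1000)
  dot <- function(a, b) a[, , , 1] * b[, , , 1] + a[, , , 2] * b[, , , 2] + a[, , , 3] * b[, , , 3]
  expect_lt(max(abs(dot(fr$C, fr$L)[v])), 1e-6)
  expect_lt(max(abs(dot(fr$C, fr$R)[v])), 1e-6)
  expect_lt(max(abs(dot(fr$L, fr$R)[v])), 1e-6)
  nrm <- function(a) sqrt(dot(a, a))
  expect_lt(max(abs(nrm(fr$C)[v] - 1)), 1e-6)
  expect_lt(max(abs(nrm(fr$R)[v] - 1)), 1e-6)
  # R points toward the centre: R . (centre - position) > 0
  tox <- an$cx - an$xx; toy <- an$cy - an$yy
  inward <- fr$R[, , , 1] * tox + fr$R[, , , 2] * toy
  expect_true(all(inward[v] > 0))
  # on a circular annulus C is tangent (perpendicular to the radius), L = z;
  # evaluate on a mid-wall ring away from boundary pixelation
  tang <- abs(fr$C[, , , 1] * tox + fr$C[, , , 2] * toy) /
    sqrt(tox^2 + toy^2)
  ring <- v & sqrt(tox^2 + toy^2) > 16 & sqrt(tox^2 + toy^2) < 23
  expect_gt(sum(ring), 500)
  expect_lt(max(tang[ring]), 0.1)             # within ~6 degrees of tangent
  expect_lt(max(abs(abs(fr$L[, , , 3][v]) - 1)), 1e-6)
  expect_error(build_wall_frame(array(FALSE, c(8, 8, 2))), "empty")
})

test_that("elliptical annulus normals stay perpendicular to the outer boundary", {
  # nx must exceed the outer semi-major axis (1.6 * 24 = 38.4 voxels)
  an <- make_annulus_mask(d = c(120, 176, 6), r_in = 24, r_out = 48, ab = c(1.6, 1))
  # analytic mask: light normal smoothing preserves the curvature gradient
  fr <- build_wall_frame(an$mask, 2, normal_sigma_vox = 3)
  cx <- (dim(an$mask)[2] + 1) / 2; cy <- (dim(an$mask)[1] + 1) / 2
  # reference: direction from the nearest point on the analytic outer
  # ellipse to the voxel (the true inward distance-transform gradient)
  tt <- seq(0, 2 * pi, length.out = 8000)
  qx <- cx + 1.6 * 48 * cos(tt); qy <- cy + 48 * sin(tt)
  lv <- sqrt(((an$xx - cx) / 1.6)^2 + (an$yy - cy)^2)
  sel <- which(fr$valid & lv > 40 & lv < 46)
  co <- arrayInd(sel, dim(an$mask))
  ang <- vapply(seq_along(sel), function(i) {
    px <- co[i, 2]; py <- co[i, 1]
    j <- which.min((qx - px)^2 + (qy - py)^2)
    ref <- c(px - qx[j], py - qy[j])
    ref <- ref / sqrt(sum(ref^2))
    Rv <- c(fr$R[co[i, 1], co[i, 2], co[i, 3], 1], fr$R[co[i, 1], co[i, 2], co[i, 3], 2])
    acos(min(abs(sum(ref * Rv)), 1)) * 180 / pi
  }, numeric(1))
  expect_gt(length(sel), 200)
  expect_lt(stats::quantile(ang, 0.95), 3)
})

test_that("theta and phi follow the short-axis-plane conventions", {
  f <- array(0, c(1, 4, 1, 3))
  f[1, 1, 1, ] <- c(1, 0, 0)
  f[1, 2, 1, ] <- c(1, 1, 0) / sqrt(2)
  f[1, 3, 1, ] <- c(0, 0, 1)
  f[1, 4, 1, ] <- c(0.5, 0, sqrt(3) / 2)
  tp <- compute_theta_phi(f)
  expect_equal(tp$theta_deg[1, 1, 1], 0)
  expect_equal(tp$phi_deg[1, 1, 1], 0)
  expect_equal(tp$theta_deg[1, 2, 1], 45, tolerance = 1e-9)
  expect_equal(tp$phi_deg[1, 3, 1], 90)
  expect_false(tp$theta_valid[1, 3, 1])       # vertical vector: theta undefined
  expect_equal(tp$phi_deg[1, 4, 1], 60, tolerance = 1e-9)
})

test_that("helix angles follow the tangent-plane convention", {
  an <- make_annulus_mask()
  fr <- build_wall_frame(an$mask, 2)
  # v = C -> 0 deg; v = L -> +90; v = (C+L)/sqrt(2) -> 45; v = R -> flagged
  for (case in list(list(src = "C", want = 0), list(src = "L", want = 90),
                    list(src = "R", want = NA))) {
    f <- fr[[case$src]]
    ah <- compute_helix_angle(f, fr)
    if (is.na(case$want)) {
      expect_true(all(!ah$valid[fr$valid]))
    } else {
      expect_equal(max(abs(ah$alpha_h_deg[fr$valid] - case$want)), 0,
                   tolerance = 1e-6)
    }
  }
  mix <- fr$C
  mix[, , , ] <- (fr$C[, , , ] + fr$L[, , , ]) / sqrt(2)
  ahm <- compute_helix_angle(mix, fr)
  expect_equal(max(abs(ahm$alpha_h_deg[fr$valid] - 45)), 0, tolerance = 1e-6)
  # axial invariance: v and -v give the same angle
  ahn <- compute_helix_angle(-1 * mix, fr)
  expect_equal(ahm$alpha_h_deg[fr$valid], ahn$alpha_h_deg[fr$valid])
})

test_that("sector profiles are flat for constant fields and conserve voxels", {
  an <- make_annulus_mask()
  fr <- build_wall_frame(an$mask, 2)
  a30 <- array(NA_real_, dim(an$mask))
  a30[fr$valid] <- 30
  prof <- sector_profile(list(alpha_h_deg = a30, valid = fr$valid), fr)
  expect_true(all(abs(prof$mean_alpha_deg - 30) < 1e-9))
  expect_equal(sum(prof$n), sum(fr$valid))
  # wedge geometry: default 10-degree wedges combined in pairs -> 18 sectors
  expect_equal(sort(unique(prof$sector)), 0:17)
})

test_that("profile slopes and piecewise fits recover constructed shapes", {
  mk_prof <- function(y) {
    structure(data.frame(sector = 0L, depth_um = seq_along(y) * 2 - 1,
                         mean_alpha_deg = y, n = 50L),
              class = c("transmural_profile", "data.frame"))
  }
  # linear profile slope s -> constant s away from edges
  y <- seq(-40, 40, length.out = 50)           # slope: 80 deg over 98 um
  rc <- profile_rate_of_change(mk_prof(y), window_voxels = 15)
  s_true <- (y[2] - y[1]) / 2
  expect_lt(max(abs(rc$slope_deg_per_um - s_true)), 1e-9)
  # window of 15 bins at 2 um spacing spans 30 um
  expect_error(profile_rate_of_change(mk_prof(y[1:10]), window_voxels = 15),
               "shorter")

  # flat then steep: slope near 0, then near steep, transition within a window
  y2 <- c(rep(10, 30), 10 + seq(2, 60, by = 2))
  rc2 <- profile_rate_of_change(mk_prof(y2), window_voxels = 15)
  expect_lt(max(abs(rc2$slope_deg_per_um[rc2$depth_um < 30])), 1e-9)
  expect_equal(rc2$slope_deg_per_um[rc2$depth_um > 90], rep(1, sum(rc2$depth_um > 90)),
               tolerance = 1e-9)

  # exact two-segment input: flat 25 bins then slope 1 deg/um
  y3 <- c(rep(5, 25), 5 + seq(2, 50, by = 2))
  f2 <- piecewise_linear_fit(mk_prof(y3), n_segments = 2)
  expect_lt(abs(f2$breakpoints_um - 50), 2.1)  # breakpoint at bin 25 +/- 1
  expect_lt(abs(f2$segment_lengths_um[1] - 50), 2.1)
  expect_false(f2$degenerate)
  expect_equal(f2$slopes_deg_per_um[2], 1, tolerance = 1e-6)

  # pure line with two segments: equal slopes, degenerate flag
  fl <- piecewise_linear_fit(mk_prof(seq(0, 98, by = 2)), n_segments = 2)
  expect_lt(abs(diff(fl$slopes_deg_per_um)), 1e-6)
  expect_true(fl$degenerate)

  # noisy two-segment input: breakpoint within 3 bins
  set.seed(21)
  y4 <- y3 + stats::rnorm(length(y3), sd = 2)
  f4 <- piecewise_linear_fit(mk_prof(y4), n_segments = 2)
  expect_lt(abs(f4$breakpoints_um - 50), 3 * 2 + 1e-9)
})

test_that("axial unwrapping and band statistics handle the +/-90 wrap", {
  expect_equal(unwrap_axial(c(80, 88, -88, -80)), c(80, 88, 92, 100))
  expect_equal(unwrap_axial(c(-80, -89, 89, 80)), c(-80, -89, -91, -100))
  y <- c(rep(80, 10), seq(85, 115, by = 5) %% 180 - ifelse(seq(85, 115, by = 5) %% 180 > 90, 180, 0))
  prof <- structure(data.frame(sector = 0L, depth_um = seq_along(y) * 2 - 1,
                               mean_alpha_deg = y, n = 10L),
                    class = c("transmural_profile", "data.frame"))
  expect_equal(band_change_deg(prof, 20), 0)   # inside the flat band
  expect_gt(band_change_deg(prof, 34), 14)     # past the ramp start
})
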