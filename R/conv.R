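# Separable and FFT convolution primitives used throughout the package.
# Boundaries are handled by mirror reflection unless stated otherwise:
# stacks end abruptly at the coverslip and at depth, and reflective
# padding avoids the ringing that circular wrap-around would inject.

# 1D Gaussian taps, unit sum
gauss_kernel1d <- function(sigma, radius = max(1L, ceiling(3.5 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D Gaussian first-derivative taps. Convolution out(i) = sum_t k(t) f(i-t),
# so k(t) = -t g(t) / sum(t^2 g) makes the response to the ramp f(x)=x
# exactly +1 (true d/dx).
gauss_deriv_kernel1d <- function(sigma, radius = max(1L, ceiling(3.5 * sigma))) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  -x * g / sum(x^2 * g)
}

reflect_index <- function(i, n) {
  # mirror reflection without edge repetition (..3 2 1 2 3.. for n>=2)
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j[j < 0] <- j[j < 0] + p
  ifelse(j >= n, p - j, j) + 1L
}

# dense (n x n) matrix applying 1D convolution with reflect boundary
conv_matrix1d <- function(kernel, n) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  ii <- seq_len(n)
  for (t in seq_along(kernel)) {
    off <- t - r - 1L
    jj <- reflect_index(ii - off, n)   # true convolution: out(i) = sum k(t) f(i-t)
    idx <- cbind(ii, jj)
    K[idx] <- K[idx] + kernel[t]
  }
  K
}

# convolve a 3D array along one axis (1=y, 2=x, 3=z), reflect boundary
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  if (length(kernel) == 1L) return(a * kernel)
  K <- conv_matrix1d(kernel, d[axis])
  if (axis == 1L) {
    out <- K %*% matrix(a, d[1])
    dim(out) <- d
  } else {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    out <- K %*% matrix(ap, dp[1])
    dim(out) <- dp
    out <- aperm(out, order(perm))
  }
  out
}

# separable Gaussian smoothing, sigma per axis in voxels (length 1 or 3)
gauss_smooth3 <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 1e-8) a <- conv_axis(a, gauss_kernel1d(sigma_vox[ax]), ax)
  }
  a
}

# Gaussian-derivative gradient; returns components in (x, y, z) order.
# Storage is [y, x, z] so x varies along array axis 2, y along 1, z along 3.
gauss_gradient3 <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  dk <- lapply(sigma_vox, gauss_deriv_kernel1d)
  gk <- lapply(sigma_vox, gauss_kernel1d)
  one <- function(daxis) {
    out <- a
    for (ax in 1:3) {
      k <- if (ax == daxis) dk[[ax]] else gk[[ax]]
      out <- conv_axis(out, k, ax)
    }
    out
  }
  list(x = one(2L), y = one(1L), z = one(3L))
}

# reflect-pad a 3D array by r voxels per side (r length 3)
pad_reflect3 <- function(a, r) {
  r <- rep_len(as.integer(r), 3L)
  d <- dim(a)
  idx <- lapply(1:3, function(ax) reflect_index(seq(1L - r[ax], d[ax] + r[ax]), d[ax]))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# full 3D convolution with a small centred kernel via FFT, reflect boundary.
# Kernel dims must be odd.
conv3d_fft <- function(a, kernel, correlate = FALSE) {
  kd <- dim(kernel)
  stopifnot(all(kd %% 2L == 1L))
  if (correlate) kernel <- kernel[rev(seq_len(kd[1])), rev(seq_len(kd[2])), rev(seq_len(kd[3])), drop = FALSE]
  r <- (kd - 1L) %/% 2L
  ap <- pad_reflect3(a, r)
  dp <- dim(ap)
  kp <- array(0, dp)
  kp[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kernel
  # circular shift so kernel centre sits at index (1,1,1)
  for (ax in 1:3) {
    n <- dp[ax]
    sh <- ((seq_len(n) - 1L + r[ax]) %% n) + 1L
    kp <- switch(ax, kp[sh, , , drop = FALSE], kp[, sh, , drop = FALSE], kp[, , sh, drop = FALSE])
  }
  out <- Re(stats::fft(stats::fft(ap) * stats::fft(kp), inverse = TRUE)) / prod(dp)
  out[r[1] + seq_len(dim(a)[1]), r[2] + seq_len(dim(a)[2]), r[3] + seq_len(dim(a)[3]), drop = FALSE]
}
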