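# Separable 1D convolutions along array axes. Used by the Gaussian /
# Laplacian-of-Gaussian and wavelet filter implementations and by the
# phantom texture synthesis. Boundary handling is symmetric (half-sample
# mirror), which reproduces constants exactly.

# Convolve a 3D array with a 1D kernel along `axis`.
# `origin` is the (1-based) index of the kernel tap aligned with the output
# voxel; defaults to the centre for odd-length kernels.
conv_axis <- function(arr, kernel, axis, origin = (length(kernel) + 1L) %/% 2L) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  x <- aperm(arr, perm)
  dp <- dim(x)
  n <- dp[1]
  m <- prod(dp[2:3])
  dim(x) <- c(n, m)
  nk <- length(kernel)
  # symmetric (mirror) padding
  lpad <- origin - 1L
  rpad <- nk - origin
  top <- if (lpad > 0) x[pmin(n, pmax(1, lpad:1)), , drop = FALSE] else NULL
  bot <- if (rpad > 0) x[pmin(n, pmax(1, n:(n - rpad + 1L))), , drop = FALSE] else NULL
  xp <- rbind(top, x, bot)
  out <- matrix(0, n, m)
  for (t in seq_len(nk)) {
    if (kernel[t] == 0) next
    rows <- (t - 1L) + seq_len(n)
    out <- out + kernel[t] * xp[rows, , drop = FALSE]
  }
  dim(out) <- dp
  aperm(out, order(perm))
}

gauss_kernel <- function(sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Gaussian smoothing with per-axis sigma expressed in voxels.
gauss_smooth <- function(arr, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) arr <- conv_axis(arr, gauss_kernel(sigma_vox[ax]), ax)
  }
  arr
}

# Smooth standard-normal-ish random field on a grid, for phantom textures.
# Normalised to unit standard deviation after smoothing.
smooth_noise_field <- function(dims, sigma_vox) {
  f <- array(stats::rnorm(prod(dims)), dims)
  f <- gauss_smooth(f, sigma_vox)
  s <- stats::sd(f)
  if (s > 0) f / s else f
}
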