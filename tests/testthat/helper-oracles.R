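# Independent oracles and shared fixtures for the test suite. Oracles are
# written naively (explicit loops, definitional formulas) and must stay
# independent of the package implementation paths they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- ICC(1,1) oracle: definitional one-way ANOVA with explicit loops ------
naive_icc <- function(m, alpha = 0.05) {
  n <- nrow(m); k <- ncol(m)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + m[i, j]
  grand <- grand / (n * k)
  ssb <- 0
  for (i in 1:n) {
    mi <- 0
    for (j in 1:k) mi <- mi + m[i, j]
    mi <- mi / k
    ssb <- ssb + k * (mi - grand)^2
  }
  ssw <- 0
  for (i in 1:n) {
    mi <- mean(m[i, ])
    for (j in 1:k) ssw <- ssw + (m[i, j] - mi)^2
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  f0 <- msb / msw
  fl <- f0 / qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- f0 * qf(1 - alpha / 2, n * (k - 1), n - 1)
  list(estimate = (msb - msw) / (msb + (k - 1) * msw),
       ci_lower = (fl - 1) / (fl + k - 1),
       ci_upper = (fu - 1) / (fu + k - 1))
}

# --- grey-level co-occurrence oracle: brute-force pair enumeration --------
# Counts symmetric co-occurrences of grey levels (0 = outside ROI) for one
# direction by looping over every voxel.
brute_cooccurrence <- function(G, n_bins, d) {
  dm <- dim(G)
  C <- matrix(0, n_bins, n_bins)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    for (s in c(-1L, 1L)) {
      ii <- i + s * d[1]; jj <- j + s * d[2]; kk <- k + s * d[3]
      if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] || kk < 1 || kk > dm[3]) next
      g1 <- G[i, j, k]; g2 <- G[ii, jj, kk]
      if (g1 > 0 && g2 > 0) C[g1, g2] <- C[g1, g2] + 1
    }
  }
  C
}

# --- run-length oracle: brute-force line walking --------------------------
# Enumerates all runs (grey, length) along direction d by walking every
# line voxel by voxel; 0 marks out-of-ROI gaps.
brute_runs <- function(G, d) {
  dm <- dim(G)
  runs <- list()
  start_of_line <- function(i, j, k) {
    p <- c(i, j, k) - d
    p[1] < 1 || p[1] > dm[1] || p[2] < 1 || p[2] > dm[2] || p[3] < 1 || p[3] > dm[3]
  }
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!start_of_line(i, j, k)) next
    p <- c(i, j, k)
    cur_g <- 0L; cur_len <- 0L
    while (p[1] >= 1 && p[1] <= dm[1] && p[2] >= 1 && p[2] <= dm[2] &&
           p[3] >= 1 && p[3] <= dm[3]) {
      g <- G[p[1], p[2], p[3]]
      if (g == cur_g && g > 0L) {
        cur_len <- cur_len + 1L
      } else {
        if (cur_g > 0L) runs[[length(runs) + 1L]] <- c(cur_g, cur_len)
        cur_g <- g; cur_len <- if (g > 0L) 1L else 0L
      }
      p <- p + d
    }
    if (cur_g > 0L) runs[[length(runs) + 1L]] <- c(cur_g, cur_len)
  }
  do.call(rbind, runs)
}

# --- shared fixtures ------------------------------------------------------

# A small isotropic phantom subject: normalized T2w-like image plus the
# resampled ground-truth mask (both on the 2 mm grid) and the native mask.
small_subject <- function(seed, semi_axes = c(14, 12, 13)) {
  spec <- phantom_spec(semi_axes = semi_axes,
                       spacing = list(t2w = c(1.5, 1.5, 3),
                                      adc = c(2, 2, 3), dce = c(2, 2, 3)),
                       seed = seed)
  s <- generate_mpmri_phantom(spec)
  pp <- preprocess_config()
  img <- resample_image(s$t2w, pp, kind = "intensity")
  msk <- resample_image(s$t2w_mask, pp, kind = "mask")
  list(img = normalize_roi(img, msk, pp), mask = msk,
       native_mask = s$t2w_mask, subject = s, preprocess = pp)
}

# A block mask spanning axial slices `slices` of a small grid.
slab_mask <- function(slices, d = c(8, 8, 20), spacing = c(1, 1, 3)) {
  a <- array(0L, d)
  a[3:6, 3:6, slices] <- 1L
  mask3d(a, spacing)
}

slice_span <- function(mask) {
  range(which(apply(mask$data, 3, sum) > 0))
}

# 90-degree in-plane rotation of a 3D array (and masks/images built on it).
rot90_inplane <- function(v) {
  a <- aperm(v$data, c(2, 1, 3))
  a <- a[, dim(a)[2]:1, , drop = FALSE]
  if (inherits(v, "mask3d")) mask3d(a, v$spacing[c(2, 1, 3)], v$origin[c(2, 1, 3)])
  else vol3d(a, v$spacing[c(2, 1, 3)], v$origin[c(2, 1, 3)])
}
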