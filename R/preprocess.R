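#' Preprocessing configuration
#'
#' Settings of the image-processing chain applied before feature extraction:
#' resampling to an isotropic grid (cubic in-plane, nearest-neighbour
#' through-plane; masks nearest-neighbour throughout), z-scoring on the ROI
#' (or pooled across subjects for maps with absolute meaning such as the
#' apparent diffusion coefficient), clipping at `clip_sigma` standard
#' deviations and rescaling to mean 300 / sd 100 so that practically all
#' values land in `[0, 600]`. The dynamic series is split at the earliest
#' acquisition at or after `sub_split_time` seconds to form the wash-in and
#' wash-out subtraction maps.
#'
#' @param target_spacing isotropic target voxel size, mm (default 2).
#' @param clip_sigma z-score clip bound (default 3).
#' @param target_mean,target_std rescaled intensity mean / sd (300 / 100).
#' @param sub_split_time wash-in/wash-out split time, s (default 90).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = c(2, 2, 2), clip_sigma = 3,
                              target_mean = 300, target_std = 100,
                              sub_split_time = 90) {
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(target_spacing <= 0)) stop("`target_spacing` must be positive")
  if (clip_sigma <= 0) stop("`clip_sigma` must be positive")
  if (target_std <= 0) stop("`target_std` must be positive")
  structure(list(target_spacing = target_spacing, clip_sigma = clip_sigma,
                 target_mean = target_mean, target_std = target_std,
                 sub_split_time = sub_split_time),
            class = "preprocess_config")
}

#' Apparent diffusion coefficient map from a diffusion-weighted stack
#'
#' Per voxel, fits an ordinary least-squares straight line through
#' `(b, ln S(b))` and returns the negative slope, i.e. the decay rate of the
#' mono-exponential model `S(b) = S0 exp(-b * ADC)`. The fit is exact when
#' the signals are exactly mono-exponential. Non-positive samples are
#' excluded voxelwise; voxels retaining fewer than two positive samples are
#' set to 0 and counted in the `qc` attribute.
#'
#' @param dwi_stack list of `vol3d`, one per b-value, on one grid.
#' @param b_values numeric b-values in s/mm^2 (>= 2 distinct).
#' @return `vol3d` of ADC values (mm^2/s) with attribute
#'   `qc = list(n_degenerate)`.
#' @export
compute_adc_map <- function(dwi_stack, b_values) {
  b_values <- as.numeric(b_values)
  if (length(dwi_stack) != length(b_values))
    stop("one volume per b-value required")
  if (length(unique(b_values)) < 2L) stop("need >= 2 distinct b-values")
  ref <- dwi_stack[[1]]
  for (v in dwi_stack[-1]) if (!same_grid(ref, v)) stop("DWI frames must share one grid")
  S <- vapply(dwi_stack, function(v) as.vector(v$data),
              numeric(length(ref$data)))
  nb <- length(b_values)
  adc <- numeric(nrow(S))
  pos <- S > 0
  all_pos <- rowSums(pos) == nb
  bc <- b_values - mean(b_values)
  ssb <- sum(bc^2)
  if (any(all_pos)) {
    Y <- log(S[all_pos, , drop = FALSE])
    adc[all_pos] <- -as.vector(Y %*% bc) / ssb
  }
  n_degenerate <- 0L
  bad <- which(!all_pos)
  for (i in bad) {
    keep <- pos[i, ]
    if (sum(keep) >= 2L) {
      bi <- b_values[keep]
      yi <- log(S[i, keep])
      adc[i] <- -sum((bi - mean(bi)) * (yi - mean(yi))) / sum((bi - mean(bi))^2)
    } else {
      adc[i] <- 0
      n_degenerate <- n_degenerate + 1L
    }
  }
  out <- vol3d(array(adc, dim(ref$data)), ref$spacing, ref$origin)
  attr(out, "qc") <- list(n_degenerate = n_degenerate)
  out
}

#' Wash-in and wash-out subtraction maps from a dynamic series
#'
#' Splits the dynamic acquisition at the earliest frame acquired at or after
#' `sub_split_time` (i.e. at `90 + eps` seconds with `eps >= 0`):
#' wash-in = frame(split) - frame(first), wash-out = frame(last) -
#' frame(split).
#'
#' @param dce a [dyn_series()] with >= 3 frames.
#' @param config a [preprocess_config()].
#' @return list with `sub_win`, `sub_wout` (both `vol3d`) and `split_time`.
#' @export
compute_sub_maps <- function(dce, config = preprocess_config()) {
  stopifnot(inherits(dce, "dyn_series"))
  n <- length(dce$frames)
  if (n < 3L) stop("need >= 3 frames to form subtraction maps")
  idx <- which(dce$times >= config$sub_split_time)
  if (length(idx) == 0L || idx[1] == n)
    stop("no frame at or after the split time strictly before the last frame")
  s <- idx[1]
  if (s == 1L) stop("split frame must lie strictly after the first frame")
  g <- dce$frames[[1]]
  win <- dce$frames[[s]]$data - dce$frames[[1]]$data
  wout <- dce$frames[[n]]$data - dce$frames[[s]]$data
  list(sub_win = vol3d(win, g$spacing, g$origin),
       sub_wout = vol3d(wout, g$spacing, g$origin),
       split_time = dce$times[s])
}

# Natural cubic-spline interpolation weight matrix from source coordinates
# `x_old` to targets `x_new` (clamped to the source range, no extrapolation).
# Interpolation is linear in the data, so resampling one axis is a single
# matrix product.
spline_weights <- function(x_old, x_new) {
  n <- length(x_old)
  x_new <- pmin(max(x_old), pmax(min(x_old), x_new))
  if (n == 1L) return(matrix(1, length(x_new), 1))
  if (n < 4L) {
    # too few samples for a cubic: fall back to linear weights
    W <- matrix(0, length(x_new), n)
    for (t in seq_along(x_new)) {
      j <- max(1L, min(n - 1L, findInterval(x_new[t], x_old)))
      f <- (x_new[t] - x_old[j]) / (x_old[j + 1] - x_old[j])
      W[t, j] <- 1 - f; W[t, j + 1] <- f
    }
    return(W)
  }
  W <- matrix(0, length(x_new), n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    W[, j] <- stats::splinefun(x_old, e, method = "natural")(x_new)
  }
  W
}

nn_index <- function(x_old, x_new) {
  sp <- if (length(x_old) > 1) x_old[2] - x_old[1] else 1
  idx <- round((x_new - x_old[1]) / sp) + 1L
  pmin(length(x_old), pmax(1L, idx))
}

resample_axis_matrix <- function(arr, W, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  x <- aperm(arr, perm)
  dp <- dim(x)
  dim(x) <- c(dp[1], prod(dp[2:3]))
  y <- W %*% x
  dim(y) <- c(nrow(W), dp[2], dp[3])
  aperm(y, order(perm))
}

#' Resample a volume to the target isotropic spacing
#'
#' Intensity images are resampled in two passes: the in-plane axes with a
#' cubic spline interpolant, then the through-plane axis with nearest
#' neighbour (avoiding interpolation artefacts across thick slices). Masks
#' are resampled with nearest neighbour on all three axes and stay binary.
#'
#' @param img a `vol3d` or `mask3d`.
#' @param config a [preprocess_config()].
#' @param kind `"intensity"` or `"mask"`; defaults to `"mask"` for `mask3d`
#'   input.
#' @return resampled volume at `config$target_spacing`.
#' @export
resample_image <- function(img, config = preprocess_config(),
                           kind = if (inherits(img, "mask3d")) "mask" else "intensity") {
  stopifnot(inherits(img, "vol3d"))
  kind <- match.arg(kind, c("intensity", "mask"))
  sp_new <- config$target_spacing
  d <- dim(img$data)
  n_new <- pmax(1L, as.integer(round(d * img$spacing / sp_new)))
  coords_old <- lapply(1:3, function(ax) axis_coords(img, ax))
  coords_new <- lapply(1:3, function(ax) img$origin[ax] + (seq_len(n_new[ax]) - 1) * sp_new[ax])
  arr <- img$data
  if (kind == "intensity") {
    arr <- resample_axis_matrix(arr, spline_weights(coords_old[[1]], coords_new[[1]]), 1)
    arr <- resample_axis_matrix(arr, spline_weights(coords_old[[2]], coords_new[[2]]), 2)
    arr <- arr[, , nn_index(coords_old[[3]], coords_new[[3]]), drop = FALSE]
    dim(arr) <- n_new
    vol3d(arr, sp_new, img$origin)
  } else {
    arr <- arr[nn_index(coords_old[[1]], coords_new[[1]]), ,
               , drop = FALSE]
    arr <- arr[, nn_index(coords_old[[2]], coords_new[[2]]), , drop = FALSE]
    arr <- arr[, , nn_index(coords_old[[3]], coords_new[[3]]), drop = FALSE]
    dim(arr) <- n_new
    mask3d(arr, sp_new, img$origin)
  }
}

# Shared z-score / clip / rescale step.
affine_clip_rescale <- function(img, mu, sd, config) {
  z <- (img$data - mu) / sd
  n_clipped <- sum(abs(z) > config$clip_sigma)
  z[z > config$clip_sigma] <- config$clip_sigma
  z[z < -config$clip_sigma] <- -config$clip_sigma
  out <- vol3d(z * config$target_std + config$target_mean,
               img$spacing, img$origin)
  attr(out, "qc") <- list(n_clipped = n_clipped,
                          clip_fraction = n_clipped / length(z))
  out
}

#' Normalize a volume using its own ROI statistics
#'
#' z-scores the whole image with the mean and standard deviation of the
#' voxels inside `mask`, clips at `clip_sigma`, then rescales to
#' mean `target_mean` / sd `target_std`. When no ROI voxel is clipped the
#' ROI of the output has mean 300 and sd 100 exactly (to float tolerance),
#' and all output values lie in `[0, 600]` by construction.
#'
#' @param img a `vol3d`.
#' @param mask a [mask3d()] on the same grid (non-empty).
#' @param config a [preprocess_config()].
#' @return normalized `vol3d` with a `qc` attribute (clip counts).
#' @export
normalize_roi <- function(img, mask, config = preprocess_config()) {
  stopifnot(inherits(img, "vol3d"), inherits(mask, "mask3d"))
  if (!same_grid(img, mask)) stop("image and mask must share one grid")
  vals <- img$data[mask$data > 0]
  if (length(vals) == 0L) stop("ROI is empty")
  mu <- mean(vals); sd <- stats::sd(vals)
  if (!is.finite(sd) || sd == 0) stop("ROI standard deviation is zero")
  affine_clip_rescale(img, mu, sd, config)
}

#' Normalize a cohort with pooled ROI statistics
#'
#' For maps whose intensities carry absolute meaning across subjects, one
#' mean/sd pair is computed over the pooled ROI voxels of all subjects and
#' the identical affine map (with clipping) is applied to every volume.
#'
#' @param imgs list of `vol3d`.
#' @param masks list of [mask3d()], parallel to `imgs`.
#' @param config a [preprocess_config()].
#' @return list of normalized `vol3d`, with the pooled statistics attached
#'   as attributes `pooled_mean` / `pooled_sd`.
#' @export
normalize_population <- function(imgs, masks, config = preprocess_config()) {
  if (length(imgs) != length(masks) || length(imgs) < 1L)
    stop("need parallel non-empty lists of images and masks")
  vals <- unlist(lapply(seq_along(imgs), function(i) {
    if (!same_grid(imgs[[i]], masks[[i]]))
      stop("image/mask grid mismatch for subject ", i)
    imgs[[i]]$data[masks[[i]]$data > 0]
  }))
  if (length(vals) == 0L) stop("pooled ROI is empty")
  mu <- mean(vals); sd <- stats::sd(vals)
  if (!is.finite(sd) || sd == 0) stop("pooled ROI standard deviation is zero")
  out <- lapply(imgs, affine_clip_rescale, mu = mu, sd = sd, config = config)
  attr(out, "pooled_mean") <- mu
  attr(out, "pooled_sd") <- sd
  out
}
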