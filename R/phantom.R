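#' Phantom specification
#'
#' Describes a prostate-scale synthetic subject: an irregular ellipsoidal
#' gland voxelised on one grid per MRI sequence, with textured intensities,
#' a mono-exponential diffusion signal and a gamma-variate dynamic
#' contrast-enhancement curve. The defaults mirror a standard multi-parametric
#' prostate protocol: T2w 0.297 x 0.297 x 3 mm, DWI 1.25 x 1.25 x 3 mm with
#' b = 0/1500/2000 s/mm^2, DCE 1.136 x 1.136 x 3 mm sampled every 10 s over
#' 0..180 s, and a gland of semi-axes 22.5 x 19 x 20 mm.
#'
#' @param semi_axes numeric length-3, ellipsoid semi-axes in mm.
#' @param surface_irregularity amplitude in `[0, 0.2]` of the band-limited
#'   radial modulation applied to the ellipsoid surface (0 = exact ellipsoid).
#' @param spacing named list of per-sequence voxel spacings (mm).
#' @param grid_shape optional named list of voxel counts per sequence;
#'   `NULL` = smallest grid containing the gland plus a 6 mm margin.
#' @param dce_times DCE acquisition times in seconds, strictly increasing and
#'   spanning the 90 s wash-in/wash-out split.
#' @param dce_peak_time time-to-peak (s) of the enhancement curve.
#' @param b_values diffusion weightings in s/mm^2 (>= 2 distinct values).
#' @param noise_sd additive Gaussian noise sd on synthesised signals
#'   (0 = noise-free, the default).
#' @param seed RNG seed controlling surface irregularity and textures.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes = c(22.5, 19, 20),
                         surface_irregularity = 0.1,
                         spacing = list(t2w = c(0.297, 0.297, 3),
                                        adc = c(1.25, 1.25, 3),
                                        dce = c(1.136, 1.136, 3)),
                         grid_shape = NULL,
                         dce_times = seq(0, 180, by = 10),
                         dce_peak_time = 75,
                         b_values = c(0, 1500, 2000),
                         noise_sd = 0,
                         seed = 1L) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("`semi_axes` must be 3 positive lengths in mm")
  if (surface_irregularity < 0 || surface_irregularity > 0.2)
    stop("`surface_irregularity` must lie in [0, 0.2]")
  if (!is.list(spacing) || is.null(names(spacing)))
    stop("`spacing` must be a named list of voxel sizes")
  for (sp in spacing) {
    if (length(sp) != 3L || any(sp <= 0)) stop("each spacing must be 3 positive mm values")
  }
  dce_times <- as.numeric(dce_times)
  if (any(diff(dce_times) <= 0))
    stop("`dce_times` must be strictly increasing")
  if (min(dce_times) >= 90 || max(dce_times) <= 90)
    stop("`dce_times` must span the 90 s split point")
  b_values <- sort(as.numeric(b_values))
  if (length(b_values) < 2L || anyDuplicated(b_values) || any(b_values < 0))
    stop("`b_values` must be >= 2 distinct non-negative values")
  structure(list(semi_axes = semi_axes,
                 surface_irregularity = surface_irregularity,
                 spacing = spacing, grid_shape = grid_shape,
                 dce_times = dce_times, dce_peak_time = dce_peak_time,
                 b_values = b_values, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Band-limited radial modulation on the unit sphere: a short sum of random
# plane-wave cosines of low spatial frequency, normalised so |f| <= 1.
# Returned as a closure mapping an n x 3 matrix of unit directions to [-1,1].
radial_modulation <- function(n_modes = 6, freq_range = c(1.5, 3.5)) {
  amp <- stats::rnorm(n_modes)
  phase <- stats::runif(n_modes, 0, 2 * pi)
  dirs <- matrix(stats::rnorm(3 * n_modes), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  freq <- stats::runif(n_modes, freq_range[1], freq_range[2])
  k <- dirs * freq
  norm <- sum(abs(amp))
  function(u) {
    acc <- 0
    for (m in seq_len(n_modes)) {
      acc <- acc + amp[m] * cos(u %*% k[m, ] + phase[m])
    }
    as.vector(acc) / norm
  }
}

phantom_grid <- function(spec, sequence) {
  sp <- spec$spacing[[sequence]]
  if (is.null(sp)) stop("no spacing defined for sequence: ", sequence)
  if (!is.null(spec$grid_shape) && !is.null(spec$grid_shape[[sequence]])) {
    dims <- as.integer(spec$grid_shape[[sequence]])
  } else {
    margin <- 6
    extent <- 2 * spec$semi_axes * (1 + spec$surface_irregularity) + 2 * margin
    dims <- as.integer(ceiling(extent / sp))
  }
  # centre the gland on the grid: origin such that physical centre is 0
  origin <- -(dims - 1) * sp / 2
  list(dims = dims, spacing = sp, origin = origin)
}

# Voxelise the irregular ellipsoid on a grid. `fmod` is the radial
# modulation closure (shared across sequences for one subject).
voxelize_gland <- function(spec, grid, fmod) {
  d <- grid$dims
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  ax <- spec$semi_axes
  inside <- array(FALSE, d)
  amp <- spec$surface_irregularity
  for (k in seq_len(d[3])) {
    pg <- cbind(rep(xs, times = d[2]), rep(ys, each = d[1]), zs[k])
    w <- sweep(pg, 2, ax, "/")
    r <- sqrt(rowSums(w^2))
    if (amp > 0) {
      nz <- r > 0
      rs <- rep(1, length(r))
      u <- w[nz, , drop = FALSE] / r[nz]
      rs[nz] <- 1 + amp * fmod(u)
      inside[, , k] <- matrix(r <= rs, d[1], d[2])
    } else {
      inside[, , k] <- matrix(r <= 1, d[1], d[2])
    }
  }
  inside
}

#' Generate a phantom gland mask
#'
#' Voxelises the (optionally irregular) ellipsoidal gland of a
#' [phantom_spec()] on the grid of one sequence. The result is a single
#' connected, centred foreground component whose volume tracks the analytic
#' ellipsoid volume `4/3 pi a b c`.
#'
#' @param spec a [phantom_spec()].
#' @param sequence which sequence grid to voxelise on (name into
#'   `spec$spacing`).
#' @return a [mask3d()].
#' @examples
#' m <- generate_phantom_mask(phantom_spec(seed = 7), sequence = "adc")
#' mask_volume(m) / (4 / 3 * pi * prod(c(22.5, 19, 20)))
#' @export
generate_phantom_mask <- function(spec, sequence = "t2w") {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- phantom_grid(spec, sequence)
  reach <- spec$semi_axes * (1 + spec$surface_irregularity)
  half_extent <- (grid$dims - 1) * grid$spacing / 2
  if (any(reach > half_extent + grid$spacing / 2))
    stop("gland exceeds the grid: enlarge `grid_shape` or reduce `semi_axes`")
  fmod <- withr_seed(spec$seed, radial_modulation())
  inside <- voxelize_gland(spec, grid, fmod)
  if (!any(inside)) stop("gland voxelised to an empty mask; refine the grid")
  mask3d(array(as.integer(inside), grid$dims), grid$spacing, grid$origin)
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the
# caller's RNG state afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gamma-variate enhancement curve, unit peak at `tp`, onset at t = 0.
gamma_variate <- function(t, tp, shape = 2) {
  y <- numeric(length(t))
  pos <- t > 0
  y[pos] <- (t[pos] / tp)^shape * exp(shape * (1 - t[pos] / tp))
  y
}

#' Generate a full multi-parametric phantom subject
#'
#' Produces, for one [phantom_spec()]:
#' * `t2w`: smooth random texture with distinct in-gland / background means;
#' * `dwi`: one frame per b-value following `S(b) = S0 exp(-b * A)` with a
#'   spatially varying diffusion coefficient `A` around 1.2e-3 mm^2/s
#'   (returned as `adc_truth` for oracle checks);
#' * `dce`: a [dyn_series()] whose in-gland voxels follow a gamma-variate
#'   rise-then-decay enhancement, so wash-in and wash-out subtractions are
#'   both non-zero;
#' * one gland mask voxelised on each sequence grid.
#'
#' All outputs are deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `t2w`, `dwi` (list of `vol3d`, named by
#'   b-value), `dce` (`dyn_series`), `adc_truth`, and masks `t2w_mask`,
#'   `dwi_mask`, `dce_mask`.
#' @export
generate_mpmri_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr_seed(spec$seed, {
    fmod <- radial_modulation()
    g_t2 <- phantom_grid(spec, "t2w")
    g_dwi <- phantom_grid(spec, "adc")
    g_dce <- phantom_grid(spec, "dce")
    in_t2 <- voxelize_gland(spec, g_t2, fmod)
    in_dwi <- voxelize_gland(spec, g_dwi, fmod)
    in_dce <- voxelize_gland(spec, g_dce, fmod)

    tex_sigma <- 3  # mm correlation length of the textures
    fld <- function(grid) smooth_noise_field(grid$dims, tex_sigma / grid$spacing)

    # T2w: background 150, gland 400, textured
    t2 <- 150 + 250 * in_t2 + 40 * fld(g_t2)
    t2[t2 < 1] <- 1
    if (spec$noise_sd > 0) t2 <- t2 + stats::rnorm(length(t2), sd = spec$noise_sd)

    # DWI: mono-exponential decay, gland A ~ 1.2e-3 mm^2/s, background faster
    A <- 2.0e-3 + (1.2e-3 - 2.0e-3) * in_dwi + 0.15e-3 * fld(g_dwi) * in_dwi
    A[A < 0.2e-3] <- 0.2e-3
    S0 <- 800 * (1 + 0.15 * fld(g_dwi))
    S0[S0 < 50] <- 50
    dwi <- lapply(spec$b_values, function(b) {
      s <- S0 * exp(-b * A)
      if (spec$noise_sd > 0) s <- s + stats::rnorm(length(s), sd = spec$noise_sd)
      vol3d(array(s, g_dwi$dims), g_dwi$spacing, g_dwi$origin)
    })
    names(dwi) <- paste0("b", spec$b_values)

    # DCE: baseline + gamma-variate enhancement (strong in gland)
    base <- 200 * (1 + 0.15 * fld(g_dce))
    base[base < 20] <- 20
    amp <- (60 + 300 * in_dce) * (1 + 0.25 * pmax(-0.9, fld(g_dce)))
    curve <- gamma_variate(spec$dce_times, spec$dce_peak_time)
    frames <- lapply(seq_along(spec$dce_times), function(i) {
      s <- base + amp * curve[i]
      if (spec$noise_sd > 0) s <- s + stats::rnorm(length(s), sd = spec$noise_sd)
      vol3d(array(s, g_dce$dims), g_dce$spacing, g_dce$origin)
    })

    list(t2w = vol3d(array(t2, g_t2$dims), g_t2$spacing, g_t2$origin),
         dwi = dwi,
         dce = dyn_series(frames, spec$dce_times),
         adc_truth = vol3d(array(A, g_dwi$dims), g_dwi$spacing, g_dwi$origin),
         t2w_mask = mask3d(array(as.integer(in_t2), g_t2$dims), g_t2$spacing, g_t2$origin),
         dwi_mask = mask3d(array(as.integer(in_dwi), g_dwi$dims), g_dwi$spacing, g_dwi$origin),
         dce_mask = mask3d(array(as.integer(in_dce), g_dce$dims), g_dce$spacing, g_dce$origin))
  })
}

#' Write a phantom subject to a directory as NIfTI files
#'
#' @param subject output of [generate_mpmri_phantom()].
#' @param dir output directory (created if needed).
#' @param stem filename prefix.
#' @return `dir`, invisibly.
#' @export
write_phantom_subject <- function(subject, dir, stem = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(dir, paste0(stem, "_", x))
  write_nifti(subject$t2w, p("t2w.nii.gz"))
  write_nifti(subject$t2w_mask, p("t2w_mask.nii.gz"))
  for (nm in names(subject$dwi)) write_nifti(subject$dwi[[nm]], p(paste0("dwi_", nm, ".nii.gz")))
  write_nifti(subject$dwi_mask, p("dwi_mask.nii.gz"))
  write_dyn_series(subject$dce, p("dce.nii.gz"))
  write_nifti(subject$dce_mask, p("dce_mask.nii.gz"))
  invisible(dir)
}
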