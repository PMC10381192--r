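#' Contour augmentation configuration
#'
#' Parameters of the in silico contour generator. Each synthetic contour is
#' one simulated "rater": axial slices of a mask are perturbed in-plane by
#' bounded width/height changes (`dw`, `dh`, drawn uniformly within
#' `[-dw_bound, +dw_bound]` mm) and a small rotation about the slice centroid
#' (`alpha` within +/- `alpha_bound` degrees), and/or out-of-plane by shifting
#' the superior and inferior boundary-slice choice by at most
#' `slice_shift_max` slices. Under `bias = "random"` every slice draws its
#' perturbation independently; under `bias = "systematic"` the signs of `dw`,
#' `dh` and `alpha` are fixed per contour (a consistently "abundant" or
#' "restrictive" rater) while magnitudes still vary per slice.
#'
#' @param dw_bound,dh_bound in-plane width/height perturbation bound, mm.
#' @param alpha_bound rotation bound, degrees.
#' @param slice_shift_max maximum boundary-slice shift (slices).
#' @param scenario one of `"in_plane"`, `"out_plane"`, `"in_out_plane"`.
#' @param bias `"random"` or `"systematic"` (in-plane component only;
#'   out-of-plane shifts are always random).
#' @param n_contours number of synthetic contours per mask (default 15).
#' @param translation_bound optional in-plane centroid translation bound in
#'   mm (default 0 = off).
#' @param alpha_scope under systematic bias, whether the rotation magnitude
#'   is drawn per `"slice"` (default) or once per `"contour"`.
#' @param seed optional RNG seed for [augment()].
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(dw_bound = 2.7, dh_bound = 2.7,
                                alpha_bound = 5, slice_shift_max = 1L,
                                scenario = c("in_plane", "out_plane", "in_out_plane"),
                                bias = c("random", "systematic"),
                                n_contours = 15L, translation_bound = 0,
                                alpha_scope = c("slice", "contour"),
                                seed = NULL) {
  scenario <- match.arg(scenario)
  bias <- match.arg(bias)
  alpha_scope <- match.arg(alpha_scope)
  if (dw_bound < 0 || dh_bound < 0 || alpha_bound < 0 || translation_bound < 0)
    stop("perturbation bounds must be >= 0")
  if (slice_shift_max < 0) stop("`slice_shift_max` must be >= 0")
  n_contours <- as.integer(n_contours)
  if (n_contours < 1L) stop("`n_contours` must be >= 1")
  structure(list(dw_bound = dw_bound, dh_bound = dh_bound,
                 alpha_bound = alpha_bound,
                 slice_shift_max = as.integer(slice_shift_max),
                 scenario = scenario, bias = bias, n_contours = n_contours,
                 translation_bound = translation_bound,
                 alpha_scope = alpha_scope,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "augmentation_config")
}

#' Dice similarity coefficient of two masks
#'
#' `2|A intersect B| / (|A| + |B|)` on a shared grid. Returns `NA` (the
#' explicit "undefined" marker) when both masks are empty.
#'
#' @param a,b two [mask3d()] on the same grid.
#' @return Dice coefficient in `[0, 1]`, or `NA` if both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "mask3d"), inherits(b, "mask3d"))
  if (!same_grid(a, b)) stop("dice requires masks on identical grids")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(a$data & b$data) / (na + nb)
}

#' Draw per-slice in-plane perturbation parameters
#'
#' Under random bias, `dw`, `dh` and `alpha` are drawn independently per
#' slice from `U(-bound, +bound)`. Under systematic bias the sign of each of
#' the three is drawn once (for the whole contour) and the magnitudes are
#' drawn per slice from `U(0, bound)`, so the perturbation direction is
#' consistent across slices. Uses the current RNG state.
#'
#' @param config an [augmentation_config()].
#' @param slice_indices axial indices of the slices intersecting the ROI.
#' @param bias overrides `config$bias` when given.
#' @return data.frame with columns `slice`, `dw`, `dh`, `alpha`, `tx`, `ty`.
#' @export
sample_inplane_params <- function(config, slice_indices, bias = config$bias) {
  ns <- length(slice_indices)
  b <- config
  if (bias == "random") {
    dw <- stats::runif(ns, -b$dw_bound, b$dw_bound)
    dh <- stats::runif(ns, -b$dh_bound, b$dh_bound)
    alpha <- stats::runif(ns, -b$alpha_bound, b$alpha_bound)
    tx <- stats::runif(ns, -b$translation_bound, b$translation_bound)
    ty <- stats::runif(ns, -b$translation_bound, b$translation_bound)
  } else {
    sgn <- function() sample(c(-1, 1), 1)
    s_dw <- sgn(); s_dh <- sgn(); s_al <- sgn()
    dw <- s_dw * stats::runif(ns, 0, b$dw_bound)
    dh <- s_dh * stats::runif(ns, 0, b$dh_bound)
    alpha <- if (b$alpha_scope == "contour") {
      rep(s_al * stats::runif(1, 0, b$alpha_bound), ns)
    } else {
      s_al * stats::runif(ns, 0, b$alpha_bound)
    }
    if (b$translation_bound > 0) {
      s_tx <- sgn(); s_ty <- sgn()
      tx <- s_tx * stats::runif(ns, 0, b$translation_bound)
      ty <- s_ty * stats::runif(ns, 0, b$translation_bound)
    } else {
      tx <- ty <- numeric(ns)
    }
  }
  data.frame(slice = slice_indices, dw = dw, dh = dh, alpha = alpha,
             tx = tx, ty = ty)
}

# Transform one binary axial slice. Returns list(slice, w, h, sx, sy).
perturb_slice <- function(sl, xs, ys, sp, dw, dh, alpha, tx, ty) {
  fg <- which(sl > 0, arr.ind = TRUE)
  if (nrow(fg) == 0L || (dw == 0 && dh == 0 && alpha == 0 && tx == 0 && ty == 0)) {
    if (nrow(fg) == 0L) return(list(slice = sl, w = NA_real_, h = NA_real_,
                                    sx = NA_real_, sy = NA_real_))
    ir <- range(fg[, 1]); jr <- range(fg[, 2])
    return(list(slice = sl, w = (ir[2] - ir[1] + 1) * sp[1],
                h = (jr[2] - jr[1] + 1) * sp[2], sx = 1, sy = 1))
  }
  ir <- range(fg[, 1]); jr <- range(fg[, 2])
  w <- (ir[2] - ir[1] + 1) * sp[1]
  h <- (jr[2] - jr[1] + 1) * sp[2]
  if (w + dw <= 0 || h + dh <= 0) {
    # the perturbation shrinks a sliver contour past zero extent: the
    # simulated rater omits it (the scale -> 0 limit of the transform)
    return(list(slice = array(0L, dim(sl)), w = w, h = h,
                sx = max(0, (w + dw) / w), sy = max(0, (h + dh) / h)))
  }
  sx <- (w + dw) / w
  sy <- (h + dh) / h
  cx <- mean(xs[fg[, 1]]); cy <- mean(ys[fg[, 2]])
  a <- alpha * pi / 180
  # window: input bbox expanded by the worst-case displacement
  halfdiag <- 0.5 * sqrt(w^2 + h^2)
  margin <- 0.5 * max(abs(dw), abs(dh)) + abs(sin(a)) * halfdiag +
    abs(tx) + abs(ty) + 2 * max(sp[1:2])
  iw <- which(xs >= xs[ir[1]] - margin & xs <= xs[ir[2]] + margin)
  jw <- which(ys >= ys[jr[1]] - margin & ys <= ys[jr[2]] + margin)
  px <- rep(xs[iw], times = length(jw))
  py <- rep(ys[jw], each = length(iw))
  u <- px - cx - tx
  v <- py - cy - ty
  ca <- cos(a); sa <- sin(a)
  ru <- ca * u + sa * v      # rotate by -alpha
  rv <- -sa * u + ca * v
  sxr <- ru / sx + cx
  syr <- rv / sy + cy
  ii <- round((sxr - xs[1]) / sp[1]) + 1L
  jj <- round((syr - ys[1]) / sp[2]) + 1L
  ok <- ii >= 1L & ii <= length(xs) & jj >= 1L & jj <= length(ys)
  val <- integer(length(px))
  val[ok] <- sl[cbind(ii[ok], jj[ok])]
  out <- array(0L, dim(sl))
  out[iw, jw] <- val
  list(slice = out, w = w, h = h, sx = sx, sy = sy)
}

#' Apply in-plane perturbations to a mask
#'
#' For each axial slice listed in `params`, measures the tight bounding box
#' (width `w`, height `h`, mm) of the slice foreground, builds the 2D affine
#' map composed of anisotropic scaling `(w+dw)/w`, `(h+dh)/h` and rotation by
#' `alpha` about the slice centroid, and resamples the binary slice through
#' the inverse map with nearest-neighbour interpolation. Empty slices pass
#' through unchanged; the grid is never altered.
#'
#' @param mask a [mask3d()].
#' @param params data.frame as returned by [sample_inplane_params()]; must
#'   cover every slice with foreground.
#' @return perturbed [mask3d()] on the same grid.
#' @export
apply_inplane <- function(mask, params) {
  apply_inplane_impl(mask, params)$mask
}

apply_inplane_impl <- function(mask, params) {
  stopifnot(inherits(mask, "mask3d"))
  fg_slices <- which(apply(mask$data, 3, sum) > 0)
  missing <- setdiff(fg_slices, params$slice)
  if (length(missing) > 0)
    stop("`params` must cover all in-ROI slices; missing: ",
         paste(missing, collapse = ", "))
  xs <- axis_coords(mask, 1)
  ys <- axis_coords(mask, 2)
  out <- mask$data
  log <- params
  log$w <- log$h <- log$applied_scale_x <- log$applied_scale_y <- NA_real_
  for (r in seq_len(nrow(params))) {
    k <- params$slice[r]
    res <- perturb_slice(mask$data[, , k], xs, ys, mask$spacing,
                         params$dw[r], params$dh[r], params$alpha[r],
                         params$tx[r], params$ty[r])
    out[, , k] <- res$slice
    log$w[r] <- res$w; log$h[r] <- res$h
    log$applied_scale_x[r] <- res$sx; log$applied_scale_y[r] <- res$sy
  }
  list(mask = mask3d(out, mask$spacing, mask$origin), log = log)
}

#' Draw the out-of-plane boundary shifts
#'
#' The superior and inferior boundary-slice shifts are drawn independently
#' and uniformly from `{-s, ..., 0, ..., +s}` with
#' `s = config$slice_shift_max` (default 1, i.e. `{-1, 0, +1}`).
#'
#' @param config an [augmentation_config()].
#' @return named numeric: `delta_sup`, `delta_inf`.
#' @export
sample_outplane_shift <- function(config) {
  s <- config$slice_shift_max
  ch <- seq(-s, s)
  c(delta_sup = if (s == 0) 0L else sample(ch, 1),
    delta_inf = if (s == 0) 0L else sample(ch, 1))
}

#' Apply an out-of-plane boundary-slice shift
#'
#' Simulates variability in the choice of the first/last ROI slice in the
#' cranio-caudal direction: a shrink (`delta = -1`) empties the boundary
#' slice, a grow (`delta = +1`) replicates the current boundary slice's
#' contour into the adjacent empty slice. The superior (largest slice index)
#' and inferior ends are handled independently.
#'
#' @param mask a [mask3d()] whose foreground occupies >= 3 consecutive
#'   slices.
#' @param delta_sup,delta_inf integer shifts (|delta| <= extent allows).
#' @return shifted [mask3d()].
#' @export
apply_outplane <- function(mask, delta_sup, delta_inf) {
  stopifnot(inherits(mask, "mask3d"))
  counts <- apply(mask$data, 3, sum)
  fg <- which(counts > 0)
  if (length(fg) < 3L || any(diff(fg) != 1L))
    stop("mask must occupy >= 3 consecutive axial slices")
  k0 <- fg[1]; k1 <- fg[length(fg)]
  d3 <- dim(mask$data)[3]
  n_shrink <- max(0, -delta_sup) + max(0, -delta_inf)
  if (length(fg) - n_shrink < 1L)
    stop("shrink would empty the mask")
  out <- mask$data
  apply_end <- function(out, boundary, dir, delta) {
    # dir = +1 for superior end (grow towards larger k), -1 for inferior
    if (delta == 0) return(out)
    k <- boundary
    if (delta > 0) {
      for (step in seq_len(delta)) {
        tgt <- k + dir * step
        if (tgt < 1L || tgt > d3)
          stop("out-of-plane growth extends past the grid")
        out[, , tgt] <- out[, , k]
      }
    } else {
      for (step in seq_len(-delta)) out[, , k - dir * (step - 1L)] <- 0L
    }
    out
  }
  out <- apply_end(out, k1, +1L, delta_sup)
  out <- apply_end(out, k0, -1L, delta_inf)
  mask3d(out, mask$spacing, mask$origin)
}

#' Generate a set of synthetic contours for one mask
#'
#' Emits `config$n_contours` perturbed copies of `mask` under the configured
#' scenario and bias, with a complete per-slice parameter log per contour.
#' For `"in_out_plane"` the boundary-slice shift is applied first and the
#' in-plane perturbation acts on the resulting slice extent. Reproducible
#' under `config$seed`.
#'
#' @param mask ground-truth [mask3d()].
#' @param config an [augmentation_config()].
#' @return object of class `augmented_mask_set`: list with `ground_truth`,
#'   `perturbed` (list of masks), `logs` (per contour: `params`,
#'   `delta_sup`, `delta_inf`), `config`, `seed`.
#' @export
augment <- function(mask, config) {
  stopifnot(inherits(mask, "mask3d"), inherits(config, "augmentation_config"))
  run <- function() {
    perturbed <- vector("list", config$n_contours)
    logs <- vector("list", config$n_contours)
    for (c_i in seq_len(config$n_contours)) {
      m <- mask
      delta <- c(delta_sup = 0L, delta_inf = 0L)
      params_log <- NULL
      if (config$scenario %in% c("out_plane", "in_out_plane")) {
        delta <- sample_outplane_shift(config)
        m <- apply_outplane(m, delta[["delta_sup"]], delta[["delta_inf"]])
      }
      if (config$scenario %in% c("in_plane", "in_out_plane")) {
        fg <- which(apply(m$data, 3, sum) > 0)
        params <- sample_inplane_params(config, fg)
        res <- apply_inplane_impl(m, params)
        m <- res$mask
        params_log <- res$log
      }
      perturbed[[c_i]] <- m
      logs[[c_i]] <- list(params = params_log,
                          delta_sup = as.integer(delta[["delta_sup"]]),
                          delta_inf = as.integer(delta[["delta_inf"]]))
    }
    structure(list(ground_truth = mask, perturbed = perturbed, logs = logs,
                   config = config, seed = config$seed),
              class = "augmented_mask_set")
  }
  if (!is.null(config$seed)) withr_seed(config$seed, run()) else run()
}

#' @export
print.augmented_mask_set <- function(x, ...) {
  d <- vapply(x$perturbed, dice, numeric(1), b = x$ground_truth)
  cat(sprintf("<augmented_mask_set> %d contours, scenario %s / bias %s\n",
              length(x$perturbed), x$config$scenario, x$config$bias))
  cat(sprintf("  dice vs ground truth: mean %.3f, range [%.3f, %.3f]\n",
              mean(d), min(d), max(d)))
  invisible(x)
}

#' Dice of every contour in a set against its ground truth
#'
#' @param set an [augment()] result.
#' @return numeric vector of Dice coefficients, one per contour.
#' @export
dice_vs_truth <- function(set) {
  stopifnot(inherits(set, "augmented_mask_set"))
  vapply(set$perturbed, dice, numeric(1), b = set$ground_truth)
}

#' Write an augmented mask set as NIfTI masks plus a JSON log
#'
#' @param set an [augment()] result.
#' @param dir output directory.
#' @param stem filename prefix.
#' @return `dir`, invisibly.
#' @export
write_augmented_set <- function(set, dir, stem = "contour") {
  stopifnot(inherits(set, "augmented_mask_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(set$ground_truth, file.path(dir, paste0(stem, "_gt.nii.gz")))
  for (i in seq_along(set$perturbed)) {
    write_nifti(set$perturbed[[i]],
                file.path(dir, sprintf("%s_%03d.nii.gz", stem, i)))
  }
  log <- list(seed = set$seed, scenario = set$config$scenario,
              bias = set$config$bias, n_contours = set$config$n_contours,
              bounds = list(dw = set$config$dw_bound, dh = set$config$dh_bound,
                            alpha = set$config$alpha_bound,
                            slice_shift_max = set$config$slice_shift_max),
              contours = lapply(set$logs, function(l) {
                list(delta_sup = l$delta_sup, delta_inf = l$delta_inf,
                     slices = if (is.null(l$params)) NULL else l$params)
              }))
  jsonlite::write_json(log, file.path(dir, paste0(stem, "_log.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  invisible(dir)
}
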