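#' 3D scalar volumes and binary masks
#'
#' `vol3d()` wraps a 3D numeric array together with its voxel spacing (mm)
#' and origin (mm, coordinate of the centre of voxel `[1,1,1]`). The third
#' array axis is the axial (cranio-caudal) axis; slice 1 is the inferior-most
#' slice. `mask3d()` is the binary specialisation used for regions of
#' interest: values are stored as integer 0/1.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel size in mm per axis (> 0).
#' @param origin numeric length-3, mm coordinate of the first voxel centre.
#' @return An object of class `vol3d` (or `mask3d`, which inherits `vol3d`):
#'   a list with elements `data`, `spacing`, `origin`.
#' @examples
#' v <- vol3d(array(rnorm(8), c(2, 2, 2)), spacing = c(1, 1, 3))
#' voxel_volume(v)
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite mm coordinates")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "vol3d")
}

#' @rdname vol3d
#' @export
mask3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be in {0, 1}")
  m <- vol3d(array(as.integer(data), dim(data)), spacing, origin)
  class(m) <- c("mask3d", "vol3d")
  m
}

#' @rdname vol3d
#' @param x a `vol3d` to reinterpret as a mask (values must be 0/1).
#' @export
as_mask3d <- function(x) {
  stopifnot(inherits(x, "vol3d"))
  mask3d(x$data, x$spacing, x$origin)
}

#' @rdname vol3d
#' @param a,b two `vol3d` objects.
#' @param tol geometric tolerance in mm.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' @rdname vol3d
#' @param v a `vol3d`.
#' @export
voxel_volume <- function(v) prod(v$spacing)

#' Physical volume of a binary mask
#'
#' @param mask a `mask3d`.
#' @return foreground volume in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "mask3d"))
  sum(mask$data) * voxel_volume(mask)
}

#' @export
print.vol3d <- function(x, ...) {
  kind <- if (inherits(x, "mask3d")) "mask3d" else "vol3d"
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (inherits(x, "mask3d")) {
    cat(sprintf("  foreground: %d voxels (%.1f mm^3)\n",
                sum(x$data), mask_volume(x)))
  } else {
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
                min(x$data), max(x$data)))
  }
  invisible(x)
}

# Voxel-centre physical coordinates along one axis (1-based index i ->
# origin + (i-1) * spacing).
axis_coords <- function(v, axis) {
  n <- dim(v$data)[axis]
  v$origin[axis] + (seq_len(n) - 1) * v$spacing[axis]
}

# Axial slice indices that contain foreground.
mask_slice_range <- function(mask) {
  idx <- which(apply(mask$data, 3, sum) > 0)
  if (length(idx) == 0L) return(integer(0))
  seq(min(idx), max(idx))
}

#' A dynamic (4D) image series
#'
#' Container for a dynamic contrast-enhanced acquisition: a list of frames
#' sharing one grid plus strictly increasing acquisition times in seconds.
#'
#' @param frames list of `vol3d` on a common grid.
#' @param times numeric acquisition times (s), strictly increasing, one per
#'   frame.
#' @return object of class `dyn_series`.
#' @export
dyn_series <- function(frames, times) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("need at least 2 frames")
  if (!all(vapply(frames, inherits, logical(1), "vol3d")))
    stop("all frames must be vol3d")
  times <- as.numeric(times)
  if (length(times) != length(frames))
    stop("one acquisition time per frame required")
  if (any(diff(times) <= 0))
    stop("acquisition times must be strictly increasing")
  for (i in seq_along(frames)[-1]) {
    if (!same_grid(frames[[1]], frames[[i]]))
      stop("all frames must share one grid")
  }
  structure(list(frames = frames, times = times), class = "dyn_series")
}

#' @export
print.dyn_series <- function(x, ...) {
  cat(sprintf("<dyn_series> %d frames, t = %g..%g s, grid %s\n",
              length(x$frames), min(x$times), max(x$times),
              paste(dim(x$frames[[1]]$data), collapse = "x")))
  invisible(x)
}

# Connected components of the foreground under face (6) connectivity;
# returns the number of components. Used by the phantom contract tests and
# exported for QC.
#' Count connected foreground components of a mask
#'
#' @param mask a `mask3d`.
#' @param connectivity 6 (faces) or 26 (faces+edges+corners).
#' @return integer component count (0 for an empty mask).
#' @export
n_components <- function(mask, connectivity = 6) {
  stopifnot(inherits(mask, "mask3d"), connectivity %in% c(6, 26))
  lab <- label_components(mask$data > 0, connectivity)
  if (length(lab$sizes) == 0L) 0L else length(lab$sizes)
}

# Internal: label connected TRUE-voxels of a logical 3D array.
# Returns list(labels = integer array (0 = background), sizes).
label_components <- function(fg, connectivity = 26) {
  d <- dim(fg)
  idx <- which(fg)
  labels <- array(0L, d)
  if (length(idx) == 0L) return(list(labels = labels, sizes = integer(0)))
  offs <- neighbor_offsets(connectivity)
  ai <- arrayInd(idx, d)
  pos <- array(0L, d)  # map linear voxel index -> node id
  pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    ni <- ai[, 1] + offs[r, 1]
    nj <- ai[, 2] + offs[r, 2]
    nk <- ai[, 3] + offs[r, 3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    if (!any(ok)) next
    lin <- ni[ok] + (nj[ok] - 1L) * d[1] + (nk[ok] - 1L) * d[1] * d[2]
    nb <- pos[lin]
    src <- which(ok)[nb > 0L]
    if (length(src) == 0L) next
    edges <- c(edges, rbind(src, nb[nb > 0L]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(labels = labels, sizes = as.integer(comp$csize))
}

# Half-space neighbor offsets would suffice for undirected edges, but full
# offsets keep the helper reusable; duplicate edges are harmless to
# igraph::components.
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}
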