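#' Minimal NIfTI-1 input/output
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii` / `.nii.gz`) with
#' axis-aligned geometry: spacing from `pixdim`, origin from the sform
#' translation column. This covers the needs of the phantom and pipeline
#' stages (scalar volumes, binary masks, 4D dynamic series); oblique
#' orientations, qform rotations and header extensions are out of scope.
#'
#' @param x a `vol3d`/`mask3d`, or for 4D output a `dyn_series`.
#' @param path output file; compressed automatically when it ends in `.gz`.
#' @param datatype one of `"float32"`, `"float64"`, `"uint8"`, `"int16"`.
#'   Masks default to `"uint8"`, images to `"float32"`.
#' @return `write_nifti()` returns `path` invisibly. `read_nifti()` returns a
#'   `vol3d` (3D file) or a list of `vol3d` frames (4D file); use
#'   [as_mask3d()] to reinterpret binary content.
#' @export
write_nifti <- function(x, path, datatype = NULL) {
  if (inherits(x, "dyn_series")) {
    arr <- array(0, c(dim(x$frames[[1]]$data), length(x$frames)))
    for (i in seq_along(x$frames)) arr[, , , i] <- x$frames[[i]]$data
    return(write_nifti_array(arr, x$frames[[1]]$spacing,
                             x$frames[[1]]$origin, path,
                             datatype %||% "float32"))
  }
  stopifnot(inherits(x, "vol3d"))
  if (is.null(datatype)) datatype <- if (inherits(x, "mask3d")) "uint8" else "float32"
  write_nifti_array(x$data, x$spacing, x$origin, path, datatype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nifti_dtypes <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

write_nifti_array <- function(arr, spacing, origin, path, datatype) {
  dt <- nifti_dtypes[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  nd <- length(dim(arr))
  stopifnot(nd %in% c(3L, 4L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  pad <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                       # sizeof_hdr
  pad(35)                           # data_type, db_name, extents, session_error, regular
  pad(1)                            # dim_info
  dims <- c(nd, dim(arr), rep(1L, 7 - nd))
  wi(dims, 2)                       # dim[8]
  wf(c(0, 0, 0))                    # intent_p1..p3
  wi(0L, 2)                         # intent_code
  wi(dt$code, 2)                    # datatype
  wi(dt$bitpix, 2)                  # bitpix
  wi(0L, 2)                         # slice_start
  wf(c(1, spacing, rep(1, 4)))      # pixdim[8] (qfac = 1)
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2); pad(1)                 # slice_end, slice_code
  pad(1)                            # xyzt_units
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  desc <- charToRaw("segstab")
  writeBin(c(desc, raw(80 - length(desc))), con)  # descrip[80]
  pad(24)                           # aux_file
  wi(0L, 2); wi(1L, 2)              # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                     # quatern_b/c/d, qoffset_x/y/z
  wf(c(spacing[1], 0, 0, origin[1]))  # srow_x
  wf(c(0, spacing[2], 0, origin[2]))  # srow_y
  wf(c(0, 0, spacing[3], origin[3]))  # srow_z
  pad(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)      # magic
  pad(4)                            # extension flag
  if (dt$what == "integer") {
    writeBin(as.integer(arr), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(arr), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path)
  ri <- function(off, n, size) readBin(hdr[(off + 1):length(hdr)], "integer",
                                       n = n, size = size, endian = "little")
  rf <- function(off, n) readBin(hdr[(off + 1):length(hdr)], "double",
                                 n = n, size = 4L, endian = "little")
  if (!identical(ri(0, 1, 4), 348L))
    stop("not a NIfTI-1 file (or wrong endianness): ", path)
  dims <- ri(40, 8, 2)
  datatype <- ri(70, 1, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108, 1)
  scl_slope <- rf(112, 1); scl_inter <- rf(116, 1)
  qform_code <- ri(252, 1, 2); sform_code <- ri(254, 1, 2)
  quat <- rf(256, 6)
  srow <- matrix(rf(280, 12), nrow = 3, byrow = TRUE)
  dt <- NULL
  for (nm in names(nifti_dtypes)) {
    if (nifti_dtypes[[nm]]$code == datatype) dt <- nifti_dtypes[[nm]]
  }
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  skip <- round(vox_offset) - 348
  if (skip > 0) invisible(readBin(con, "raw", n = skip))
  n <- prod(shape)
  vals <- if (dt$what == "integer") {
    readBin(con, "integer", n = n, size = dt$size, signed = dt$signed,
            endian = "little")
  } else {
    readBin(con, "double", n = n, size = dt$size, endian = "little")
  }
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- pixdim[2:4]
  origin <- if (sform_code > 0) srow[, 4] else if (qform_code > 0) quat[4:6] else c(0, 0, 0)
  if (nd == 3L) {
    vol3d(array(vals, shape), spacing, origin)
  } else if (nd == 4L) {
    arr <- array(vals, shape)
    lapply(seq_len(shape[4]), function(i) vol3d(arr[, , , i], spacing, origin))
  } else stop("only 3D and 4D NIfTI volumes are supported")
}

#' Write a dynamic series with its timing sidecar
#'
#' Stores the 4D frames as NIfTI and the acquisition times (seconds) in a
#' JSON sidecar next to it (`<stem>.json`).
#'
#' @param ds a `dyn_series`.
#' @param path `.nii`/`.nii.gz` output path.
#' @return `path`, invisibly.
#' @export
write_dyn_series <- function(ds, path) {
  stopifnot(inherits(ds, "dyn_series"))
  write_nifti(ds, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(acquisition_times_s = ds$times), side,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_dyn_series
#' @export
read_dyn_series <- function(path) {
  frames <- read_nifti(path)
  if (!is.list(frames)) stop("expected a 4D NIfTI file: ", path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side)) stop("missing timing sidecar: ", side)
  times <- jsonlite::read_json(side, simplifyVector = TRUE)$acquisition_times_s
  dyn_series(frames, times)
}
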