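#' The 17-variant image filter bank
#'
#' Produces, in a stable order, the 17 image variants features are extracted
#' from: the unfiltered image, four Laplacian-of-Gaussian responses at
#' physical scales sigma = 2, 3, 4, 5 mm, the eight single-level separable
#' wavelet decompositions (high/low-pass per axis: HHH ... LLL, first letter
#' = first array axis), and four monotone intensity remappings (square,
#' square root, logarithm, exponential), each rescaled to the input's
#' intensity range in the convention of the reference radiomics extractor.
#'
#' The wavelet kernels are undecimated Haar pairs normalised as mean
#' (`L = (x_i + x_{i+1})/2`) and half-difference (`H = (x_i - x_{i+1})/2`),
#' so the LLL response to a constant image is that constant. The LoG is
#' scale-normalised (multiplied by sigma^2). LoG scales are expressed in mm,
#' so the input must be on an isotropic grid (resample first).
#'
#' @param img a `vol3d` (normalized, isotropic spacing).
#' @param config an [extraction_config()].
#' @return named list of 17 `vol3d` variants, in stable order.
#' @export
filter_bank <- function(img, config = extraction_config()) {
  stopifnot(inherits(img, "vol3d"))
  sp <- img$spacing
  if (max(sp) - min(sp) > 1e-6)
    stop("LoG filtering requires an isotropic grid; resample the image first")
  out <- list(original = img)
  for (s in config$log_sigmas) {
    out[[sprintf("log-sigma-%g-mm", s)]] <- log_filter(img, s)
  }
  for (combo in config$wavelet_decompositions) {
    out[[paste0("wavelet-", combo)]] <- wavelet_filter(img, combo)
  }
  for (f in config$intensity_filters) {
    out[[f]] <- intensity_filter(img, f)
  }
  stopifnot(length(out) == 17L)
  out
}

# Scale-normalised Laplacian of Gaussian at physical sigma (mm).
log_filter <- function(img, sigma_mm) {
  sp <- img$spacing
  arr <- gauss_smooth(img$data, sigma_mm / sp)
  lap <- array(0, dim(arr))
  for (ax in 1:3) {
    lap <- lap + conv_axis(arr, c(1, -2, 1) / sp[ax]^2, ax)
  }
  vol3d(sigma_mm^2 * lap, img$spacing, img$origin)
}

wavelet_filter <- function(img, combo) {
  letters3 <- strsplit(combo, "")[[1]]
  stopifnot(length(letters3) == 3L, all(letters3 %in% c("H", "L")))
  arr <- img$data
  for (ax in 1:3) {
    k <- if (letters3[ax] == "L") c(0.5, 0.5) else c(0.5, -0.5)
    arr <- conv_axis(arr, k, ax, origin = 1L)
  }
  vol3d(arr, img$spacing, img$origin)
}

intensity_filter <- function(img, kind) {
  x <- img$data
  m <- max(abs(x))
  out <- if (m == 0) {
    x
  } else {
    switch(kind,
      square = {
        c0 <- 1 / sqrt(m)
        (c0 * x)^2
      },
      squareroot = {
        sign(x) * sqrt(m * abs(x))
      },
      logarithm = {
        c0 <- m / log(m + 1)
        sign(x) * c0 * log(abs(x) + 1)
      },
      exponential = {
        c0 <- log(m) / m
        exp(c0 * x)
      },
      stop("unknown intensity filter: ", kind))
  }
  vol3d(out, img$spacing, img$origin)
}
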