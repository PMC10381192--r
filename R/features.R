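#' Feature extraction configuration
#'
#' Fixed-bin-width discretisation plus the composition of the filter bank
#' and feature families. The defaults reproduce the standard configuration:
#' bin width 5 (so a full-range 0-600 ROI discretises to 120 grey levels),
#' LoG scales 2-5 mm, all eight single-level wavelet decompositions, the
#' four intensity filters, and 18 first-order + 22 co-occurrence + 16
#' run-length + 16 size-zone features, i.e. 72 features per variant and
#' 17 x 72 = 1224 per image/mask pair. Shape features are deliberately
#' absent (the 1224 arithmetic contains no shape family).
#'
#' @param bin_width grey-level bin width in intensity units (default 5).
#' @param log_sigmas LoG scales in mm.
#' @param wavelet_decompositions character vector of the 8 H/L axis combos.
#' @param intensity_filters the four monotone intensity remappings.
#' @return object of class `extraction_config`.
#' @export
extraction_config <- function(bin_width = 5,
                              log_sigmas = c(2, 3, 4, 5),
                              wavelet_decompositions = c("HHH", "HHL", "HLH", "HLL",
                                                         "LHH", "LHL", "LLH", "LLL"),
                              intensity_filters = c("square", "squareroot",
                                                    "logarithm", "exponential")) {
  if (bin_width <= 0) stop("`bin_width` must be positive")
  n_variants <- 1L + length(log_sigmas) + length(wavelet_decompositions) +
    length(intensity_filters)
  if (n_variants != 17L)
    stop("configuration must yield exactly 17 variants (1 + 4 LoG + 8 wavelet + 4 intensity)")
  structure(list(bin_width = bin_width, log_sigmas = log_sigmas,
                 wavelet_decompositions = wavelet_decompositions,
                 intensity_filters = intensity_filters),
            class = "extraction_config")
}

#' Names of all features, per family and fully qualified
#'
#' @param family one of `"firstorder"`, `"glcm"`, `"glrlm"`, `"glszm"`, or
#'   `"all"` for the fully qualified `filter|family|name` keys of one
#'   image/mask pair (1224 keys).
#' @param config an [extraction_config()] (for `family = "all"`).
#' @return character vector of feature names.
#' @export
feature_names <- function(family = "all", config = extraction_config()) {
  fo <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
          "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
          "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
          "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")
  glcm <- c("Autocorrelation", "JointAverage", "ClusterProminence",
            "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
            "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
            "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Id", "Idm",
            "Idmn", "Idn", "InverseVariance", "MaximumProbability",
            "SumEntropy", "SumSquares")
  glrlm <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
             "RunLengthNonUniformityNormalized", "RunPercentage",
             "GrayLevelVariance", "RunVariance", "RunEntropy",
             "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
             "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
             "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  glszm <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
             "SizeZoneNonUniformityNormalized", "ZonePercentage",
             "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
             "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
             "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
             "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  fam <- list(firstorder = fo, glcm = glcm, glrlm = glrlm, glszm = glszm)
  if (family != "all") {
    nm <- fam[[family]]
    if (is.null(nm)) stop("unknown family: ", family)
    return(nm)
  }
  variants <- c("original",
                sprintf("log-sigma-%g-mm", config$log_sigmas),
                paste0("wavelet-", config$wavelet_decompositions),
                config$intensity_filters)
  unlist(lapply(variants, function(v) {
    unlist(lapply(names(fam), function(f) paste(v, f, fam[[f]], sep = "|")))
  }), use.names = FALSE)
}

#' Fixed-bin-width grey-level discretisation
#'
#' Bins are anchored at the ROI minimum: label = `floor((x - min)/width) + 1`.
#' The bin count is `ceil((max - min)/width)` (at least 1); a value lying
#' exactly on the top edge folds into the last bin, so a ROI spanning the
#' full 0-600 range at width 5 yields exactly 120 grey levels.
#'
#' @param values numeric ROI intensities (non-empty).
#' @param bin_width positive bin width.
#' @return list with integer `labels` (same length as `values`) and
#'   `n_bins`.
#' @export
discretize <- function(values, bin_width = 5) {
  if (length(values) == 0L) stop("ROI is empty")
  if (bin_width <= 0) stop("`bin_width` must be positive")
  lo <- min(values)
  hi <- max(values)
  n_bins <- max(1L, as.integer(ceiling((hi - lo) / bin_width - 1e-12)))
  labels <- pmin(n_bins, as.integer(floor((values - lo) / bin_width)) + 1L)
  list(labels = labels, n_bins = n_bins)
}

# 13 unique 3D directions (one per opposite pair of the 26-neighbourhood).
texture_directions <- function() {
  g <- neighbor_offsets(26)
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

# Crop mask bbox and return the discretised grey-level array (0 = outside
# ROI) together with labels/bins.
roi_grey_array <- function(img, mask, bin_width) {
  stopifnot(same_grid(img, mask))
  idx <- which(mask$data > 0)
  if (length(idx) == 0L) stop("ROI is empty")
  ai <- arrayInd(idx, dim(mask$data))
  rng <- apply(ai, 2, range)
  sub <- list(rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3])
  m <- mask$data[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  v <- img$data[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  vals <- v[m > 0]
  d <- discretize(vals, bin_width)
  G <- array(0L, dim(m))
  G[m > 0] <- d$labels
  list(G = G, values = vals, labels = d$labels, n_bins = d$n_bins)
}

first_order_features <- function(values, labels, n_bins, voxel_vol) {
  x <- values
  n <- length(x)
  p <- tabulate(labels, n_bins) / n
  pp <- p[p > 0]
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  q <- stats::quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  rsub <- x[x >= q[1] & x <= q[4]]
  c(Energy = sum(x^2),
    TotalEnergy = voxel_vol * sum(x^2),
    Entropy = -sum(pp * log2(pp)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = mean(x),
    Median = stats::median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mean(x))),
    RobustMeanAbsoluteDeviation =
      if (length(rsub) > 0) mean(abs(rsub - mean(rsub))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

glcm_single <- function(P, Ng) {
  eps <- 2.2e-16
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(i * P)          # symmetric: mu_x = mu_y
  sigma2 <- sum((i - mu)^2 * P)
  sigma <- sqrt(sigma2)
  kd <- 0:(Ng - 1)
  pd <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * Ng)
  ps <- vapply(ks, function(k) sum(P[(i + j) == k]), numeric(1))
  DA <- sum(kd * pd)
  ent_terms <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HXY <- ent_terms(P)
  HX <- ent_terms(px)
  pxy <- outer(px, px)
  sel <- P > 0 & pxy > 0
  HXY1 <- -sum(P[sel] * log2(pxy[sel]))
  HXY2 <- ent_terms(pxy)
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  corr <- if (sigma2 > eps) (sum(i * j * P) - mu^2) / sigma2 else 1
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = DA,
    DifferenceEntropy = ent_terms(pd),
    DifferenceVariance = sum((kd - DA)^2 * pd),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / Ng^2)),
    Idn = sum(P / (1 + abs(i - j) / Ng)),
    InverseVariance = sum(P[i != j] / (i - j)[i != j]^2),
    MaximumProbability = max(P),
    SumEntropy = ent_terms(ps),
    SumSquares = sigma2)
}

glcm_features <- function(G, n_bins) {
  d <- dim(G)
  dirs <- texture_directions()
  acc <- NULL
  n_used <- 0L
  for (r in seq_len(nrow(dirs))) {
    dd <- dirs[r, ]
    lo <- pmax(1, 1 - dd)
    hi <- pmin(d, d - dd)
    if (any(hi < lo)) next
    r1 <- lo[1]:hi[1]; r2 <- lo[2]:hi[2]; r3 <- lo[3]:hi[3]
    g1 <- G[r1, r2, r3]
    g2 <- G[r1 + dd[1], r2 + dd[2], r3 + dd[3]]
    ok <- g1 > 0L & g2 > 0L
    if (!any(ok)) next
    cnt <- tabulate(g1[ok] + n_bins * (g2[ok] - 1L), n_bins * n_bins)
    C <- matrix(cnt, n_bins, n_bins)
    C <- C + t(C)
    P <- C / sum(C)
    f <- glcm_single(P, n_bins)
    acc <- if (is.null(acc)) f else acc + f
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    out <- stats::setNames(numeric(22), feature_names("glcm"))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  acc / n_used
}

glrlm_single <- function(P, Ng, Np) {
  Nr <- sum(P)
  g <- row(P); l <- col(P)
  p <- P / Nr
  mug <- sum(g * p); mul <- sum(l * p)
  pp <- p[p > 0]
  c(ShortRunEmphasis = sum(P / l^2) / Nr,
    LongRunEmphasis = sum(P * l^2) / Nr,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / Nr^2,
    RunLengthNonUniformity = sum(colSums(P)^2) / Nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / Nr^2,
    RunPercentage = Nr / Np,
    GrayLevelVariance = sum((g - mug)^2 * p),
    RunVariance = sum((l - mul)^2 * p),
    RunEntropy = -sum(pp * log2(pp)),
    LowGrayLevelRunEmphasis = sum(P / g^2) / Nr,
    HighGrayLevelRunEmphasis = sum(P * g^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (g^2 * l^2)) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(P * g^2 / l^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(P * l^2 / g^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(P * g^2 * l^2) / Nr)
}

glrlm_features <- function(G, n_bins) {
  d <- dim(G)
  idx <- which(G > 0L)
  Np <- length(idx)
  ai <- arrayInd(idx, d)
  gl <- G[idx]
  dirs <- texture_directions()
  acc <- NULL
  for (r in seq_len(nrow(dirs))) {
    dd <- dirs[r, ]
    a <- which(dd != 0)[1]
    tt <- ai[, a] * dd[a]   # advances by 1 per step along the direction
    l1 <- ai[, 1] - tt * dd[1]
    l2 <- ai[, 2] - tt * dd[2]
    l3 <- ai[, 3] - tt * dd[3]
    ord <- order(l1, l2, l3, tt)
    t_o <- tt[ord]; g_o <- gl[ord]
    newrun <- c(TRUE, diff(l1[ord]) != 0L | diff(l2[ord]) != 0L |
                  diff(l3[ord]) != 0L | diff(t_o) != 1L | diff(g_o) != 0L)
    rid <- cumsum(newrun)
    lens <- tabulate(rid)
    greys <- g_o[newrun]
    maxlen <- max(lens)
    cnt <- tabulate(greys + n_bins * (lens - 1L), n_bins * maxlen)
    P <- matrix(cnt, n_bins, maxlen)
    f <- glrlm_single(P, n_bins, Np)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(dirs)
}

glszm_features <- function(G, n_bins) {
  d <- dim(G)
  idx <- which(G > 0L)
  Np <- length(idx)
  ai <- arrayInd(idx, d)
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  gl <- G[idx]
  offs <- texture_directions()
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    dd <- offs[r, ]
    ni <- ai[, 1] + dd[1]; nj <- ai[, 2] + dd[2]; nk <- ai[, 3] + dd[3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    lin <- ni[ok] + (nj[ok] - 1L) * d[1] + (nk[ok] - 1L) * d[1] * d[2]
    nb <- pos[lin]
    src <- which(ok)
    keep <- nb > 0L & gl[src] == gl[pmax(1L, nb)]
    from <- c(from, src[keep]); to <- c(to, nb[keep])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, Np - igraph::vcount(g)))
  comp <- igraph::components(g)
  zone_g <- tapply(gl, comp$membership, function(v) v[1])
  zone_s <- as.integer(comp$csize)
  maxs <- max(zone_s)
  cnt <- tabulate(as.integer(zone_g) + n_bins * (zone_s - 1L), n_bins * maxs)
  P <- matrix(cnt, n_bins, maxs)
  Nz <- sum(P)
  gg <- row(P); s <- col(P)
  p <- P / Nz
  mug <- sum(gg * p); mus <- sum(s * p)
  pp <- p[p > 0]
  c(SmallAreaEmphasis = sum(P / s^2) / Nz,
    LargeAreaEmphasis = sum(P * s^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / Nz^2,
    SizeZoneNonUniformity = sum(colSums(P)^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    ZonePercentage = Nz / Np,
    GrayLevelVariance = sum((gg - mug)^2 * p),
    ZoneVariance = sum((s - mus)^2 * p),
    ZoneEntropy = -sum(pp * log2(pp)),
    LowGrayLevelZoneEmphasis = sum(P / gg^2) / Nz,
    HighGrayLevelZoneEmphasis = sum(P * gg^2) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (gg^2 * s^2)) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * gg^2 / s^2) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * s^2 / gg^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * gg^2 * s^2) / Nz)
}

#' Extract one feature family from an image/mask pair
#'
#' Grey levels for the texture families (and for first-order Entropy and
#' Uniformity) come from fixed-bin-width discretisation of the ROI values
#' ([discretize()]). Co-occurrence and run-length matrices are built per
#' direction over the 13 unique 3D offsets, symmetrised (co-occurrence) and
#' averaged feature-wise across directions; size zones are 26-connected
#' components of equal grey level. Degenerate matrices (e.g. a single-voxel
#' ROI with no voxel pairs) yield zero-valued features flagged with a
#' `degenerate` attribute.
#'
#' @param img a `vol3d` (a filter-bank variant).
#' @param mask a [mask3d()] on the same grid.
#' @param family `"firstorder"`, `"glcm"`, `"glrlm"` or `"glszm"`.
#' @param config an [extraction_config()].
#' @return named numeric vector (18/22/16/16 values).
#' @export
extract_family <- function(img, mask, family, config = extraction_config()) {
  roi <- roi_grey_array(img, mask, config$bin_width)
  extract_family_roi(roi, family, voxel_volume(img))
}

extract_family_roi <- function(roi, family, voxel_vol) {
  switch(family,
    firstorder = first_order_features(roi$values, roi$labels, roi$n_bins, voxel_vol),
    glcm = glcm_features(roi$G, roi$n_bins),
    glrlm = glrlm_features(roi$G, roi$n_bins),
    glszm = glszm_features(roi$G, roi$n_bins),
    stop("unknown family: ", family))
}

#' Extract the full 1224-feature vector for one image/mask pair
#'
#' Runs the [filter_bank()] (or reuses a precomputed one, e.g. when
#' extracting many perturbed masks against one image) and extracts all four
#' families from every variant. Keys are `filter|family|name`.
#'
#' @param img normalized `vol3d` on an isotropic grid.
#' @param mask a [mask3d()] on the same grid.
#' @param config an [extraction_config()].
#' @param bank optional precomputed [filter_bank()] output for `img`.
#' @return named numeric vector of length 1224, stable order.
#' @export
extract_all <- function(img, mask, config = extraction_config(), bank = NULL) {
  if (is.null(bank)) bank <- filter_bank(img, config)
  fams <- c("firstorder", "glcm", "glrlm", "glszm")
  out <- unlist(lapply(names(bank), function(v) {
    roi <- roi_grey_array(bank[[v]], mask, config$bin_width)
    unlist(lapply(fams, function(f) {
      vals <- extract_family_roi(roi, f, voxel_volume(img))
      stats::setNames(as.numeric(vals), paste(v, f, names(vals), sep = "|"))
    }))
  }))
  stopifnot(length(out) == 1224L)
  out
}
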