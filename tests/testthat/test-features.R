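# Discretisation and the four feature families, checked against hand
# counts and brute-force matrix oracles.

test_that("fixed-bin-width discretisation matches the stated rule", {
  # full-range 0-600 ROI at width 5 gives exactly 120 grey levels
  d <- discretize(seq(0, 600, length.out = 5000), 5)
  expect_equal(d$n_bins, 120L)
  expect_equal(min(d$labels), 1L)
  expect_equal(max(d$labels), 120L)
  # hand example
  d <- discretize(c(0, 4.9, 5.0, 12), 5)
  expect_equal(d$labels, c(1L, 1L, 2L, 3L))
  expect_equal(d$n_bins, 3L)
  # constant ROI
  expect_equal(discretize(rep(4.2, 10), 5)$n_bins, 1L)
  expect_error(discretize(numeric(0), 5), "empty")
})

test_that("family vectors have the documented lengths and names", {
  expect_length(feature_names("firstorder"), 18)
  expect_length(feature_names("glcm"), 22)
  expect_length(feature_names("glrlm"), 16)
  expect_length(feature_names("glszm"), 16)
  expect_length(feature_names("all"), 1224)
  img <- vol3d(array(rnorm(512, 300, 60), c(8, 8, 8)), c(2, 2, 2))
  msk <- mask3d(array(as.integer(array(rnorm(512)) > -1), c(8, 8, 8)), c(2, 2, 2))
  for (fam in c("firstorder", "glcm", "glrlm", "glszm")) {
    v <- extract_family(img, msk, fam)
    expect_named(v, feature_names(fam))
    expect_true(all(is.finite(v)))
  }
})

test_that("a constant ROI is maximally ordered", {
  img <- vol3d(array(250, c(6, 6, 3)), c(2, 2, 2))
  msk <- mask3d(array(1L, c(6, 6, 3)), c(2, 2, 2))
  fo <- extract_family(img, msk, "firstorder")
  expect_equal(unname(fo["Entropy"]), 0)
  expect_equal(unname(fo["Uniformity"]), 1)
  expect_equal(unname(fo["Variance"]), 0)
  expect_equal(unname(fo["Skewness"]), 0)
  g <- extract_family(img, msk, "glcm")
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["JointEntropy"]), 0)
  expect_equal(unname(g["MaximumProbability"]), 1)
})

test_that("GLCM features agree with a brute-force co-occurrence oracle", {
  # 2x2x1 slab with columns at grey levels 1 and 2
  arr <- array(c(0, 0, 6, 6), c(2, 2, 1))
  img <- vol3d(arr, c(2, 2, 2))
  msk <- mask3d(array(1L, c(2, 2, 1)), c(2, 2, 2))
  got <- extract_family(img, msk, "glcm")

  G <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
  dirs <- segstab:::texture_directions()
  feats <- NULL; used <- 0
  for (r in seq_len(nrow(dirs))) {
    C <- brute_cooccurrence(G, 2, dirs[r, ])
    if (sum(C) == 0) next
    P <- C / sum(C)
    i <- row(P); j <- col(P)
    mu <- sum(i * P)
    f <- c(Contrast = sum((i - j)^2 * P),
           JointEnergy = sum(P^2),
           MaximumProbability = max(P),
           Autocorrelation = sum(i * j * P),
           JointEntropy = -sum(P[P > 0] * log2(P[P > 0])),
           SumSquares = sum((i - mu)^2 * P),
           Id = sum(P / (1 + abs(i - j))))
    feats <- if (is.null(feats)) f else feats + f
    used <- used + 1
  }
  expected <- feats / used
  for (nm in names(expected)) {
    expect_equal(unname(got[nm]), unname(expected[nm]), tolerance = 1e-12,
                 info = nm)
  }
})

test_that("GLRLM features agree with a brute-force run enumeration oracle", {
  set.seed(14)
  labels <- array(sample(1:3, 4 * 4 * 2, replace = TRUE), c(4, 4, 2))
  roi <- array(rbinom(32, 1, 0.8), c(4, 4, 2))
  roi[1, 1, 1] <- 1  # keep non-empty
  img <- vol3d(labels + 0, c(2, 2, 2))
  msk <- mask3d(roi, c(2, 2, 2))
  got <- extract_family(img, msk, "glrlm",
                        extraction_config(bin_width = 0.9))
  dd <- discretize(labels[roi > 0], 0.9)
  G <- array(0L, dim(labels)); G[roi > 0] <- dd$labels
  nb <- dd$n_bins
  Np <- sum(roi)
  dirs <- segstab:::texture_directions()
  acc <- NULL
  for (r in seq_len(nrow(dirs))) {
    runs <- brute_runs(G, dirs[r, ])
    P <- matrix(0, nb, max(runs[, 2]))
    for (q in seq_len(nrow(runs))) {
      P[runs[q, 1], runs[q, 2]] <- P[runs[q, 1], runs[q, 2]] + 1
    }
    Nr <- sum(P)
    g <- row(P); l <- col(P)
    f <- c(ShortRunEmphasis = sum(P / l^2) / Nr,
           LongRunEmphasis = sum(P * l^2) / Nr,
           RunPercentage = Nr / Np,
           GrayLevelNonUniformity = sum(rowSums(P)^2) / Nr,
           HighGrayLevelRunEmphasis = sum(P * g^2) / Nr)
    acc <- if (is.null(acc)) f else acc + f
  }
  expected <- acc / nrow(dirs)
  for (nm in names(expected)) {
    expect_equal(unname(got[nm]), unname(expected[nm]), tolerance = 1e-12,
                 info = nm)
  }
})

test_that("GLSZM features match a hand-counted zone decomposition", {
  # three 26-connected zones of size 3, one per grey level
  labels <- array(0L, c(3, 3, 1))
  labels[1, , 1] <- c(1L, 1L, 2L)
  labels[2, , 1] <- c(1L, 2L, 2L)
  labels[3, , 1] <- c(3L, 3L, 3L)
  img <- vol3d(labels + 0, c(2, 2, 2))
  msk <- mask3d(array(1L, c(3, 3, 1)), c(2, 2, 2))
  z <- extract_family(img, msk, "glszm", extraction_config(bin_width = 0.9))
  expect_equal(unname(z["SmallAreaEmphasis"]), 1 / 9, tolerance = 1e-12)
  expect_equal(unname(z["LargeAreaEmphasis"]), 9, tolerance = 1e-12)
  expect_equal(unname(z["ZonePercentage"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(z["GrayLevelNonUniformity"]), 1, tolerance = 1e-12)
  expect_equal(unname(z["SizeZoneNonUniformity"]), 3, tolerance = 1e-12)
  expect_equal(unname(z["GrayLevelVariance"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(z["ZoneVariance"]), 0, tolerance = 1e-12)
  expect_equal(unname(z["ZoneEntropy"]), log2(3), tolerance = 1e-12)
  expect_equal(unname(z["HighGrayLevelZoneEmphasis"]), 14 / 3, tolerance = 1e-12)
})

test_that("degenerate ROIs are flagged, not propagated as NaN", {
  img <- vol3d(array(rnorm(27, 300, 10), c(3, 3, 3)), c(2, 2, 2))
  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  msk <- mask3d(single, c(2, 2, 2))
  fo <- extract_family(img, msk, "firstorder")
  expect_true(all(is.finite(fo)))
  g <- extract_family(img, msk, "glcm")
  expect_true(all(g == 0))
  expect_true(isTRUE(attr(g, "degenerate")))
})

test_that("extract_all yields 1224 deterministic, stably-ordered features", {
  s <- small_subject(61)
  v1 <- extract_all(s$img, s$mask)
  expect_length(v1, 1224)
  expect_identical(names(v1), feature_names("all"))
  expect_true(all(is.finite(v1)))
  v2 <- extract_all(s$img, s$mask)
  expect_identical(v1, v2)
  # identity perturbation leaves every feature unchanged
  cfg0 <- augmentation_config(dw_bound = 0, dh_bound = 0, alpha_bound = 0,
                              slice_shift_max = 0, n_contours = 1, seed = 1)
  m0 <- augment(s$mask, cfg0)$perturbed[[1]]
  expect_identical(extract_all(s$img, m0), v1)
  # first-order Mean of the unfiltered normalized sequence sits at the
  # 300 target (up to clipping of a few ROI voxels)
  expect_equal(unname(v1[["original|firstorder|Mean"]]), 300, tolerance = 2)
})

test_that("direction-averaged texture features are 90-degree rotation coherent", {
  s <- small_subject(62)
  rim <- rot90_inplane(s$img)
  rmk <- rot90_inplane(s$mask)
  for (fam in c("firstorder", "glcm", "glrlm", "glszm")) {
    a <- extract_family(s$img, s$mask, fam)
    b <- extract_family(rim, rmk, fam)
    expect_equal(a, b, tolerance = 1e-9, info = fam)
  }
})
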