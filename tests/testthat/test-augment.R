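# The in silico contour generator: dice, in-plane and out-of-plane
# perturbations, bias structure, and the full augment contract.

test_that("dice handles the identity, disjoint, partial and empty cases", {
  a <- array(0L, c(4, 4, 1)); a[1:2, 1:2, 1] <- 1L
  b <- array(0L, c(4, 4, 1)); b[2:3, 1:2, 1] <- 1L   # overlap = 2 voxels
  ma <- mask3d(a); mb <- mask3d(b)
  expect_equal(dice(ma, ma), 1)
  expect_equal(dice(ma, mb), 2 * 2 / (4 + 4))
  dis <- mask3d(array(0L, c(4, 4, 1))); dis$data[4, 4, 1] <- 1L
  expect_equal(dice(ma, dis), 0)
  empty <- mask3d(array(0L, c(4, 4, 1)))
  expect_true(is.na(dice(empty, empty)))
  expect_error(dice(ma, mask3d(array(0L, c(4, 4, 2)))), "identical grids")
})

test_that("in-plane parameter sampling follows the stated uniform laws", {
  # degenerate bounds give the identity everywhere
  cfg0 <- augmentation_config(dw_bound = 0, dh_bound = 0, alpha_bound = 0)
  p0 <- sample_inplane_params(cfg0, 1:12)
  expect_true(all(p0$dw == 0 & p0$dh == 0 & p0$alpha == 0))

  # systematic bias: one sign per contour for each of dw, dh, alpha
  cfg <- augmentation_config(bias = "systematic")
  set.seed(4)
  for (r in 1:20) {
    p <- sample_inplane_params(cfg, 1:12)
    expect_true(length(unique(sign(p$dw[p$dw != 0]))) <= 1)
    expect_true(length(unique(sign(p$dh[p$dh != 0]))) <= 1)
    expect_true(length(unique(sign(p$alpha[p$alpha != 0]))) <= 1)
  }

  # random bias: Monte-Carlo check of U(-2.7, 2.7) per slice
  set.seed(5)
  p <- sample_inplane_params(augmentation_config(bias = "random"), 1:10000)
  se <- 2.7 / sqrt(3) / sqrt(10000)
  expect_lt(abs(mean(p$dw)), 3 * se)
  expect_lt(abs(mean(p$dh)), 3 * se)
  expect_true(all(abs(p$dw) <= 2.7 & abs(p$dh) <= 2.7 & abs(p$alpha) <= 5))
  # signs mix across slices under random bias
  expect_gt(sum(p$dw > 0), 4000)
  expect_gt(sum(p$dw < 0), 4000)
})

test_that("out-of-plane shifts are uniform on the 9 boundary combinations", {
  cfg <- augmentation_config(scenario = "out_plane")
  set.seed(6)
  draws <- t(replicate(9000, sample_outplane_shift(cfg)))
  expect_true(all(abs(draws) <= 1))
  freq <- table(factor(draws[, 1], levels = -1:1),
                factor(draws[, 2], levels = -1:1)) / 9000
  tol <- 3 * sqrt((1 / 9) * (8 / 9) / 9000)
  expect_true(all(abs(freq - 1 / 9) < tol))
  cfg0 <- augmentation_config(slice_shift_max = 0)
  expect_equal(unname(sample_outplane_shift(cfg0)), c(0, 0))
})

test_that("apply_inplane is exact on the identity and scales areas analytically", {
  m <- generate_phantom_mask(phantom_spec(seed = 31), "adc")
  fg <- which(apply(m$data, 3, sum) > 0)
  idp <- data.frame(slice = fg, dw = 0, dh = 0, alpha = 0, tx = 0, ty = 0)
  expect_identical(apply_inplane(m, idp)$data, m$data)
  expect_error(apply_inplane(m, idp[-1, ]), "cover all in-ROI slices")

  # a 20 mm disc grown by dw = dh = 2.7 mm gains area (22.7/20)^2
  n <- 161; spx <- 0.25
  xs <- (seq_len(n) - 81) * spx
  a <- array(0L, c(n, n, 1))
  a[, , 1][outer(xs, xs, function(u, v) u^2 + v^2 <= 100)] <- 1L
  disc <- mask3d(a, c(spx, spx, 3))
  grown <- apply_inplane(disc, data.frame(slice = 1, dw = 2.7, dh = 2.7,
                                          alpha = 0, tx = 0, ty = 0))
  expect_equal(sum(grown$data) / sum(disc$data), (22.7 / 20)^2,
               tolerance = 0.02)
  # pure rotation preserves the disc (rotational symmetry)
  rot <- apply_inplane(disc, data.frame(slice = 1, dw = 0, dh = 0,
                                        alpha = 5, tx = 0, ty = 0))
  expect_gt(dice(rot, disc), 0.99)
  # outputs stay binary on the same grid
  expect_true(all(grown$data %in% c(0L, 1L)))
  expect_true(same_grid(grown, disc))
})

test_that("default in-plane perturbations keep every contour above dice 0.88", {
  m <- generate_phantom_mask(phantom_spec(seed = 5), "adc")
  cfg <- augmentation_config(scenario = "in_plane", bias = "random",
                             n_contours = 100, seed = 2)
  d <- dice_vs_truth(augment(m, cfg))
  expect_true(all(d >= 0.88))
})

test_that("apply_outplane shifts each boundary independently", {
  m <- slab_mask(5:12)
  expect_identical(apply_outplane(m, 0, 0)$data, m$data)
  expect_equal(slice_span(apply_outplane(m, -1, -1)), c(6, 11))
  grown <- apply_outplane(m, +1, 0)
  expect_equal(slice_span(grown), c(5, 13))
  expect_identical(grown$data[, , 13], grown$data[, , 12])
  expect_equal(slice_span(apply_outplane(m, 0, +1)), c(4, 12))
  # errors: growth past the grid edge, shrink to nothing, sparse masks
  expect_error(apply_outplane(slab_mask(18:20), +1, 0), "past the grid")
  expect_error(apply_outplane(slab_mask(5:7), -2, -1), "empty the mask")
  expect_error(apply_outplane(slab_mask(c(5, 7, 9)), 0, 0), "consecutive")
})

test_that("augment emits k reproducible contours with complete logs", {
  m <- generate_phantom_mask(phantom_spec(semi_axes = c(14, 12, 13), seed = 41), "adc")
  cfg <- augmentation_config(scenario = "in_out_plane", bias = "systematic",
                             n_contours = 15, seed = 77)
  set <- augment(m, cfg)
  expect_length(set$perturbed, 15)
  expect_true(all(vapply(set$perturbed, function(p) same_grid(p, m), logical(1))))
  expect_true(all(vapply(set$perturbed, function(p) all(p$data %in% 0:1), logical(1))))
  # log completeness: one parameter row per in-ROI slice of the shifted mask
  for (i in seq_along(set$perturbed)) {
    l <- set$logs[[i]]
    shifted <- apply_outplane(m, l$delta_sup, l$delta_inf)
    fg <- which(apply(shifted$data, 3, sum) > 0)
    expect_setequal(l$params$slice, fg)
    expect_true(all(abs(l$delta_sup) <= 1 & abs(l$delta_inf) <= 1))
  }
  # seed determinism across the full call
  set2 <- augment(m, cfg)
  for (i in 1:15) expect_identical(set$perturbed[[i]]$data, set2$perturbed[[i]]$data)

  # zero-bound augmentation reproduces the ground truth exactly
  cfg0 <- augmentation_config(dw_bound = 0, dh_bound = 0, alpha_bound = 0,
                              slice_shift_max = 0, scenario = "in_out_plane",
                              n_contours = 15, seed = 1)
  set0 <- augment(m, cfg0)
  expect_true(all(dice_vs_truth(set0) == 1))
})

test_that("systematic bias leaves a sign-consistent volume signature", {
  m <- generate_phantom_mask(phantom_spec(seed = 51), "adc")
  cfg <- augmentation_config(scenario = "in_plane", bias = "systematic",
                             alpha_bound = 0, n_contours = 40, seed = 8)
  set <- augment(m, cfg)
  v0 <- sum(m$data)
  for (i in seq_along(set$perturbed)) {
    p <- set$logs[[i]]$params
    if (all(p$dw >= 0) && all(p$dh >= 0)) {
      expect_gte(sum(set$perturbed[[i]]$data), v0)
    }
    if (all(p$dw <= 0) && all(p$dh <= 0)) {
      expect_lte(sum(set$perturbed[[i]]$data), v0)
    }
  }
})

test_that("augmented sets serialise with their parameter logs", {
  m <- generate_phantom_mask(phantom_spec(semi_axes = c(10, 9, 9), seed = 6), "adc")
  set <- augment(m, augmentation_config(n_contours = 3, seed = 9,
                                        scenario = "in_out_plane"))
  d <- tempfile()
  write_augmented_set(set, d)
  expect_true(file.exists(file.path(d, "contour_gt.nii.gz")))
  expect_true(file.exists(file.path(d, "contour_003.nii.gz")))
  log <- jsonlite::read_json(file.path(d, "contour_log.json"),
                             simplifyVector = TRUE)
  expect_equal(log$n_contours, 3)
  expect_length(log$contours$delta_sup, 3)
})
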