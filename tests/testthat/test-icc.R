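# ICC(1,1) estimation, stability classification, robustness and summaries.

test_that("ICC hits its exact limiting cases", {
  # raters agree perfectly, subjects differ: ICC = 1
  m <- matrix(rep(1:6, 4), 6, 4)
  r <- icc_1_1(m)
  expect_equal(r$estimate, 1)
  expect_equal(r$ci_lower, 1)
  expect_false(r$degenerate)
  # identical cells everywhere: explicit degenerate marker, never silently 1
  r0 <- icc_1_1(matrix(5, 6, 4))
  expect_true(r0$degenerate)
  expect_true(is.na(r0$estimate))
  # pure noise with no subject effect: estimate near 0
  set.seed(20)
  rn <- icc_1_1(matrix(rnorm(500 * 8), 500, 8))
  expect_lt(abs(rn$estimate), 0.05)
  expect_error(icc_1_1(matrix(1:4, 2, 2)), "n >= 3")
  expect_error(icc_1_1(matrix(c(NA, rnorm(11)), 4, 3)), "missing")
})

test_that("estimate and CI match the brute-force ANOVA oracle", {
  set.seed(21)
  m <- matrix(rnorm(6 * 4, sd = 1), 6, 4) + 3 * rnorm(6)
  got <- icc_1_1(m)
  exp <- naive_icc(m)
  expect_equal(got$estimate, exp$estimate, tolerance = 1e-10)
  expect_equal(got$ci_lower, exp$ci_lower, tolerance = 1e-10)
  expect_equal(got$ci_upper, exp$ci_upper, tolerance = 1e-10)
  expect_true(got$ci_lower <= got$estimate && got$estimate <= got$ci_upper)
  expect_equal(got$df1, 5)
  expect_equal(got$df2, 18)
})

test_that("ICC is invariant under positive affine rescaling of ratings", {
  set.seed(22)
  m <- matrix(rnorm(10 * 5), 10, 5) + 2 * rnorm(10)
  a <- icc_1_1(m)
  b <- icc_1_1(3.2 * m - 40)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(a$ci_lower, b$ci_lower, tolerance = 1e-12)
})

test_that("the F-based interval has near-nominal coverage", {
  set.seed(23)
  rho <- 0.7
  n <- 100; k <- 8
  cover <- replicate(1000, {
    y <- matrix(rnorm(n, sd = sqrt(rho)), n, k) +
      matrix(rnorm(n * k, sd = sqrt(1 - rho)), n, k)
    r <- icc_1_1(y)
    r$ci_lower < rho && rho < r$ci_upper
  })
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})

test_that("stability uses a strict threshold on the CI lower bound", {
  df <- data.frame(ci_lower = c(0.91, 0.90, 0.89, NA),
                   degenerate = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(classify_stable(df, 0.90), c(TRUE, FALSE, FALSE, FALSE))
  # the stable set shrinks monotonically as the threshold rises
  set.seed(24)
  lows <- runif(200)
  sizes <- sapply(c(0.5, 0.7, 0.9, 0.95), function(th)
    sum(classify_stable(data.frame(ci_lower = lows), th)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("icc_table estimates every feature and excludes NaN columns", {
  set.seed(25)
  n <- 8; k <- 4
  ft <- data.frame(subject = rep(sprintf("s%d", 1:n), each = k),
                   rater = rep(sprintf("r%d", 1:k), n))
  ft[["original|firstorder|Mean"]] <- rep(rnorm(n, 100, 20), each = k) + rnorm(n * k)
  ft[["original|glcm|Contrast"]] <- rep(rnorm(n), each = k) + rnorm(n * k, sd = 3)
  ft[["wavelet-LLL|glszm|ZoneEntropy"]] <- c(NaN, rnorm(n * k - 1))
  tab <- icc_table(ft)
  expect_equal(nrow(tab), 3)
  expect_equal(attr(tab, "excluded"), "wavelet-LLL|glszm|ZoneEntropy")
  expect_true(is.na(tab$estimate[tab$feature == "wavelet-LLL|glszm|ZoneEntropy"]))
  expect_equal(tab$filter, c("original", "original", "wavelet-LLL"))
  expect_equal(tab$family, c("firstorder", "glcm", "glszm"))
  m <- ratings_matrix(ft, "original|firstorder|Mean")
  expect_equal(dim(m), c(n, k))
  expect_equal(tab$estimate[1], icc_1_1(m)$estimate)
})

test_that("robustness is the intersection of the two stable sets", {
  mk <- function(lows) {
    data.frame(feature = sprintf("original|glcm|f%02d", seq_along(lows)),
               filter = "original", family = "glcm",
               name = sprintf("f%02d", seq_along(lows)),
               estimate = pmin(1, lows + 0.05), ci_lower = lows,
               ci_upper = 1, degenerate = FALSE)
  }
  set.seed(26)
  li <- runif(40, 0.5, 1); le <- runif(40, 0.5, 1)
  rob <- assess_robustness(mk(li), mk(le))
  # brute-force set identity
  stable_i <- which(li > 0.9); stable_e <- which(le > 0.9)
  expect_equal(which(rob$robust), intersect(stable_i, stable_e))
  expect_equal(rob$overlap, pmin(li, le))
  # hand cases
  r2 <- assess_robustness(mk(c(0.95, 0.95)), mk(c(0.92, 0.80)))
  expect_equal(r2$robust, c(TRUE, FALSE))
  expect_equal(r2$stable_internal, c(TRUE, TRUE))
  # unmatched keys are reported
  ext <- mk(li); ext$feature <- sub("glcm", "glrlm", ext$feature)
  expect_error(assess_robustness(mk(li), ext), "unmatched")
})

test_that("best-filter selection is an argmax over the stable set", {
  filters <- c("original", "wavelet-LLL", "log-sigma-2-mm")
  rep1 <- expand.grid(filter = filters, name = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
  rep1$family <- "glcm"
  rep1$feature <- with(rep1, paste(filter, family, name, sep = "|"))
  # A: stable only under wavelet-LLL; B: all stable, distinct overlaps;
  # C: none stable
  rep1$ci_lower_internal <- c(0.5, 0.95, 0.6,   0.93, 0.96, 0.99,  0.1, 0.2, 0.3)
  rep1$ci_lower_external <- c(0.9, 0.94, 0.9,   0.97, 0.95, 0.92,  0.9, 0.9, 0.9)
  rep1$overlap <- pmin(rep1$ci_lower_internal, rep1$ci_lower_external)
  rep1$stable_internal <- rep1$ci_lower_internal > 0.9
  rep1$robust <- rep1$stable_internal & rep1$ci_lower_external > 0.9
  best <- select_best_filters(rep1)
  a <- best[best$name == "A", ]
  expect_equal(a$stable_filters, "wavelet-LLL")
  expect_equal(a$best_filters, "wavelet-LLL")
  b <- best[best$name == "B", ]
  # brute-force argmax over the stable set
  bsub <- rep1[rep1$name == "B" & rep1$stable_internal, ]
  expect_equal(b$best_filters, bsub$filter[which.max(bsub$overlap)])
  expect_equal(b$best_overlap, max(bsub$overlap))
  cc <- best[best$name == "C", ]
  expect_true(cc$no_stable_filter)
  expect_equal(cc$stable_filters, "")
})

test_that("fraction summaries match hand counts", {
  # 16 glszm features, 2 stable under the unfiltered variant
  nms <- sprintf("f%02d", 1:16)
  rep1 <- data.frame(filter = "original", family = "glszm", name = nms,
                     feature = paste("original|glszm|", nms),
                     stable = c(TRUE, TRUE, rep(FALSE, 14)),
                     ci_lower = 0.5, degenerate = FALSE)
  fr <- summarize_fractions(rep1)
  expect_equal(fr$O_stable[fr$family == "glszm"], 2 / 16)
  expect_true(is.na(fr$O_robust[1]))
  # all features stable in both datasets: all fractions 1
  rep2 <- expand.grid(filter = c("original", "square"),
                      family = c("glcm", "glrlm"), name = c("x", "y"),
                      stringsAsFactors = FALSE)
  rep2$feature <- with(rep2, paste(filter, family, name, sep = "|"))
  rep2$stable_internal <- TRUE
  rep2$robust <- TRUE
  fr2 <- summarize_fractions(rep2)
  expect_true(all(fr2$O_stable == 1 & fr2$O_robust == 1 &
                    fr2$BF_stable == 1 & fr2$BF_robust == 1))
  # overall fraction is the feature-count-weighted mean of family fractions
  fam_rows <- fr2[fr2$family != "overall", ]
  overall <- fr2[fr2$family == "overall", ]
  expect_equal(overall$O_stable,
               sum(fam_rows$O_stable * fam_rows$n_features) / sum(fam_rows$n_features))
})
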