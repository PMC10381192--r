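#' Intraclass correlation ICC(1,1) with F-based confidence interval
#'
#' One-way random-effects, single-rater, absolute-agreement intraclass
#' correlation: each subject is rated by `k` raters regarded as a random
#' sample of possible raters (here, synthetic contours). From the one-way
#' ANOVA decomposition with between-subject mean square `MSB` (df `n-1`) and
#' within-subject mean square `MSW` (df `n(k-1)`):
#' \deqn{ICC = (MSB - MSW) / (MSB + (k-1) MSW)}
#' and the `1-alpha` confidence interval follows from `F0 = MSB/MSW`:
#' lower `(FL-1)/(FL+k-1)` with `FL = F0 / qf(1-alpha/2, n-1, n(k-1))`,
#' upper `(FU-1)/(FU+k-1)` with `FU = F0 * qf(1-alpha/2, n(k-1), n-1)`.
#'
#' A matrix whose raters agree exactly on every subject while subjects
#' differ gives ICC = 1; a matrix with all cells identical has no variance
#' to apportion and is returned as an explicit degenerate marker (estimate
#' `NA`), never silently 1.
#'
#' @param m numeric matrix, subjects in rows (n >= 3), raters in columns
#'   (k >= 2), no missing cells.
#' @param alpha two-sided confidence level complement (default 0.05).
#' @return object of class `icc_result`: estimate, ci_lower, ci_upper,
#'   alpha, ms_between, ms_within, df1, df2, f_statistic, n, k, degenerate.
#' @export
icc_1_1 <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("ratings matrix must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) stop("need n >= 3 subjects and k >= 2 raters")
  row_means <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((m - row_means)^2) / (n * (k - 1))
  df1 <- n - 1
  df2 <- n * (k - 1)
  res <- list(estimate = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
              alpha = alpha, ms_between = msb, ms_within = msw,
              df1 = df1, df2 = df2, f_statistic = NA_real_,
              n = n, k = k, degenerate = FALSE)
  if (msb == 0 && msw == 0) {
    res$degenerate <- TRUE
    class(res) <- "icc_result"
    return(res)
  }
  if (msw == 0) {
    res$estimate <- 1
    res$ci_lower <- 1
    res$ci_upper <- 1
    res$f_statistic <- Inf
    class(res) <- "icc_result"
    return(res)
  }
  f0 <- msb / msw
  fl <- f0 / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f0 * stats::qf(1 - alpha / 2, df2, df1)
  res$estimate <- (msb - msw) / (msb + (k - 1) * msw)
  res$ci_lower <- (fl - 1) / (fl + k - 1)
  res$ci_upper <- (fu - 1) / (fu + k - 1)
  res$f_statistic <- f0
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<icc_result> degenerate (no variance in ratings)\n")
  } else {
    cat(sprintf("<icc_result> ICC(1,1) = %.4f, %d%% CI [%.4f, %.4f] (n=%d, k=%d)\n",
                x$estimate, round(100 * (1 - x$alpha)), x$ci_lower,
                x$ci_upper, x$n, x$k))
  }
  invisible(x)
}

#' Flag features as stable from their ICC confidence interval
#'
#' A feature is stable when the lower bound of its confidence interval lies
#' strictly above the threshold (default 0.90). Degenerate ICC results are
#' never stable.
#'
#' @param r an `icc_result`, or a data.frame with columns `ci_lower` and
#'   (optionally) `degenerate`.
#' @param threshold stability threshold on the CI lower bound.
#' @return logical (vector for data.frame input).
#' @export
classify_stable <- function(r, threshold = 0.90) {
  if (inherits(r, "icc_result")) {
    return(!r$degenerate && is.finite(r$ci_lower) && r$ci_lower > threshold)
  }
  if (is.data.frame(r)) {
    deg <- if ("degenerate" %in% names(r)) r$degenerate else FALSE
    return(!deg & !is.na(r$ci_lower) & r$ci_lower > threshold)
  }
  stop("`r` must be an icc_result or a data.frame")
}

#' Reshape a feature table into a subjects-by-raters ratings matrix
#'
#' @param ft a feature table (data.frame with `subject`, `rater` and feature
#'   columns), as produced by [extract_feature_table()].
#' @param feature one feature key (column name).
#' @return numeric matrix, subjects in rows and raters in columns.
#' @export
ratings_matrix <- function(ft, feature) {
  if (!feature %in% names(ft)) stop("unknown feature: ", feature)
  subj <- unique(ft$subject)
  raters <- unique(ft$rater)
  m <- matrix(NA_real_, length(subj), length(raters),
              dimnames = list(subj, raters))
  m[cbind(match(ft$subject, subj), match(ft$rater, raters))] <- ft[[feature]]
  m
}

#' Per-feature ICC(1,1) table for a feature table
#'
#' Computes ICC(1,1) with its confidence interval for every feature column.
#' Features containing any non-finite value across raters are excluded from
#' estimation (listed in the `excluded` attribute) rather than imputed.
#'
#' @param ft a feature table ([extract_feature_table()]).
#' @param alpha confidence level complement (default 0.05).
#' @param threshold stability threshold applied to the CI lower bound.
#' @return data.frame with one row per feature: `feature`, parsed
#'   `filter`/`family`/`name`, `estimate`, `ci_lower`, `ci_upper`,
#'   `degenerate`, `stable`, `n`, `k`.
#' @export
icc_table <- function(ft, alpha = 0.05, threshold = 0.90) {
  feat_cols <- setdiff(names(ft), c("subject", "rater", "sequence"))
  subj <- unique(ft$subject)
  raters <- unique(ft$rater)
  n <- length(subj); k <- length(raters)
  ri <- match(ft$subject, subj)
  ci <- match(ft$rater, raters)
  excluded <- character(0)
  rows <- lapply(feat_cols, function(fc) {
    m <- matrix(NA_real_, n, k)
    m[cbind(ri, ci)] <- ft[[fc]]
    if (any(!is.finite(m))) {
      excluded <<- c(excluded, fc)
      return(data.frame(feature = fc, estimate = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        degenerate = NA, n = n, k = k))
    }
    r <- icc_1_1(m, alpha)
    data.frame(feature = fc, estimate = r$estimate, ci_lower = r$ci_lower,
               ci_upper = r$ci_upper, degenerate = r$degenerate, n = n, k = k)
  })
  out <- do.call(rbind, rows)
  parts <- strsplit(out$feature, "|", fixed = TRUE)
  npart <- lengths(parts)
  if (all(npart == 3L)) {
    out$filter <- vapply(parts, `[`, "", 1)
    out$family <- vapply(parts, `[`, "", 2)
    out$name <- vapply(parts, `[`, "", 3)
  } else if (all(npart == 4L)) {
    out$sequence <- vapply(parts, `[`, "", 1)
    out$filter <- vapply(parts, `[`, "", 2)
    out$family <- vapply(parts, `[`, "", 3)
    out$name <- vapply(parts, `[`, "", 4)
  }
  out$stable <- classify_stable(out, threshold)
  out$stable[is.na(out$estimate) & is.na(out$degenerate)] <- NA
  attr(out, "excluded") <- excluded
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- threshold
  out
}

#' Cross-dataset robustness of stable features
#'
#' Joins the per-feature ICC tables of an internal and an external dataset
#' and labels a feature robust when the minimum of the two CI lower bounds
#' lies strictly above the threshold — equivalently, when the feature is
#' stable in both datasets. `sequence_map` renames external sequences before
#' matching (e.g. both wash-in and wash-out maps onto a single
#' scanner-derived subtraction map).
#'
#' @param internal,external [icc_table()] outputs.
#' @param threshold stability threshold.
#' @param sequence_map optional named character, internal sequence ->
#'   external sequence.
#' @return robustness report: data.frame with per-feature internal/external
#'   lower bounds, `overlap` (their minimum), `stable_internal`,
#'   `stable_external` and `robust` flags.
#' @export
assess_robustness <- function(internal, external, threshold = 0.90,
                              sequence_map = NULL) {
  key_int <- internal$feature
  key_ext <- external$feature
  if (!is.null(sequence_map) && "sequence" %in% names(internal)) {
    mapped <- ifelse(internal$sequence %in% names(sequence_map),
                     sequence_map[internal$sequence], internal$sequence)
    key_int <- paste(mapped,
                     internal$filter, internal$family, internal$name,
                     sep = "|")
  }
  j <- match(key_int, key_ext)
  if (any(is.na(j))) {
    stop("unmatched feature keys: ",
         paste(utils::head(key_int[is.na(j)], 10), collapse = ", "))
  }
  out <- internal[, intersect(c("feature", "sequence", "filter", "family", "name"),
                              names(internal)), drop = FALSE]
  out$ci_lower_internal <- internal$ci_lower
  out$ci_lower_external <- external$ci_lower[j]
  out$overlap <- pmin(out$ci_lower_internal, out$ci_lower_external)
  out$stable_internal <- classify_stable(
    data.frame(ci_lower = out$ci_lower_internal), threshold)
  out$stable_external <- classify_stable(
    data.frame(ci_lower = out$ci_lower_external), threshold)
  out$robust <- out$stable_internal & out$stable_external &
    !is.na(out$overlap) & out$overlap > threshold
  attr(out, "threshold") <- threshold
  out
}

#' Best-filter selection per base feature
#'
#' For each base feature (family + name), the stable-filter set is the set
#' of filter variants whose internal CI lower bound clears the threshold;
#' the best filter(s) maximise the cross-dataset overlap (minimum of the two
#' lower bounds) over that set, with ties all reported. Features with an
#' empty stable set are flagged `no_stable_filter`.
#'
#' @param report an [assess_robustness()] report (needs `filter`, `family`,
#'   `name`, `overlap`, `stable_internal`).
#' @param threshold stability threshold.
#' @return data.frame with one row per (sequence,) family, name:
#'   `stable_filters` and `best_filters` (comma-collapsed), `best_overlap`,
#'   `no_stable_filter`.
#' @export
select_best_filters <- function(report, threshold = 0.90) {
  stopifnot(all(c("filter", "family", "name") %in% names(report)))
  has_seq <- "sequence" %in% names(report)
  keys <- if (has_seq) {
    paste(report$sequence, report$family, report$name, sep = "|")
  } else paste(report$family, report$name, sep = "|")
  rows <- lapply(split(seq_len(nrow(report)), keys), function(ii) {
    sub <- report[ii, ]
    st <- sub[sub$stable_internal %in% TRUE, ]
    base <- sub[1, intersect(c("sequence", "family", "name"), names(sub)),
                drop = FALSE]
    if (nrow(st) == 0L) {
      base$stable_filters <- ""
      base$best_filters <- ""
      base$best_overlap <- NA_real_
      base$no_stable_filter <- TRUE
    } else {
      best <- st$overlap == max(st$overlap)
      base$stable_filters <- paste(st$filter, collapse = ",")
      base$best_filters <- paste(st$filter[best], collapse = ",")
      base$best_overlap <- max(st$overlap)
      base$no_stable_filter <- FALSE
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Family-level stable/robust fraction summary
#'
#' For each feature family (optionally per sequence) and overall, the
#' fraction of base features that are stable / robust in the Original
#' (unfiltered) configuration and in the Best-Filtered configuration, where
#' a base feature counts as BF-stable (BF-robust) if any of its filter
#' variants qualifies.
#'
#' @param report an [assess_robustness()] report, or an [icc_table()] with
#'   `stable` (then only stable fractions are reported).
#' @return data.frame with columns `sequence` (optional), `family`,
#'   `n_features`, `O_stable`, `O_robust`, `BF_stable`, `BF_robust`
#'   (robust columns `NA` without external data), plus an `overall` row per
#'   sequence.
#' @export
summarize_fractions <- function(report) {
  stopifnot(all(c("filter", "family", "name") %in% names(report)))
  stable <- if ("stable_internal" %in% names(report)) report$stable_internal else report$stable
  robust <- if ("robust" %in% names(report)) report$robust else rep(NA, nrow(report))
  has_seq <- "sequence" %in% names(report)
  seqs <- if (has_seq) report$sequence else rep("all", nrow(report))
  base_key <- paste(seqs, report$family, report$name, sep = "|")
  one_group <- function(ii) {
    orig <- report$filter[ii] == "original"
    bkey <- base_key[ii]
    nb <- length(unique(bkey))
    any_by <- function(flag) {
      v <- tapply(flag[ii], bkey, function(z) any(z %in% TRUE))
      mean(v)
    }
    data.frame(n_features = nb,
               O_stable = mean(stable[ii][orig] %in% TRUE),
               O_robust = if (all(is.na(robust))) NA_real_ else mean(robust[ii][orig] %in% TRUE),
               BF_stable = any_by(stable),
               BF_robust = if (all(is.na(robust))) NA_real_ else any_by(robust))
  }
  rows <- list()
  for (sq in unique(seqs)) {
    for (fam in unique(report$family)) {
      ii <- which(seqs == sq & report$family == fam)
      if (length(ii) == 0L) next
      r <- one_group(ii)
      r <- cbind(data.frame(sequence = sq, family = fam), r)
      rows[[length(rows) + 1L]] <- r
    }
    ii <- which(seqs == sq)
    r <- cbind(data.frame(sequence = sq, family = "overall"), one_group(ii))
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  if (!has_seq) out$sequence <- NULL
  rownames(out) <- NULL
  out
}
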