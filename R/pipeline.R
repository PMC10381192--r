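#' Extract a feature table across raters
#'
#' Runs the filter bank once on the normalized image and extracts the full
#' 1224-feature vector for every rater mask (ground truth and/or synthetic
#' contours), all sharing the image grid.
#'
#' @param img normalized `vol3d` on an isotropic grid.
#' @param masks named list of [mask3d()] rater masks.
#' @param config an [extraction_config()].
#' @param subject subject identifier recorded in the table.
#' @return data.frame with columns `subject`, `rater` and the 1224 feature
#'   columns keyed `filter|family|name`.
#' @export
extract_feature_table <- function(img, masks, config = extraction_config(),
                                  subject = "s1") {
  bank <- filter_bank(img, config)
  rows <- lapply(names(masks), function(r) {
    v <- extract_all(img, masks[[r]], config, bank = bank)
    cbind(data.frame(subject = subject, rater = r),
          as.data.frame(as.list(v), check.names = FALSE, optional = TRUE))
  })
  do.call(rbind, rows)
}

#' The five augmentation scenarios
#'
#' @return data.frame naming each scenario (`in_plane` / `out_plane` /
#'   `in_out_plane`) with its bias, in the canonical order.
#' @export
scenario_table <- function() {
  data.frame(
    label = c("InP-R", "InP-S", "OutP", "In&OutP-R", "In&OutP-S"),
    scenario = c("in_plane", "in_plane", "out_plane",
                 "in_out_plane", "in_out_plane"),
    bias = c("random", "systematic", "random", "random", "systematic"),
    stringsAsFactors = FALSE)
}

#' Phantom-scale Dice experiment
#'
#' Generates `n_subjects` irregular phantom glands (per-subject semi-axes
#' jittered +/-10% around the prostate-scale defaults), draws `n_contours`
#' synthetic contours per subject under one scenario/bias, and returns the
#' Dice of every contour against its ground truth on the native grid.
#'
#' @param scenario,bias augmentation scenario and bias.
#' @param n_subjects number of phantom subjects (default 100).
#' @param n_contours contours per subject (default 15).
#' @param seed RNG seed for the whole experiment.
#' @param spacing native grid spacing in mm (diffusion-like by default).
#' @param semi_axes,surface_irregularity gland geometry (see
#'   [phantom_spec()]).
#' @param jitter relative half-range of per-subject semi-axis variation.
#' @param config_args extra arguments passed to [augmentation_config()].
#' @return list with `mean`, `sd` and the full `dice` vector
#'   (`n_subjects * n_contours` values).
#' @export
dice_experiment <- function(scenario, bias = "random", n_subjects = 100,
                            n_contours = 15, seed = 1,
                            spacing = c(1.25, 1.25, 3),
                            semi_axes = c(22.5, 19, 20),
                            surface_irregularity = 0.1,
                            jitter = 0.1, config_args = list()) {
  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  dices <- numeric(0)
  for (i in seq_len(n_subjects)) {
    set.seed(subj_seeds[i])
    jit <- stats::runif(3, 1 - jitter, 1 + jitter)
    shape_seed <- sample.int(.Machine$integer.max - 1L, 1)
    aug_seed <- sample.int(.Machine$integer.max - 1L, 1)
    spec <- phantom_spec(semi_axes = semi_axes * jit,
                         surface_irregularity = surface_irregularity,
                         spacing = list(native = spacing),
                         seed = shape_seed)
    mask <- generate_phantom_mask(spec, sequence = "native")
    cfg <- do.call(augmentation_config,
                   c(list(scenario = scenario, bias = bias,
                          n_contours = n_contours, seed = aug_seed),
                     config_args))
    set <- augment(mask, cfg)
    dices <- c(dices, dice_vs_truth(set))
  }
  list(mean = mean(dices), sd = stats::sd(dices), dice = dices)
}

#' End-to-end run configuration
#'
#' Composition of the stage configurations for [run_experiment()].
#'
#' @param n_subjects number of phantom subjects.
#' @param sequences subset of `c("t2w", "adc", "sub_win", "sub_wout")`.
#' @param scenarios subset of `scenario_table()$label`.
#' @param phantom a [phantom_spec()] template (per-subject seeds are derived
#'   from `seed`).
#' @param augmentation an [augmentation_config()] template.
#' @param preprocess a [preprocess_config()].
#' @param extraction an [extraction_config()].
#' @param threshold,alpha stability threshold and CI level.
#' @param include_original include the ground-truth contour as a rater
#'   (k = 1 + n_contours).
#' @param seed global seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_subjects = 10, sequences = "t2w",
                       scenarios = scenario_table()$label,
                       phantom = phantom_spec(),
                       augmentation = augmentation_config(),
                       preprocess = preprocess_config(),
                       extraction = extraction_config(),
                       threshold = 0.90, alpha = 0.05,
                       include_original = TRUE, seed = 1L) {
  stopifnot(all(scenarios %in% scenario_table()$label))
  stopifnot(all(sequences %in% c("t2w", "adc", "sub_win", "sub_wout")))
  structure(list(n_subjects = n_subjects, sequences = sequences,
                 scenarios = scenarios, phantom = phantom,
                 augmentation = augmentation, preprocess = preprocess,
                 extraction = extraction, threshold = threshold,
                 alpha = alpha, include_original = include_original,
                 seed = as.integer(seed)),
            class = "run_config")
}

native_for_sequence <- function(subject, sequence) {
  switch(sequence,
    t2w = list(img = subject$t2w, mask = subject$t2w_mask),
    adc = list(img = compute_adc_map(subject$dwi,
                 as.numeric(sub("^b", "", names(subject$dwi)))),
               mask = subject$dwi_mask),
    sub_win = ,
    sub_wout = {
      subs <- compute_sub_maps(subject$dce)
      list(img = subs[[sequence]], mask = subject$dce_mask)
    })
}

#' Run the full phantom stability experiment
#'
#' For every configured scenario and sequence: generate phantom subjects,
#' synthesise contours on the native mask grid, record the Dice
#' distribution, preprocess (derived maps in native space, resample to the
#' isotropic target, normalize on the ground-truth ROI — pooled across
#' subjects for the ADC map), extract the 1224-feature table over all
#' raters, estimate per-feature ICC(1,1) and summarise stable fractions.
#' All tables are written as CSV under `out_dir` together with a JSON
#' manifest (config, seeds, package version); re-running with the same
#' manifest reproduces the numeric outputs.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with `dice_summary`, per-scenario `icc` tables
#'   and `fractions`, and the manifest.
#' @export
run_experiment <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_subjects)
  scen <- scenario_table()
  scen <- scen[scen$label %in% cfg$scenarios, ]
  dice_rows <- list()
  results <- list()

  # phantom subjects are generated once and shared across scenarios
  subjects <- lapply(seq_len(cfg$n_subjects), function(i) {
    sp <- cfg$phantom
    sp$seed <- subj_seeds[i]
    generate_mpmri_phantom(sp)
  })

  for (si in seq_len(nrow(scen))) {
    lab <- scen$label[si]
    per_seq <- list()
    for (sq in cfg$sequences) {
      tables <- list()
      dvals <- numeric(0)
      imgs_rs <- list(); masks_rs <- list(); rater_masks_rs <- list()
      for (i in seq_len(cfg$n_subjects)) {
        nat <- native_for_sequence(subjects[[i]], sq)
        aug_cfg <- cfg$augmentation
        aug_cfg$scenario <- scen$scenario[si]
        aug_cfg$bias <- scen$bias[si]
        aug_cfg$seed <- (subj_seeds[i] + 7L * si + match(sq, cfg$sequences)) %%
          .Machine$integer.max
        set <- augment(nat$mask, aug_cfg)
        dvals <- c(dvals, dice_vs_truth(set))
        img_rs <- resample_image(nat$img, cfg$preprocess, kind = "intensity")
        gt_rs <- resample_image(nat$mask, cfg$preprocess, kind = "mask")
        raters <- lapply(set$perturbed, resample_image, config = cfg$preprocess,
                         kind = "mask")
        names(raters) <- sprintf("contour_%02d", seq_along(raters))
        if (cfg$include_original) raters <- c(list(original = gt_rs), raters)
        imgs_rs[[i]] <- img_rs; masks_rs[[i]] <- gt_rs
        rater_masks_rs[[i]] <- raters
      }
      norm_imgs <- if (sq == "adc") {
        normalize_population(imgs_rs, masks_rs, cfg$preprocess)
      } else {
        lapply(seq_along(imgs_rs), function(i)
          normalize_roi(imgs_rs[[i]], masks_rs[[i]], cfg$preprocess))
      }
      for (i in seq_len(cfg$n_subjects)) {
        tables[[i]] <- extract_feature_table(
          norm_imgs[[i]], rater_masks_rs[[i]], cfg$extraction,
          subject = sprintf("subject_%03d", i))
      }
      ft <- do.call(rbind, tables)
      icc <- icc_table(ft, alpha = cfg$alpha, threshold = cfg$threshold)
      icc$sequence <- sq
      per_seq[[sq]] <- list(features = ft, icc = icc)
      dice_rows[[length(dice_rows) + 1L]] <-
        data.frame(scenario = lab, sequence = sq,
                   mean = mean(dvals), sd = stats::sd(dvals),
                   n = length(dvals))
    }
    icc_all <- do.call(rbind, lapply(per_seq, `[[`, "icc"))
    fractions <- summarize_fractions(icc_all)
    slug <- gsub("[^A-Za-z]", "_", lab)
    utils::write.csv(icc_all, file.path(out_dir, sprintf("icc_%s.csv", slug)),
                     row.names = FALSE)
    utils::write.csv(fractions,
                     file.path(out_dir, sprintf("fractions_%s.csv", slug)),
                     row.names = FALSE)
    for (sq in names(per_seq)) {
      utils::write.csv(per_seq[[sq]]$features,
                       file.path(out_dir, sprintf("features_%s_%s.csv", slug, sq)),
                       row.names = FALSE)
    }
    results[[lab]] <- list(icc = icc_all, fractions = fractions)
  }
  dice_summary <- do.call(rbind, dice_rows)
  utils::write.csv(dice_summary, file.path(out_dir, "dice_summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("segstab")),
    seed = cfg$seed, subject_seeds = subj_seeds,
    n_subjects = cfg$n_subjects, sequences = cfg$sequences,
    scenarios = cfg$scenarios, threshold = cfg$threshold, alpha = cfg$alpha,
    include_original = cfg$include_original,
    k_raters = cfg$augmentation$n_contours + as.integer(cfg$include_original),
    augmentation = unclass(cfg$augmentation),
    preprocess = unclass(cfg$preprocess),
    bin_width = cfg$extraction$bin_width)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(dice_summary = dice_summary, results = results,
                 manifest = manifest))
}
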