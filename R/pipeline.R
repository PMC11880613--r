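#' Default run configuration for the end-to-end pipeline
#'
#' Nested sections, one per stage; every stage reads only its own
#' section.  One global seed fans out to stage-specific seeds via
#' stable hashing so each stage is independently reproducible.  The
#' defaults describe a scaled-down run (small grid, tiny models) that
#' exercises every stage on one CPU; pass `grid = c(240, 240, 155)`
#' style overrides for full-geometry work.
#'
#' @param seed Global seed.
#' @param out_dir Run directory.
#' @param n_subjects Number of phantom subjects to synthesize.
#' @param grid Phantom grid shape.
#' @param scenarios List of modality sets to train (default: the nine
#'   columns of the standard comparison — four singles, four
#'   combinations, plus the ensemble added by the `ensemble` stage).
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("xaimri-run-"),
                       n_subjects = 6L, grid = c(48L, 48L, 40L),
                       scenarios = NULL) {
  if (is.null(scenarios))
    scenarios <- list("T1", "T2", "T1ce", "FLAIR",
                      c("T2", "T1ce"), c("T2", "FLAIR"),
                      c("T1ce", "FLAIR"), c("T2", "T1ce", "FLAIR"))
  structure(list(
    seed = .check_count(seed, "seed"),
    out_dir = out_dir,
    phantom = list(n_subjects = .check_count(n_subjects, "n_subjects", 3L),
                   grid = as.integer(grid), noise_sigma = 10,
                   # at reduced grids tumors occupy a larger radius
                   # fraction so sub-region voxel fractions stay in the
                   # regime of full-scale data
                   tumor_radius_frac_range = c(0.40, 0.55)),
    preprocess = list(reference_slice = as.integer(grid[3L] %/% 2),
                      depth_range = c(as.integer((grid[3L] - 32L) %/% 2),
                                      as.integer((grid[3L] - 32L) %/% 2 + 32L)),
                      target_inplane = 32L),
    model = list(depth_levels = 2L, base_filters = 4L, dropout_rate = 0.1),
    training = list(batch_size = 4L, max_epochs = 8L, learning_rate = 3e-3,
                    patience = 5L),
    ensemble = list(base_a = c("T2", "T1ce"), base_b = c("T1ce", "FLAIR"),
                    fusion_filters = 16L, freeze_base = TRUE),
    gradcam = list(target_class = 3L, slice_index = 16L),
    scenarios = scenarios,
    split = list(fractions = c(0.70, 0.15, 0.15))),
    class = "run_config")
}

.scenario_name <- function(mods) paste(mods, collapse = "_")

.stage_done <- function(dir, stage) file.exists(file.path(dir, paste0(stage, ".done")))
.mark_done <- function(dir, stage) {
  writeLines(format(Sys.time()), file.path(dir, paste0(stage, ".done")))
}

#' Run the pipeline stages
#'
#' Executes, in order, any subset of: `synth` (phantom generation to a
#' BraTS-layout directory), `preprocess`, `train` (one model per
#' configured scenario), `ensemble` (fuse the two configured dual
#' models), `evaluate` (a metrics report per scenario on the test
#' split), `gradcam` (heat map + overlay for one test subject).
#' Completed stages are skipped on re-runs unless `force = TRUE`; the
#' resolved configuration is written into the run directory.
#'
#' @param config A [run_config()].
#' @param stages Character vector, subset of
#'   `c("synth", "preprocess", "train", "ensemble", "evaluate",
#'   "gradcam")`.
#' @param force Recompute stages already marked complete.
#' @param verbose Print stage progress.
#' @return The run directory path, invisibly; artifacts and JSON
#'   reports live beneath it.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("synth", "preprocess", "train",
                                    "ensemble", "evaluate", "gradcam"),
                         force = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, c("synth", "preprocess", "train", "ensemble",
                                "evaluate", "gradcam"), several.ok = TRUE)
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  say <- function(...) if (verbose) message(sprintf(...))

  env <- new.env()
  ids <- sprintf("phantom-%03d", seq_len(config$phantom$n_subjects))

  if ("synth" %in% stages) {
    if (.stage_done(dir, "synth") && !force) {
      say("stage synth: already complete, skipping")
    } else {
      say("stage synth: %d subjects on grid (%s)",
          length(ids), paste(config$phantom$grid, collapse = ", "))
      for (i in seq_along(ids)) {
        spec <- phantom_spec(grid_shape = config$phantom$grid,
                             noise_sigma = config$phantom$noise_sigma,
                             tumor_radius_frac_range =
                               config$phantom$tumor_radius_frac_range,
                             seed = derive_seed(config$seed, "synth"))
        write_brats_layout(generate_subject(spec, ids[i]),
                           file.path(dir, "data"))
      }
      .mark_done(dir, "synth")
    }
  }

  pp_cfg <- preprocess_config(
    reference_slice = config$preprocess$reference_slice,
    depth_range = config$preprocess$depth_range,
    target_inplane = config$preprocess$target_inplane)

  need_prep <- any(c("preprocess", "train", "ensemble", "evaluate",
                     "gradcam") %in% stages)
  if (need_prep) {
    if (!dir.exists(file.path(dir, "data")))
      .stopf("pipeline stage needs synthesized data; run the 'synth' stage first")
    records <- discover_subjects(file.path(dir, "data"))
    if (length(records) == 0L)
      .stopf("pipeline stage needs synthesized data; run the 'synth' stage first")
    env$preps <- lapply(records, preprocess_subject, config = pp_cfg)
    names(env$preps) <- vapply(records, `[[`, "", "subject_id")
    if ("preprocess" %in% stages && (!.stage_done(dir, "preprocess") || force)) {
      say("stage preprocess: %d subjects -> (%d, %d, %d)",
          length(env$preps), pp_cfg$target_inplane, pp_cfg$target_inplane,
          diff(pp_cfg$depth_range))
      .mark_done(dir, "preprocess")
    }
    env$split <- split_dataset(names(env$preps),
                               config$split$fractions,
                               seed = derive_seed(config$seed, "split"))
    write_split(env$split, file.path(dir, "split.json"))
  }

  part <- function(idset, mods) make_dataset(env$preps[idset], mods)

  if ("train" %in% stages) {
    for (mods in config$scenarios) {
      nm <- .scenario_name(mods)
      rd <- file.path(dir, "runs", nm)
      if (.stage_done(rd, "train") && !force) {
        say("stage train[%s]: already complete, skipping", nm)
        next
      }
      say("stage train[%s]", nm)
      cfg <- unet_config(in_channels = length(mods),
                         depth_levels = config$model$depth_levels,
                         base_filters = config$model$base_filters,
                         dropout_rate = config$model$dropout_rate)
      model <- build_unet(cfg, seed = derive_seed(config$seed,
                                                  paste0("init-", nm)))
      model$modalities <- mods
      tc <- train_config(batch_size = config$training$batch_size,
                         max_epochs = config$training$max_epochs,
                         learning_rate = config$training$learning_rate,
                         patience = config$training$patience,
                         seed = derive_seed(config$seed, paste0("train-", nm)))
      train(model, part(env$split$train_ids, mods),
            part(env$split$val_ids, mods), tc, run_dir = rd)
      .mark_done(rd, "train")
    }
  }

  if ("ensemble" %in% stages) {
    rd <- file.path(dir, "runs", "ensemble")
    if (.stage_done(rd, "ensemble") && !force) {
      say("stage ensemble: already complete, skipping")
    } else {
      nm_a <- .scenario_name(config$ensemble$base_a)
      nm_b <- .scenario_name(config$ensemble$base_b)
      pa <- file.path(dir, "runs", nm_a, "best.rds")
      pb <- file.path(dir, "runs", nm_b, "best.rds")
      for (p in c(pa, pb))
        if (!file.exists(p))
          .stopf("ensemble stage needs the trained base '%s'; run 'train' first",
                 dirname(p))
      say("stage ensemble: %s + %s", nm_a, nm_b)
      ens <- build_ensemble(load_checkpoint(pa), load_checkpoint(pb),
                            ensemble_config(
                              fusion_filters = config$ensemble$fusion_filters,
                              freeze_base = config$ensemble$freeze_base),
                            seed = derive_seed(config$seed, "ensemble-init"))
      tc <- train_config(batch_size = config$training$batch_size,
                         max_epochs = config$training$max_epochs,
                         learning_rate = config$training$learning_rate,
                         patience = config$training$patience,
                         seed = derive_seed(config$seed, "train-ensemble"))
      train(ens, part(env$split$train_ids, ens$modalities),
            part(env$split$val_ids, ens$modalities), tc, run_dir = rd)
      .mark_done(rd, "ensemble")
    }
  }

  if ("evaluate" %in% stages) {
    say("stage evaluate")
    reports <- list()
    for (mods in config$scenarios) {
      nm <- .scenario_name(mods)
      p <- file.path(dir, "runs", nm, "best.rds")
      if (!file.exists(p))
        .stopf("evaluate stage needs trained model '%s'; run 'train' first", nm)
      model <- load_checkpoint(p)
      reports[[nm]] <- evaluate(model, part(env$split$test_ids, mods))
    }
    pe <- file.path(dir, "runs", "ensemble", "best.rds")
    if (file.exists(pe)) {
      ens <- load_checkpoint(pe)
      reports[[paste0(.scenario_name(config$ensemble$base_a), "+",
                      .scenario_name(config$ensemble$base_b))]] <-
        evaluate(ens, part(env$split$test_ids, ens$modalities))
    }
    .write_json(lapply(reports, function(r)
      r[c("accuracy", "mean_iou", "dice_coef", "precision", "sensitivity",
          "specificity")]),
      file.path(dir, "evaluation.json"))
    env$reports <- reports
  }

  if ("gradcam" %in% stages) {
    pe <- file.path(dir, "runs", "ensemble", "best.rds")
    if (!file.exists(pe))
      .stopf("gradcam stage needs the trained ensemble; run 'ensemble' first")
    say("stage gradcam")
    ens <- load_checkpoint(pe)
    sid <- env$split$test_ids[1L]
    x <- stack_modalities(env$preps[[sid]], ens$modalities)
    hm <- compute_gradcam(ens, x,
                          gradcam_config(target_class =
                                           config$gradcam$target_class))
    write_heatmap(hm, file.path(dir, sprintf("gradcam_%s.nii.gz", sid)))
    overlay(hm, env$preps[[sid]]$volumes[[ens$modalities[1L]]],
            slice_index = config$gradcam$slice_index,
            file = file.path(dir, sprintf("gradcam_%s.png", sid)))
  }

  attr(dir, "reports") <- env$reports
  invisible(dir)
}
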