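## End-to-end orchestration: configuration, the synth -> tile -> label ->
## train -> aggregate -> evaluate pipeline, and artifact writing.

milts_config_keys <- c(
  "seed", "threshold", "labeled_proportion", "epochs", "batch_size",
  "base_lr", "min_lr", "lr_cycles", "momentum", "lambda", "ema_decay",
  "encoder_d", "encoder_input_px", "slide_lr", "slide_epochs",
  "n_patients", "slides_per_patient", "image_size", "witness_lo",
  "witness_hi", "tissue_coverage", "nucleus_density", "witness_density",
  "expression_cutoff", "mpp", "mask_low", "mask_high", "mask_downsample",
  "min_tissue_fraction", "bootstrap", "arm", "out_dir")

#' Experiment configuration
#'
#' A flat key-value configuration for [run_experiment()].  Training
#' defaults follow the full-scale recipe (`lambda = 100`, EMA decay
#' 0.99, batch 512, 30 epochs, learning rate `1e-2` annealed to `1e-4`
#' over two cosine cycles, labeled proportion tied to the threshold
#' kind); cohort defaults describe the desk-scale synthetic benchmark.
#' Unknown keys are rejected.
#'
#' @param ... key-value overrides of the defaults (see
#'   `milts:::milts_config_keys`).
#' @return An object of class `milts_config`.
#' @export
milts_config <- function(...) {
  defaults <- list(
    seed = 1L, threshold = "median", labeled_proportion = NA_real_,
    epochs = 30L, batch_size = 512L, base_lr = 1e-2, min_lr = 1e-4,
    lr_cycles = 2L, momentum = 0.9, lambda = 100, ema_decay = 0.99,
    encoder_d = 32L, encoder_input_px = 32L,
    slide_lr = 2e-4, slide_epochs = 500L,
    n_patients = 20L, slides_per_patient = 1L, image_size = 1536L,
    witness_lo = 0.2, witness_hi = 0.5, tissue_coverage = 0.7,
    nucleus_density = 40, witness_density = 260,
    expression_cutoff = 10, mpp = 0.5,
    mask_low = 0.05, mask_high = 0.15, mask_downsample = 32L,
    min_tissue_fraction = 0.05, bootstrap = 2000L,
    arm = "full", out_dir = NA_character_)
  over <- list(...)
  unknown <- setdiff(names(over), milts_config_keys)
  if (length(unknown))
    stopf("unknown configuration keys: %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, over)
  for (k in c("seed", "epochs", "batch_size", "lr_cycles", "encoder_d",
              "encoder_input_px", "slide_epochs", "n_patients",
              "slides_per_patient", "image_size", "mask_downsample",
              "bootstrap"))
    cfg[[k]] <- as.integer(cfg[[k]])
  if (!cfg$arm %in% c("full", "fs_avgpool"))
    stopf("arm must be 'full' or 'fs_avgpool'")
  cfg$threshold <- match.arg(cfg$threshold,
                             c("median", "tertile", "quartile"))
  if (is.na(cfg$labeled_proportion))
    cfg$labeled_proportion <- labeled_proportion(cfg$threshold)
  structure(cfg, class = "milts_config")
}

#' Write / read a configuration as flat YAML
#'
#' Round-trips exactly: `read_milts_config(write_milts_config(cfg, f))`
#' resolves to the same settings.  Unknown keys in the file are
#' rejected.
#'
#' @param config a [milts_config()].
#' @param path file path.
#' @return `write_milts_config` returns `path` invisibly;
#'   `read_milts_config` returns a `milts_config`.
#' @export
write_milts_config <- function(config, path) {
  x <- unclass(config)
  x$out_dir <- if (is.na(x$out_dir)) NULL else x$out_dir
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_milts_config
#' @export
read_milts_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(milts_config, x)
}

## Tile one synthetic slide into a bag carrying ground-truth witness
## flags matched by tile coordinates.
tile_synthetic_slide <- function(gen, label, config) {
  mask <- compute_tissue_mask(gen$slide, config$mask_low,
                              config$mask_high, config$mask_downsample)
  tiles <- extract_tiles(gen$slide, mask,
                         min_tissue_fraction = config$min_tissue_fraction,
                         out_px = config$encoder_input_px)
  if (length(tiles) == 0L) return(NULL)
  tt <- gen$truth$tiles
  key <- paste(tt$x, tt$y)
  wit <- vapply(tiles, function(t)
    tt$witness[match(paste(t$x, t$y), key)], 0L)
  bag <- milts_bag(gen$slide$slide_id, tiles, label, witness = wit)
  bag$slide_dim <- c(gen$slide$height_px, gen$slide$width_px)
  bag$tile_coords <- tile_index(tiles)[, c("x", "y")]
  bag
}

#' Run the full synthetic experiment end to end
#'
#' Generates a synthetic cohort, dichotomizes the generated expression
#' values at the configured percentile, splits patients 60/15/25, tiles
#' every slide over its tissue mask, trains the teacher-student
#' instance model and the slide-level classifier on the training split,
#' and evaluates on the held-out test split (slide-level metrics with
#' bootstrap CI, plus instance-level AUC of teacher typicality against
#' the planted witness flags).  With `arm = "fs_avgpool"` the ablation
#' arm is run instead: fully supervised training (`lambda = 0`, labeled
#' proportion 1) with mean-pooled tile probabilities as the slide
#' score.
#'
#' When `out_dir` is set, writes `config.yaml`, `metrics.json`,
#' `training_log.csv`, the labeled manifest, and test-split heatmap
#' PNGs, all stamped with the configuration hash.
#'
#' @param config a [milts_config()].
#' @param verbose print stage progress.
#' @return An object of class `milts_experiment`: `metrics`
#'   (a [metrics_report()]), `instance_auc`, `fit`, `manifest`,
#'   `test`, `config`, `config_hash`.
#' @export
run_experiment <- function(config = milts_config(), verbose = FALSE) {
  stopifnot(inherits(config, "milts_config"))
  hash <- object_hash(unclass(config)[setdiff(milts_config_keys, "out_dir")])
  seeds <- derive_seeds(config$seed, 4L)
  say <- function(...) if (verbose) message(sprintf(...))

  ## 1. synthesize cohort and label it from the generated expression
  spec <- synthetic_spec(
    n_patients = config$n_patients,
    slides_per_patient = config$slides_per_patient,
    image_size = config$image_size,
    witness_rate_range = c(config$witness_lo, config$witness_hi),
    tissue_coverage = config$tissue_coverage,
    nucleus_density = config$nucleus_density,
    witness_density = config$witness_density,
    expression_cutoff = config$expression_cutoff,
    mpp = config$mpp, seed = seeds[1])
  cohort <- generate_cohort(spec)
  manifest <- label_cohort(cohort$manifest, kind = config$threshold,
                           seed = seeds[2])
  say("cohort: %d slides (%d positive)", nrow(manifest),
      sum(manifest$label))

  ## 2. mask + tile every slide into bags (slides built lazily)
  bags <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    gen <- cohort_slide(cohort, i)
    bags[[i]] <- tile_synthetic_slide(gen, manifest$label[i], config)
    rm(gen)
  }
  keep <- !vapply(bags, is.null, TRUE)
  bags <- bags[keep]; manifest <- manifest[keep, ]
  say("tiled: %d bags, %d tiles total", length(bags),
      sum(vapply(bags, `[[`, 0L, "n")))

  ## 3. train on the training split
  is_fs <- config$arm == "fs_avgpool"
  train_cfg <- milts_train_config(
    epochs = config$epochs, batch_size = config$batch_size,
    base_lr = config$base_lr, min_lr = config$min_lr,
    lr_cycles = config$lr_cycles, momentum = config$momentum,
    labeled_proportion = if (is_fs) 1 else config$labeled_proportion,
    ema_decay = config$ema_decay,
    encoder = encoder_spec(d = config$encoder_d,
                           input_px = config$encoder_input_px),
    seed = seeds[3])
  loss_cfg <- milts_loss_config(lambda = if (is_fs) 0 else config$lambda)
  tr <- manifest$split == "train"
  te <- manifest$split == "test"
  if (is_fs) {
    fit_state <- train_teacher_student(bags[tr], train_cfg, loss_cfg,
                                       verbose = verbose)
    fit <- list(state = fit_state, log = fit_state$log)
  } else {
    fit <- milts(bags[tr], train_cfg, loss_cfg,
                 slide_lr = config$slide_lr,
                 slide_epochs = config$slide_epochs, verbose = verbose)
  }
  say("trained %s arm", config$arm)

  ## 4. evaluate on the held-out test split
  test_bags <- bags[te]
  tile_probs <- lapply(test_bags, function(b)
    score_instances(fit$state, b))
  scores <- if (is_fs) {
    vapply(tile_probs, mean, 0)
  } else {
    predict.milts(fit, test_bags)
  }
  labels <- manifest$label[te]
  metrics <- metrics_report(scores, labels,
                            n_resamples = config$bootstrap,
                            seed = seeds[4])
  wit <- unlist(lapply(test_bags, `[[`, "witness"))
  inst_auc <- if (length(unique(wit)) == 2L)
    roc_auc(unlist(tile_probs), wit) else NA_real_

  out <- structure(
    list(metrics = metrics, instance_auc = inst_auc,
         n_test_tiles = length(unlist(tile_probs)), fit = fit,
         manifest = manifest,
         test = data.frame(slide_id = manifest$slide_id[te],
                           label = labels, score = scores),
         config = config, config_hash = hash),
    class = "milts_experiment")

  ## 5. artifacts
  if (!is.na(config$out_dir)) {
    dir <- config$out_dir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_milts_config(config, file.path(dir, "config.yaml"))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    write.csv(cbind(fit$log, config_hash = hash),
              file.path(dir, "training_log.csv"), row.names = FALSE)
    m <- out$metrics
    jsonlite::write_json(
      list(config_hash = hash, n = m$n, auc = m$auc,
           ci_low = m$ci_low, ci_high = m$ci_high,
           threshold = m$threshold, accuracy = m$accuracy,
           sensitivity = m$sensitivity, specificity = m$specificity,
           f1 = m$f1, mcc = m$mcc, instance_auc = inst_auc),
      file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    for (k in which(te)) {
      b <- bags[[k]]
      df <- b$tile_coords
      df$side_px <- 256L
      df$typicality <- score_instances(fit$state, b)
      render_heatmap(df, b$slide_dim,
                     file = file.path(dir, paste0(b$slide_id,
                                                  "_heatmap.png")))
    }
  }
  out
}

#' @export
print.milts_experiment <- function(x, ...) {
  cat(sprintf("Synthetic MIL experiment (%s arm, hash %s)\n",
              x$config$arm, substr(x$config_hash, 1, 8)))
  cat(sprintf("  slides: %d train / %d test\n",
              sum(x$manifest$split == "train"), nrow(x$test)))
  print(x$metrics)
  if (!is.na(x$instance_auc))
    cat(sprintf("Instance-level AUC vs planted witness tiles: %.3f\n",
                x$instance_auc))
  invisible(x)
}
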