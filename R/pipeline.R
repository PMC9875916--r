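#' Default end-to-end run configuration
#'
#' Nested sections mirror each stage's parameters; every defaulted field is
#' materialized so the saved manifest fully reproduces the run.
#'
#' @param seed Run seed, reused by every seeded stage.
#' @param out_dir Output directory.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = "gancmlae_run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    phantom = unclass(phantom_spec(seed = seed)),
    model = list(input_size = 32L, base_filters = 4L, n_down_blocks = 4L,
                 latent_dim = 32L),
    training = list(batch_size = 32L, lr_generator = 2e-4, lr_critic = 2e-4,
                    critic_steps_per_generator_step = 2L, max_batches = 2000L,
                    loss_variant = "full", mu = 1, gamma = 0.001,
                    lambda_gp = 10),
    analysis = list(threshold = NULL, threshold_quantile = 0.95,
                    support_erosion = 3L, freq_threshold = 0.60,
                    min_cluster = 10L, alpha = 0.05, score_method = "mean"),
    metrics = list(mode = "windowed", window = 7L)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config` (or compatible nested list).
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (nm in names(cfg)) {
    if (is.list(cfg[[nm]]) && is.list(base[[nm]]))
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    else base[[nm]] <- cfg[[nm]]
  }
  base$seed <- as.integer(base$seed)
  base
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.write_nifti <- function(x, path) {
  RNifti::writeNifti(array(as.numeric(x), dim(x)), path)
  invisible(path)
}

#' Run the full phantom-to-ROC pipeline
#'
#' Executes simulate -> preprocess -> train -> reconstruct -> residual maps ->
#' atrophy/frequency/t-test masks -> reconstruction metrics -> subject scores,
#' z-scores and ROC, writing a manifest, a model checkpoint, NIfTI maps and
#' masks, CSV tables and a JSON summary into the run directory.
#'
#' Normal subjects are split into a training set and a held-out reference
#' group; the reference group supplies the threshold calibration
#' ([calibrate_threshold()]), the z-score reference statistics and the t-test
#' baseline.
#'
#' @param config A `run_config` (see [default_run_config()]) or a YAML path.
#' @return The output directory, invisibly; the `summary` attribute carries
#'   the headline numbers (held-out SSIM, subject-level AUC, frequency-mask
#'   Dice against the common lesion region).
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate ---
  pop <- stage("simulate", make_population(do.call(phantom_spec, config$phantom)))
  normals <- Filter(function(s) !s$is_anomalous, pop)
  anomalous <- Filter(function(s) s$is_anomalous, pop)
  if (length(normals) < 4L)
    stop("pipeline needs at least 4 normal subjects (got ", length(normals), ")")
  n_ref <- max(2L, ceiling(length(normals) / 3))
  ref <- normals[seq_len(n_ref)]
  train_set <- normals[-seq_len(n_ref)]

  # --- train ---
  arch <- stage("model", do.call(architecture_spec, config$model))
  tr <- config$training
  cfg <- train_config(batch_size = tr$batch_size, lr_generator = tr$lr_generator,
                      lr_critic = tr$lr_critic,
                      critic_steps_per_generator_step =
                        tr$critic_steps_per_generator_step,
                      max_batches = tr$max_batches, seed = config$seed,
                      loss_variant = tr$loss_variant,
                      weights = loss_weights(mu = tr$mu, gamma = tr$gamma,
                                             lambda_gp = tr$lambda_gp))
  slices <- stage("preprocess", pool_slices(train_set, size = arch$input_size))
  fit <- stage("train", train(build_model(arch, seed = config$seed), slices, cfg))
  model <- fit$model
  save_model(model, file.path(config$out_dir, "checkpoint.rds"))
  utils::write.csv(fit$history, file.path(config$out_dir, "history.csv"),
                   row.names = FALSE)

  # --- reconstruct + residual maps (in source 3D geometry) ---
  maps <- stage("residual", lapply(pop, function(s) {
    rec <- reconstruct_volume(model, s$volume)
    residual_map(rec$input, rec$reconstruction, subject_id = s$subject_id)
  }))
  names(maps) <- vapply(pop, `[[`, character(1), "subject_id")
  is_anom <- vapply(pop, `[[`, logical(1), "is_anomalous")
  support <- pop[[1]]$support
  for (i in seq_along(maps))
    .write_nifti(maps[[i]]$signed,
                 file.path(config$out_dir,
                           paste0(maps[[i]]$subject_id, "_residual.nii.gz")))

  # --- masks ---
  an <- config$analysis
  ref_ids <- vapply(ref, `[[`, character(1), "subject_id")
  analysis_mask <- erode_mask(support, an$support_erosion)
  if (!any(analysis_mask)) analysis_mask <- support
  thr <- an$threshold
  if (is.null(thr))
    thr <- stage("mask", calibrate_threshold(maps[ref_ids], analysis_mask,
                                             q = an$threshold_quantile))
  subj_masks <- lapply(maps, function(m) {
    am <- effective_atrophy_mask(m, threshold = thr)
    am$mask <- am$mask & analysis_mask
    am
  })
  fm <- group_frequency_mask(subj_masks[is_anom],
                             freq_threshold = an$freq_threshold)
  fmask <- cluster_filter(fm$binary, min_size = an$min_cluster)
  tt <- stage("ttestmask",
              voxelwise_ttest_mask(lapply(ref, `[[`, "volume"),
                                   lapply(anomalous, `[[`, "volume"),
                                   alpha = an$alpha, min_size = an$min_cluster))
  .write_nifti(fm$frequency, file.path(config$out_dir, "frequency.nii.gz"))
  .write_nifti(fmask, file.path(config$out_dir, "frequency_mask.nii.gz"))
  .write_nifti(tt$mask, file.path(config$out_dir, "ttest_mask.nii.gz"))

  # --- metrics ---
  ev <- stage("evaluate", evaluate(model, pop, mode = config$metrics$mode,
                                   window = config$metrics$window))
  utils::write.csv(ev, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)

  # --- scores + ROC ---
  scores <- vapply(maps, subject_residual_score, numeric(1),
                   brain_mask = analysis_mask, method = an$score_method,
                   threshold = thr)
  ref_scores <- scores[ref_ids]
  z <- standardize_scores(scores, center = mean(ref_scores),
                          scale = stats::sd(ref_scores))
  roc <- stage("roc", roc_auc(scores, is_anom))
  sc <- tibble::tibble(subject_id = names(scores), score = unname(scores),
                       z = unname(z), is_anomalous = is_anom)
  utils::write.csv(sc, file.path(config$out_dir, "scores.csv"),
                   row.names = FALSE)

  common <- attr(pop, "common_mask")
  summary <- list(
    threshold = thr,
    heldout_ssim = mean(ev$ssim[!is_anom][seq_len(n_ref)]),
    subject_auc = roc$auc,
    frequency_mask_dice = dice(fmask, common),
    n_train = length(train_set), n_ref = n_ref,
    n_anomalous = length(anomalous))
  jsonlite::write_json(list(roc_auc = roc$auc, curve = roc$curve,
                            summary = summary),
                       file.path(config$out_dir, "roc.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("gancmlae")),
                   summary = summary)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  structure(invisible(config$out_dir), summary = summary)
}
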