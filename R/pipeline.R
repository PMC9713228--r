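#' End-to-end pipeline and configuration
#'
#' Ties the stages together: phantom cohort synthesis, subject-level
#' splitting, training, prediction and evaluation, driven by a single
#' configuration (R list or YAML file) with sections `synth`, `train` and
#' `eval`. Every produced artifact directory carries a run manifest with the
#' configuration snapshot, seeds and a configuration hash.
#'
#' @name cli_config
NULL

#' Default pipeline configuration
#'
#' Full-scale defaults (C = 64, lr 2e-3, batch 6, 500 + 200 epochs,
#' 256 x 256 phantoms). `profile = "test"` is a desk-scale preset
#' (C = 8, 64 x 64, 3 slices, short training) used throughout the test
#' suite.
#'
#' @param profile `"full"` or `"test"`.
#' @return nested configuration list.
#' @export
default_config <- function(profile = c("full", "test")) {
  profile <- match.arg(profile)
  cfg <- list(
    synth = list(n_subjects = 253L, image_shape = c(256L, 256L),
                 n_slices = 10L, lesion_intensity = 0.3, noise_sigma = 0.05,
                 contiguity_tol_px = 1, seed = 1L),
    train = list(arch = "cascade", lr = 2e-3, batch_size = 6L,
                 epochs = 500L, pretrain_epochs = 200L,
                 train_n = 176L, val_n = 18L,
                 base_channels = 64L, depth = 4L, seed = 1L),
    eval = list(threshold = 0.5))
  if (profile == "test") {
    cfg$synth$n_subjects <- 10L
    cfg$synth$image_shape <- c(64L, 64L)
    cfg$synth$n_slices <- 3L
    cfg$synth$lesion_intensity <- 0.5
    cfg$synth$noise_sigma <- 0.02
    cfg$train$epochs <- 2L
    cfg$train$pretrain_epochs <- 1L
    cfg$train$train_n <- 8L
    cfg$train$val_n <- 2L
    cfg$train$base_channels <- 4L
    cfg$train$depth <- 2L
  }
  cfg
}

#' Read a pipeline configuration
#'
#' Loads a YAML file and fills unset keys from [default_config()].
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param profile base profile to merge into.
#' @return configuration list.
#' @export
read_config <- function(path = NULL, profile = "full") {
  cfg <- default_config(profile)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    for (sec in names(user))
      for (k in names(user[[sec]]))
        cfg[[sec]][[k]] <- user[[sec]][[k]]
  }
  cfg
}

build_train_config <- function(cfg) {
  train_config(arch = cfg$train$arch, lr = cfg$train$lr,
               batch_size = cfg$train$batch_size, epochs = cfg$train$epochs,
               pretrain_epochs = cfg$train$pretrain_epochs,
               val_count = cfg$train$val_n,
               base_channels = cfg$train$base_channels,
               depth = cfg$train$depth, seed = cfg$train$seed)
}

synth_from_config <- function(cfg) {
  base <- synth_params(image_shape = cfg$synth$image_shape,
                       n_slices = cfg$synth$n_slices,
                       lesion_intensity = cfg$synth$lesion_intensity,
                       noise_sigma = cfg$synth$noise_sigma,
                       contiguity_tol_px = cfg$synth$contiguity_tol_px)
  generate_cohort(cfg$synth$n_subjects, seed = cfg$synth$seed,
                  base_params = base)
}

#' Run the full pipeline
#'
#' synth -> split -> train -> predict -> evaluate for the configured
#' architecture. Writes per-subject predicted label maps, the per-subject
#' metrics CSV, the stratified report CSV, a volume table CSV and a run
#' manifest JSON under `out_dir`.
#'
#' @param config configuration list ([default_config()] /
#'   [read_config()]) or a YAML path.
#' @param out_dir output directory.
#' @param verbose print progress.
#' @return (invisibly) list with the fit, metrics tibble, stratified report
#'   and volume correlation.
#' @export
run_pipeline <- function(config = default_config("test"), out_dir = tempfile("wmhrun"),
                         verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (!config$train$arch %in% c("cascade", "pipeline", "separate"))
    stop("unknown architecture: ", config$train$arch)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- synth_from_config(config)
  split <- split_cohort(cohort$manifest, config$train$train_n,
                        config$train$val_n, seed = config$train$seed)
  tc <- build_train_config(config)
  fit <- train_model(cohort, split, tc, verbose = verbose)

  pred_dir <- file.path(out_dir, "predictions")
  dir.create(pred_dir, showWarnings = FALSE)
  by_id <- stats::setNames(cohort$subjects,
                           vapply(cohort$subjects, function(s) s$image$subject_id,
                                  character(1)))
  for (id in split$test_ids) {
    pr <- predict_subject(fit$model, by_id[[id]]$image,
                          threshold = config$eval$threshold)
    write_labelmap(pr$labels, file.path(pred_dir, paste0(id, "_pred.nii.gz")),
                   sidecar = FALSE)
  }

  metrics <- evaluate_model(fit$model, cohort, split$test_ids,
                            threshold = config$eval$threshold)
  report <- stratified_report(metrics, cohort$manifest)
  wmh_rows <- metrics[metrics$class == "wmh", ]
  # needs >= 3 test subjects with varying burden; NULL on tiny smoke runs
  volcor <- tryCatch(
    volume_correlation(wmh_rows$pred_volume_ml, wmh_rows$gold_volume_ml),
    error = function(e) NULL)

  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(report, file.path(out_dir, "stratified_report.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics[, c("subject_id", "class", "pred_volume_ml",
                               "gold_volume_ml")],
                   file.path(out_dir, "volumes.csv"), row.names = FALSE)
  utils::write.csv(fit$log, file.path(out_dir, "train_log.csv"), row.names = FALSE)
  save_checkpoint(fit, file.path(out_dir, "checkpoint.rds"))
  manifest <- list(config = config, config_hash = config_hash(config),
                   best_epoch = fit$best_epoch,
                   split = split, timestamp = as.character(Sys.time()))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(fit = fit, metrics = metrics, report = report,
                 volume_correlation = volcor, split = split,
                 cohort = cohort, out_dir = out_dir))
}

#' Compare the three architectures on one cohort
#'
#' Trains cascade, pipeline and separate models on the same cohort, split
#' and seed, and emits a side-by-side mean +/- SD table of DSC, MCC,
#' precision and recall per lesion class.
#'
#' @param config configuration list; the `train$arch` entry is ignored.
#' @param verbose print progress.
#' @return list with `table` (tibble: model, class, metric means/sds) and
#'   `metrics` (per-subject rows per model).
#' @export
compare_architectures <- function(config = default_config("test"), verbose = FALSE) {
  cohort <- synth_from_config(config)
  split <- split_cohort(cohort$manifest, config$train$train_n,
                        config$train$val_n, seed = config$train$seed)
  res <- list()
  for (arch in c("cascade", "pipeline", "separate")) {
    cfg <- config; cfg$train$arch <- arch
    tc <- build_train_config(cfg)
    fit <- train_model(cohort, split, tc, verbose = verbose)
    res[[arch]] <- evaluate_model(fit$model, cohort, split$test_ids,
                                  threshold = config$eval$threshold)
  }
  tab <- do.call(rbind, lapply(names(res), function(arch) {
    m <- res[[arch]]
    agg <- stats::aggregate(m[, c("dsc", "mcc", "precision", "recall")],
                            by = list(class = m$class), FUN = mean)
    sds <- stats::aggregate(m[, c("dsc", "mcc", "precision", "recall")],
                            by = list(class = m$class), FUN = stats::sd)
    names(sds)[-1] <- paste0(names(sds)[-1], "_sd")
    cbind(model = arch, merge(agg, sds, by = "class"))
  }))
  list(table = tibble::as_tibble(tab), metrics = res)
}
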