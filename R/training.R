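#' Training orchestration
#'
#' Subject-level cohort splitting, segmentation-stage pretraining, full
#' training of the three architectures with Adam under the study
#' hyperparameters (learning rate 2e-3, batch size 6, 500 epochs after 200
#' pretraining epochs at full scale), per-epoch validation and
#' minimum-validation-loss model selection.
#'
#' @name training
NULL

#' Training configuration
#'
#' Defaults are the full-scale settings; desk-scale runs shrink
#' `base_channels`, `epochs` and the image size.
#'
#' @param arch `"cascade"`, `"pipeline"` or `"separate"`.
#' @param lr Adam learning rate.
#' @param batch_size slices per optimization step.
#' @param epochs training epochs (joint epochs for the cascade).
#' @param pretrain_epochs segmentation-stage pretraining epochs (cascade
#'   only; ignored otherwise).
#' @param val_count validation subjects drawn from the training set.
#' @param base_channels,depth U-net size.
#' @param seed global seed covering weight init, splits, batch order and
#'   augmentation draws.
#' @param augment an [augment_config()]; NULL disables augmentation.
#' @param eps DSC loss epsilon.
#' @return a `train_config` list.
#' @export
train_config <- function(arch = c("cascade", "pipeline", "separate"),
                         lr = 2e-3, batch_size = 6L, epochs = 500L,
                         pretrain_epochs = 200L, val_count = 18L,
                         base_channels = 64L, depth = 4L, seed = 1L,
                         augment = augment_config(), eps = 1e-4) {
  arch <- match.arg(arch)
  stopifnot(lr > 0, batch_size >= 1, epochs >= 0, pretrain_epochs >= 0,
            val_count >= 1, base_channels >= 1, depth >= 2)
  structure(list(arch = arch, lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 val_count = as.integer(val_count),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), seed = as.integer(seed),
                 augment = augment, eps = eps),
            class = "train_config")
}

#' Split a cohort into train/validation/test subjects
#'
#' Subject-level and deterministic given the seed: no subject's slices ever
#' cross splits. `train_n` subjects are drawn for training, of which
#' `val_n` are held out for validation; the remainder is the test set.
#'
#' @param manifest data frame with a `subject_id` column.
#' @param train_n training subjects including validation.
#' @param val_n validation subjects (`val_n < train_n`).
#' @param seed split seed.
#' @return list of character vectors `train_ids`, `val_ids`, `test_ids`.
#' @export
split_cohort <- function(manifest, train_n, val_n, seed = 1L) {
  ids <- as.character(manifest$subject_id)
  n <- length(ids)
  if (train_n > n) stop("insufficient subjects: cohort has ", n)
  if (val_n >= train_n) stop("val_n must be smaller than train_n")
  with_seed(seed, {
    tr <- sample(ids, train_n)
    val <- sample(tr, val_n)
    list(train_ids = setdiff(tr, val), val_ids = val,
         test_ids = setdiff(ids, tr))
  })
}

# ---- data staging ---------------------------------------------------------

# Flatten subjects into per-slice records of raw image + labels.
cohort_slices <- function(subjects, ids) {
  by_id <- stats::setNames(subjects, vapply(subjects, function(s)
    s$image$subject_id, character(1)))
  recs <- list()
  for (id in ids) {
    s <- by_id[[id]]
    if (is.null(s)) stop("unknown subject id: ", id)
    d <- dim(s$image$voxels)
    for (k in seq_len(d[3])) {
      recs[[length(recs) + 1L]] <- list(image = s$image$voxels[, , k],
                                        labels = s$truth$labels[, , k],
                                        subject_id = id)
    }
  }
  recs
}

# Stack slice records into a network batch: z-scored pixel-major matrix plus
# per-pixel integer targets. Augmentation (if any) happens on raw
# intensities before normalization.
make_batch <- function(recs, augment_cfg = NULL) {
  imgs <- vector("list", length(recs))
  labs <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    img <- recs[[i]]$image; lab <- recs[[i]]$labels
    if (!is.null(augment_cfg)) {
      a <- augment(img, lab, augment_cfg)
      img <- a$image; lab <- a$labels
    }
    imgs[[i]] <- zscore_normalize(img)
    labs[[i]] <- lab
  }
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  list(X = matrix(unlist(imgs, use.names = FALSE), ncol = 1),
       target = as.integer(unlist(labs, use.names = FALSE)),
       H = H, W = W, N = length(recs))
}

# ---- loss evaluation (no augmentation, eval-mode BN) ----------------------

eval_loss <- function(model, recs, config) {
  b <- make_batch(recs)
  g <- as.numeric(b$target %in% c(1L, 2L))
  if (model$arch %in% c("cascade", "pipeline")) {
    fwd <- cascade_forward(model, b$X, b$H, b$W, b$N, train = FALSE)
    batch_dsc_loss(fwd$seg_prob[, 2L], g, b$N, eps = config$eps) +
      ce_loss(fwd$class_prob, one_hot(b$target, 3L))
  } else {
    f_pv <- unet_forward(model$pv_net, b$X, b$H, b$W, b$N, train = FALSE)
    f_d <- unet_forward(model$d_net, b$X, b$H, b$W, b$N, train = FALSE)
    binary_seg_loss(f_pv$prob, as.numeric(b$target == 1L), b$N, eps = config$eps) +
      binary_seg_loss(f_d$prob, as.numeric(b$target == 2L), b$N, eps = config$eps)
  }
}

# ---- optimization steps ---------------------------------------------------

step_cascade_joint <- function(model, opt1, opt2, b, config) {
  fwd <- cascade_forward(model, b$X, b$H, b$W, b$N, train = TRUE)
  model <- fwd$model
  g <- as.numeric(b$target %in% c(1L, 2L))
  loss <- batch_dsc_loss(fwd$seg_prob[, 2L], g, b$N, eps = config$eps) +
    ce_loss(fwd$class_prob, one_hot(b$target, 3L))
  bwd <- cascade_backward(model, fwd, b$target, eps = config$eps)
  u1 <- adam_step(model$stage1$params, bwd$grads1, opt1, config$lr)
  u2 <- adam_step(model$stage2$params, bwd$grads2, opt2, config$lr)
  model$stage1$params <- u1$params; model$stage2$params <- u2$params
  list(model = model, opt1 = u1$opt, opt2 = u2$opt, loss = loss)
}

step_binary <- function(net, opt, b, target, config) {
  fwd <- unet_forward(net, b$X, b$H, b$W, b$N, train = TRUE)
  net <- fwd$net
  loss <- binary_seg_loss(fwd$prob, target, b$N, eps = config$eps)
  bwd <- binary_seg_backward(net, fwd, target, eps = config$eps)
  u <- adam_step(net$params, bwd$grads, opt, config$lr)
  net$params <- u$params
  list(net = net, opt = u$opt, loss = loss)
}

# Pipeline stage 2: CE only, stage-1 probability as a frozen input channel.
step_stage2_ce <- function(net, stage1, opt, b, config) {
  f1 <- unet_forward(stage1, b$X, b$H, b$W, b$N, train = FALSE)
  X2 <- cbind(b$X, f1$prob[, 2L])
  fwd <- unet_forward(net, X2, b$H, b$W, b$N, train = TRUE)
  net <- fwd$net
  Y3 <- one_hot(b$target, 3L)
  loss <- ce_loss(fwd$prob, Y3)
  dLogits <- (fwd$prob - Y3) / nrow(Y3)
  bwd <- unet_backward(net, fwd$cache, dLogits)
  u <- adam_step(net$params, bwd$grads, opt, config$lr)
  net$params <- u$params
  list(net = net, opt = u$opt, loss = loss)
}

#' Pretrain the cascade segmentation stage
#'
#' Trains stage 1 alone against the binary WMH gold standard with DSC +
#' 2-class CE loss for `config$pretrain_epochs` epochs; stage-2 weights are
#' untouched. Accelerates convergence of the subsequent joint training.
#'
#' @param model a cascade `wmh_model`.
#' @param train_recs slice records (internal staging format from training).
#' @param config a [train_config()].
#' @return the model with a pretrained stage 1.
#' @export
pretrain_segmentation <- function(model, train_recs, config) {
  if (!identical(model$arch, "cascade"))
    stop("pretraining is defined for the cascade architecture only")
  if (config$pretrain_epochs == 0L) return(model)
  opt <- adam_init(model$stage1$params)
  for (ep in seq_len(config$pretrain_epochs)) {
    ord <- sample(length(train_recs))
    for (bi in batch_index_list(ord, config$batch_size)) {
      b <- make_batch(train_recs[bi], config$augment)
      st <- step_binary(model$stage1, opt, b,
                        as.numeric(b$target %in% c(1L, 2L)), config)
      model$stage1 <- st$net; opt <- st$opt
      if (!is.finite(st$loss)) stop("pretraining diverged (non-finite loss)")
    }
  }
  model
}

batch_index_list <- function(ord, batch_size) {
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Train a model
#'
#' Runs the per-epoch loop with fresh augmentation draws for every slice in
#' every epoch, Adam updates in shuffled batches, and per-epoch validation
#' loss evaluated without augmentation; the returned `model` is the one with
#' minimal validation loss. The cascade trains end-to-end under the combined
#' loss after stage-1 pretraining; the pipeline trains its two stages
#' sequentially and independently; the separate architecture trains two
#' binary U-nets independently.
#'
#' @param cohort result of [generate_cohort()] (or a compatible list of
#'   subjects + manifest).
#' @param split result of [split_cohort()].
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return list with `model` (best checkpoint), `final_model`, and `log`
#'   (tibble: epoch, phase, train_loss, val_loss, seconds; attribute
#'   `best_epoch`).
#' @export
train_model <- function(cohort, split, config, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  set.seed(config$seed)
  train_recs <- cohort_slices(cohort$subjects, split$train_ids)
  val_recs <- cohort_slices(cohort$subjects, split$val_ids)

  model <- switch(config$arch,
    cascade = build_cascade(config$base_channels, config$depth,
                            seed = config$seed, arch = "cascade"),
    pipeline = build_cascade(config$base_channels, config$depth,
                             seed = config$seed, arch = "pipeline"),
    separate = build_separate(config$base_channels, config$depth,
                              seed = config$seed))

  log_rows <- list()
  push_log <- function(epoch, phase, tl, vl, secs) {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      epoch = epoch, phase = phase, train_loss = tl, val_loss = vl,
      seconds = secs)
  }

  best <- list(loss = Inf, model = NULL, epoch = NA_integer_)
  track_best <- function(epoch, vl, model) {
    if (vl < best$loss) best <<- list(loss = vl, model = model, epoch = epoch)
  }

  if (config$arch == "cascade" && config$pretrain_epochs > 0L)
    model <- pretrain_segmentation(model, train_recs, config)

  run_epochs <- function(model, opts, stepper, phase, n_epochs) {
    for (ep in seq_len(n_epochs)) {
      t0 <- proc.time()[["elapsed"]]
      ord <- sample(length(train_recs))
      losses <- c()
      for (bi in batch_index_list(ord, config$batch_size)) {
        b <- make_batch(train_recs[bi], config$augment)
        r <- stepper(model, opts, b)
        model <- r$model; opts <- r$opts
        losses <- c(losses, r$loss)
        if (!is.finite(r$loss))
          stop("training diverged at epoch ", ep, " (non-finite loss)")
      }
      vl <- eval_loss(model, val_recs, config)
      track_best(ep, vl, model)
      push_log(ep, phase, mean(losses), vl, proc.time()[["elapsed"]] - t0)
      if (verbose)
        message(sprintf("[%s] epoch %d train %.4f val %.4f", phase, ep,
                        mean(losses), vl))
    }
    model
  }

  if (config$arch %in% c("cascade")) {
    opts <- list(o1 = adam_init(model$stage1$params),
                 o2 = adam_init(model$stage2$params))
    model <- run_epochs(model, opts, function(m, o, b) {
      st <- step_cascade_joint(m, o$o1, o$o2, b, config)
      list(model = st$model, opts = list(o1 = st$opt1, o2 = st$opt2),
           loss = st$loss)
    }, "joint", config$epochs)
  } else if (config$arch == "pipeline") {
    # stage 1: binary segmentation
    opts <- list(o = adam_init(model$stage1$params))
    model <- run_epochs(model, opts, function(m, o, b) {
      st <- step_binary(m$stage1, o$o, b,
                        as.numeric(b$target %in% c(1L, 2L)), config)
      m$stage1 <- st$net
      list(model = m, opts = list(o = st$opt), loss = st$loss)
    }, "stage1", config$epochs)
    # stage 2: differentiation with CE, stage 1 frozen; restart selection
    best <- list(loss = Inf, model = NULL, epoch = NA_integer_)
    opts <- list(o = adam_init(model$stage2$params))
    model <- run_epochs(model, opts, function(m, o, b) {
      st <- step_stage2_ce(m$stage2, m$stage1, o$o, b, config)
      m$stage2 <- st$net
      list(model = m, opts = list(o = st$opt), loss = st$loss)
    }, "stage2", config$epochs)
  } else {
    opts <- list(opv = adam_init(model$pv_net$params),
                 od = adam_init(model$d_net$params))
    model <- run_epochs(model, opts, function(m, o, b) {
      s1 <- step_binary(m$pv_net, o$opv, b, as.numeric(b$target == 1L), config)
      s2 <- step_binary(m$d_net, o$od, b, as.numeric(b$target == 2L), config)
      m$pv_net <- s1$net; m$d_net <- s2$net
      list(model = m, opts = list(opv = s1$opt, od = s2$opt),
           loss = s1$loss + s2$loss)
    }, "separate", config$epochs)
  }

  log <- do.call(rbind, log_rows)
  attr(log, "best_epoch") <- best$epoch
  list(model = if (is.null(best$model)) model else best$model,
       final_model = model, log = log, best_epoch = best$epoch,
       best_val_loss = best$loss, config = config)
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries the weights, the architecture description and a
#' hash of the training configuration.
#'
#' @param fit result of [train_model()] (or a bare `wmh_model`).
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "wmh_model")) fit else fit$model
  config <- if (inherits(fit, "wmh_model")) NULL else fit$config
  saveRDS(list(model = model, config = config,
               config_hash = config_hash(config),
               created = as.character(Sys.time())), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the stored list.
#' @export
load_checkpoint <- function(path) readRDS(path)

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Predict lesion labels for a subject volume
#'
#' Slices are z-score normalized and pushed through the trained model in
#' evaluation mode. Cascade/pipeline models return the stage-2 argmax label
#' map (pv and d disjoint by construction). The separate model returns the
#' two thresholded masks plus their overlap, and a label map in which
#' overlap pixels are reported under the pv code for file output only.
#'
#' @param model a trained `wmh_model`.
#' @param volume a [wmh_volume].
#' @param threshold threshold for the separate architecture.
#' @return list with `labels` ([wmh_labelmap]); for the separate
#'   architecture also `pv_mask`, `d_mask`, `overlap_mask` (3D logical).
#' @export
predict_subject <- function(model, volume, threshold = 0.5) {
  stopifnot(inherits(model, "wmh_model"), inherits(volume, "wmh_volume"))
  d <- dim(volume$voxels)
  recs <- lapply(seq_len(d[3]), function(k)
    list(image = volume$voxels[, , k], labels = NULL))
  imgs <- lapply(recs, function(r) zscore_normalize(r$image))
  X <- matrix(unlist(imgs, use.names = FALSE), ncol = 1)
  if (model$arch %in% c("cascade", "pipeline")) {
    fwd <- cascade_forward(model, X, d[1], d[2], d[3], train = FALSE)
    lab <- array(predict_labels(fwd$class_prob), dim = d)
    return(list(labels = wmh_labelmap(lab, volume$spacing, volume$subject_id),
                class_prob = fwd$class_prob, seg_prob = fwd$seg_prob))
  }
  f_pv <- unet_forward(model$pv_net, X, d[1], d[2], d[3], train = FALSE)
  f_d <- unet_forward(model$d_net, X, d[1], d[2], d[3], train = FALSE)
  sp <- separate_predict(f_pv$prob[, 2L], f_d$prob[, 2L], threshold)
  pv <- array(sp$pv_mask, dim = d); dm <- array(sp$d_mask, dim = d)
  lab <- array(0L, dim = d)
  lab[dm] <- 2L; lab[pv] <- 1L   # overlap reported under pv in the file map
  list(labels = wmh_labelmap(lab, volume$spacing, volume$subject_id),
       pv_mask = pv, d_mask = dm, overlap_mask = array(sp$overlap_mask, dim = d))
}

#' Evaluate a trained model on a set of subjects
#'
#' Computes per-subject, per-class metrics against the phantom truth. For
#' the separate architecture the per-class masks are used directly, so the
#' reported overlap is not resolved away.
#'
#' @param model trained `wmh_model`.
#' @param cohort cohort list with `subjects`.
#' @param ids subject ids to evaluate.
#' @param threshold separate-architecture threshold.
#' @return tibble of [subject_metrics()] rows for all subjects.
#' @export
evaluate_model <- function(model, cohort, ids, threshold = 0.5) {
  by_id <- stats::setNames(cohort$subjects, vapply(cohort$subjects, function(s)
    s$image$subject_id, character(1)))
  rows <- list()
  for (id in ids) {
    s <- by_id[[id]]
    pr <- predict_subject(model, s$image, threshold)
    if (model$arch == "separate") {
      gold <- s$truth$labels
      pred_masks <- list(wmh = pr$pv_mask | pr$d_mask, pv = pr$pv_mask,
                         d = pr$d_mask)
      gold_masks <- list(wmh = gold %in% c(1L, 2L), pv = gold == 1L,
                         d = gold == 2L)
      vox_ml <- prod(s$image$spacing) / 1000
      m <- do.call(rbind, lapply(names(pred_masks), function(cl) {
        cc <- confusion_counts(pred_masks[[cl]], gold_masks[[cl]])
        prc <- precision_recall(cc)
        tibble::tibble(subject_id = id, class = cl,
                       dsc = dsc(pred_masks[[cl]], gold_masks[[cl]]),
                       mcc = mcc(cc), precision = prc[["precision"]],
                       recall = prc[["recall"]],
                       pred_volume_ml = sum(pred_masks[[cl]]) * vox_ml,
                       gold_volume_ml = sum(gold_masks[[cl]]) * vox_ml)
      }))
    } else {
      m <- subject_metrics(pr$labels$labels, s$truth$labels, s$image$spacing, id)
    }
    rows[[length(rows) + 1L]] <- m
  }
  do.call(rbind, rows)
}
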