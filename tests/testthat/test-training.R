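# Desk-scale training fixtures: tiny cohorts and networks so every
# contract runs in seconds.

small_cohort <- function(n = 8L, seed = 1L) {
  generate_cohort(n, seed = seed,
                  base_params = tiny_params(shape = 32L, slices = 2L))
}

small_config <- function(seed = 1L, epochs = 2L, arch = "cascade",
                         pretrain = 1L) {
  train_config(arch = arch, epochs = epochs, pretrain_epochs = pretrain,
               val_count = 2L, base_channels = 4L, depth = 2L, seed = seed,
               batch_size = 6L)
}

test_that("cohort splits are subject-level partitions, sized as configured", {
  man <- tibble::tibble(subject_id = sprintf("s%03d", 1:253))
  sp <- split_cohort(man, train_n = 176L, val_n = 18L, seed = 5L)
  expect_length(sp$train_ids, 158L)
  expect_length(sp$val_ids, 18L)
  expect_length(sp$test_ids, 77L)
  all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
  expect_setequal(all_ids, man$subject_id)
  expect_equal(anyDuplicated(all_ids), 0L)
  sp2 <- split_cohort(man, 176L, 18L, seed = 5L)
  expect_identical(sp, sp2)
  expect_error(split_cohort(man, 300L, 18L), "insufficient")
  expect_error(split_cohort(man, 20L, 20L), "val_n")
})

test_that("pretraining touches only stage-1 weights and is skippable", {
  co <- small_cohort()
  sp <- split_cohort(co$manifest, 6L, 2L, seed = 1L)
  recs <- wmhcascade:::cohort_slices(co$subjects, sp$train_ids)

  cfg0 <- small_config(pretrain = 0L)
  model <- build_cascade(4L, 2L, seed = 9L)
  expect_identical(pretrain_segmentation(model, recs, cfg0), model)

  cfg1 <- small_config(pretrain = 1L)
  set.seed(1)
  trained <- pretrain_segmentation(model, recs, cfg1)
  expect_identical(trained$stage2$params, model$stage2$params)
  expect_false(identical(trained$stage1$params, model$stage1$params))

  sep <- build_separate(4L, 2L, seed = 9L)
  expect_error(pretrain_segmentation(sep, recs, cfg1), "cascade")
})

test_that("stage-1 loss decreases over a short pretraining run", {
  co <- small_cohort(n = 8L, seed = 3L)
  sp <- split_cohort(co$manifest, 6L, 2L, seed = 3L)
  recs <- wmhcascade:::cohort_slices(co$subjects, sp$train_ids)
  model <- build_cascade(4L, 2L, seed = 3L)
  cfg <- small_config(seed = 3L)
  loss_at <- function(m) {
    b <- wmhcascade:::make_batch(recs)
    f <- unet_forward(m$stage1, b$X, b$H, b$W, b$N)
    wmhcascade:::binary_seg_loss(f$prob, as.numeric(b$target %in% 1:2), b$N)
  }
  l0 <- loss_at(model)
  cfg$pretrain_epochs <- 8L
  set.seed(3)
  m8 <- pretrain_segmentation(model, recs, cfg)
  expect_lt(loss_at(m8), l0)
})

test_that("training selects the epoch with minimal validation loss and is deterministic", {
  co <- small_cohort()
  sp <- split_cohort(co$manifest, 6L, 2L, seed = 1L)
  cfg <- small_config(epochs = 3L)
  fit <- train_model(co, sp, cfg)
  expect_equal(fit$best_epoch, which.min(fit$log$val_loss[fit$log$phase == "joint"]))
  expect_equal(attr(fit$log, "best_epoch"), fit$best_epoch)

  fit2 <- train_model(co, sp, cfg)
  expect_identical(fit$log$val_loss, fit2$log$val_loss)
  expect_identical(fit$model$stage1$params, fit2$model$stage1$params)
})

test_that("checkpoints round-trip and reproduce the recorded validation loss", {
  co <- small_cohort()
  sp <- split_cohort(co$manifest, 6L, 2L, seed = 1L)
  cfg <- small_config(epochs = 2L)
  fit <- train_model(co, sp, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  ck <- load_checkpoint(path)
  expect_identical(ck$model$stage1$params, fit$model$stage1$params)
  val_recs <- wmhcascade:::cohort_slices(co$subjects, sp$val_ids)
  vl <- wmhcascade:::eval_loss(ck$model, val_recs, cfg)
  expect_equal(vl, fit$best_val_loss, tolerance = 1e-6)
})

test_that("all three architectures train and predict with valid outputs", {
  co <- small_cohort()
  sp <- split_cohort(co$manifest, 6L, 2L, seed = 2L)
  subj <- co$subjects[[match(sp$test_ids[1], co$manifest$subject_id)]]
  for (arch in c("cascade", "pipeline", "separate")) {
    cfg <- small_config(epochs = 1L, arch = arch, pretrain = 0L)
    fit <- train_model(co, sp, cfg)
    pr <- predict_subject(fit$model, subj$image)
    expect_s3_class(pr$labels, "wmh_labelmap")
    expect_true(all(pr$labels$labels %in% 0:2))
    if (arch == "separate") {
      expect_identical(pr$overlap_mask, pr$pv_mask & pr$d_mask)
    } else {
      # argmax partition: pv and d never overlap
      expect_equal(sum(pr$labels$labels == 1L & pr$labels$labels == 2L), 0L)
    }
    m <- evaluate_model(fit$model, co, sp$test_ids)
    expect_equal(nrow(m), length(sp$test_ids) * 3L)
    expect_true(all(m$dsc >= 0 & m$dsc <= 1))
  }
})
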