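test_that("phantom subjects satisfy the contiguity rule for both lesion classes", {
  for (seed in c(7L, 21L)) {
    p <- tiny_params(seed = seed, pv = 2L, d = 1L)
    s <- generate_subject(p)
    tol <- p$contiguity_tol_px
    for (k in seq_len(dim(s$truth$labels)[3])) {
      tr <- s$truth$labels[, , k]
      vent <- s$ventricle_mask[, , k]
      if (any(tr == 1L)) {
        comp <- label_components(tr == 1L)
        for (cpt in seq_len(max(comp)))
          expect_lte(min_dist_loop(comp == cpt, vent), tol)
      }
      if (any(tr == 2L)) {
        comp <- label_components(tr == 2L)
        for (cpt in seq_len(max(comp)))
          expect_gt(min_dist_loop(comp == cpt, vent), tol)
      }
    }
  }
})

test_that("grade 0 means no lesions, and generation is deterministic", {
  s0 <- generate_subject(tiny_params(seed = 3L, pv = 0L, d = 0L))
  expect_true(all(s0$truth$labels == 0L))
  expect_equal(s0$pv_volume_ml, 0)
  expect_equal(s0$d_volume_ml, 0)

  p <- tiny_params(seed = 13L, pv = 1L, d = 2L)
  a <- generate_subject(p); b <- generate_subject(p)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("recorded volumes equal pixel counts times voxel volume exactly", {
  s <- generate_subject(tiny_params(seed = 11L, pv = 2L, d = 2L))
  vox_ml <- prod(s$image$spacing) / 1000
  expect_identical(s$pv_volume_ml, sum(s$truth$labels == 1L) * vox_ml)
  expect_identical(s$d_volume_ml, sum(s$truth$labels == 2L) * vox_ml)
})

test_that("assign_lesion_classes follows the distance rule and partitions", {
  # component overlapping the ventricle border -> pv
  vent <- matrix(FALSE, 32, 32); vent[14:18, 14:18] <- TRUE
  les <- matrix(FALSE, 32, 32); les[18:22, 16] <- TRUE
  out <- assign_lesion_classes(les, vent, contiguity_tol_px = 1)
  expect_true(all(out[les] == 1L))

  # single-pixel lesion at Chebyshev distance 10 with tol 3 -> deep
  vent2 <- matrix(FALSE, 32, 32); vent2[5, 5] <- TRUE
  les2 <- matrix(FALSE, 32, 32); les2[15, 15] <- TRUE
  expect_gt(min_dist_loop(les2, vent2), 3)
  out2 <- assign_lesion_classes(les2, vent2, contiguity_tol_px = 3)
  expect_identical(out2[15, 15], 2L)

  # empty lesion mask -> empty map; empty ventricle -> all deep with warning
  expect_true(all(assign_lesion_classes(matrix(FALSE, 8, 8),
                                        matrix(FALSE, 8, 8)) == 0L))
  expect_warning(out3 <- assign_lesion_classes(les2, matrix(FALSE, 32, 32)),
                 "empty ventricle")
  expect_identical(out3[15, 15], 2L)

  # partition: no component labelled both ways
  set.seed(4)
  for (i in 1:20) {
    les <- matrix(runif(24 * 24) < 0.2, 24, 24)
    vent <- matrix(FALSE, 24, 24); vent[10:14, 10:14] <- TRUE
    out <- assign_lesion_classes(les, vent, 1)
    comp <- label_components(les)
    for (cpt in seq_len(max(comp)))
      expect_length(unique(out[comp == cpt]), 1L)
    expect_identical(out != 0L, les)
  }
})

test_that("re-running the classifier on a phantom's union mask reproduces truth", {
  for (seed in c(2L, 8L, 31L)) {
    s <- generate_subject(tiny_params(seed = seed, pv = 2L, d = 2L))
    union <- s$truth$labels %in% c(1L, 2L)
    dim(union) <- dim(s$truth$labels)
    redo <- assign_lesion_classes(union, s$ventricle_mask,
                                  s$params$contiguity_tol_px)
    expect_identical(redo, s$truth$labels)
  }
})

test_that("8-connected labelling matches a flood-fill oracle on small masks", {
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(runif(12 * 12) < 0.35, 12, 12)
    lab <- label_components(m)
    expect_identical(lab != 0L, m)
    # diagonal neighbours share a label; separated pixels do not
    px <- which(m, arr.ind = TRUE)
    if (nrow(px) >= 2) {
      for (a in seq_len(min(nrow(px), 12))) for (b in seq_len(min(nrow(px), 12))) {
        cheb <- max(abs(px[a, ] - px[b, ]))
        if (cheb == 1)
          expect_equal(lab[px[a, 1], px[a, 2]], lab[px[b, 1], px[b, 2]])
      }
    }
  }
  # two diagonal pixels form one component (8-connectivity)
  m2 <- matrix(FALSE, 4, 4); m2[1, 1] <- TRUE; m2[2, 2] <- TRUE
  expect_equal(max(label_components(m2)), 1L)
})

test_that("expected lesion burden grows with the grade", {
  counts <- sapply(0:3, function(g) {
    mean(sapply(1:50, function(seed) {
      s <- generate_subject(synth_params(image_shape = c(64L, 64L), n_slices = 1L,
                                         pv_burden = g, d_burden = g,
                                         noise_sigma = 0.02, seed = seed))
      sum(s$truth$labels != 0L)
    }))
  })
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
})

test_that("cohort generation respects the grade distribution and is reproducible", {
  co <- generate_cohort(200L, seed = 42L,
                        base_params = tiny_params(shape = 32L, slices = 1L))
  man <- co$manifest
  expect_equal(nrow(man), 200L)
  # marginal frequencies within exact binomial 99% bounds of the target
  gd <- default_grade_distribution()
  pv_marg <- rowSums(gd); d_marg <- colSums(gd)
  for (g in 0:3) {
    n_pv <- sum(man$pv_grade == g)
    expect_gte(n_pv, qbinom(0.005, 200, pv_marg[g + 1]))
    expect_lte(n_pv, qbinom(0.995, 200, pv_marg[g + 1]))
    n_d <- sum(man$d_grade == g)
    expect_gte(n_d, qbinom(0.005, 200, d_marg[g + 1]))
    expect_lte(n_d, qbinom(0.995, 200, d_marg[g + 1]))
  }
  co2 <- generate_cohort(200L, seed = 42L,
                         base_params = tiny_params(shape = 32L, slices = 1L))
  expect_identical(co$manifest, co2$manifest)

  # point mass on (0,0) -> lesion-free subjects
  pm <- matrix(0, 4, 4); pm[1, 1] <- 1
  co0 <- generate_cohort(5L, grade_distribution = pm, seed = 1L,
                         base_params = tiny_params(shape = 32L, slices = 1L))
  expect_true(all(co0$manifest$wmh_ml == 0))
  expect_error(generate_cohort(0L), "positive")
})
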