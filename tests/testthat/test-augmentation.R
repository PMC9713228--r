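test_that("gamma transform matches the closed form and preserves endpoints", {
  # min 0, max 1: value 0.25 at gamma 0.5 -> 0.5
  x <- matrix(c(0, 0.25, 0.6, 1), 2, 2)
  y <- gamma_intensity(x, 0.5)
  expect_equal(y[2, 1], 0.5)
  expect_equal(min(y), 0); expect_equal(max(y), 1)

  # gamma 1 is the identity for any image
  set.seed(1)
  z <- matrix(rnorm(64), 8, 8)
  expect_equal(gamma_intensity(z, 1), z)

  # endpoints map to themselves exactly for any gamma
  w <- matrix(c(2, 6, 2, 6), 2, 2)
  for (g in c(0.5, 0.7, 0.93)) {
    out <- gamma_intensity(w, g)
    expect_equal(min(out), 2); expect_equal(max(out), 6)
  }
  # constant image unchanged
  expect_equal(gamma_intensity(matrix(4, 3, 3), 0.6), matrix(4, 3, 3))
  expect_error(gamma_intensity(z, 0))
})

test_that("gamma transform is monotone in pixel intensity", {
  set.seed(2)
  x <- matrix(runif(100, -3, 7), 10, 10)
  for (g in c(0.5, 0.75, 1)) {
    y <- gamma_intensity(x, g)
    expect_identical(order(x), order(y))
  }
})

test_that("spatial transform: identity, flip involution, 90-degree rotation", {
  set.seed(3)
  img <- matrix(rnorm(64), 8, 8)
  lab <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)

  id <- spatial_transform(img, lab, 0, c(0, 0), 1, FALSE)
  expect_equal(id$image, img)
  expect_identical(id$labels, lab)

  f1 <- spatial_transform(img, lab, hflip = TRUE)
  f2 <- spatial_transform(f1$image, f1$labels, hflip = TRUE)
  expect_equal(f2$image, img)
  expect_identical(f2$labels, lab)

  # 90-degree rotation of an asymmetric 3x3 grid: closed-form permutation
  g3 <- matrix(1:9, 3, 3)
  r <- spatial_transform(g3 + 0, g3, rotate_deg = 90)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) oracle[i, j] <- g3[j, 4 - i]
  expect_equal(r$image, oracle)
  expect_identical(r$labels + 0, oracle)
})

test_that("labels stay categorical and in-frame shifts conserve mask area", {
  set.seed(4)
  img <- matrix(rnorm(32 * 32), 32, 32)
  lab <- matrix(0L, 32, 32); lab[14:18, 12:16] <- 1L; lab[20:22, 20] <- 2L
  for (i in 1:15) {
    tr <- spatial_transform(img, lab,
                            rotate_deg = runif(1, -30, 30),
                            shift_px = sample(-5:5, 2, replace = TRUE),
                            scale = runif(1, 0.9, 1.1),
                            hflip = runif(1) < 0.5)
    expect_true(all(tr$labels %in% 0:2))
  }
  # pure integer shift, fully in frame: per-class counts unchanged
  sh <- spatial_transform(img, lab, shift_px = c(4, -6))
  expect_equal(sum(sh$labels == 1L), sum(lab == 1L))
  expect_equal(sum(sh$labels == 2L), sum(lab == 2L))
})

test_that("augment draws respect the configured ranges and reproduce under a seed", {
  cfg <- augment_config()
  img <- matrix(runif(64), 8, 8)

  off <- augment_config(enabled = c(rotate = FALSE, shift = FALSE, scale = FALSE,
                                    hflip = FALSE, gamma = FALSE))
  a0 <- augment(img, NULL, off)
  expect_equal(a0$image, img)

  set.seed(99); a1 <- augment(img, NULL, cfg)
  set.seed(99); a2 <- augment(img, NULL, cfg)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$draws, a2$draws)

  set.seed(7)
  draws <- replicate(1000, augment(img, NULL, cfg)$draws, simplify = FALSE)
  gam <- vapply(draws, function(d) d$gamma, numeric(1))
  rot <- vapply(draws, function(d) d$rotate_deg, numeric(1))
  shf <- unlist(lapply(draws, function(d) d$shift_px))
  scl <- vapply(draws, function(d) d$scale, numeric(1))
  expect_gte(min(gam), 0.5); expect_lte(max(gam), 1)
  expect_gte(min(rot), -30); expect_lte(max(rot), 30)
  expect_true(all(shf == round(shf)))
  expect_gte(min(shf), -26); expect_lte(max(shf), 26)
  expect_gte(min(scl), 0.9); expect_lte(max(scl), 1.1)
  # mean gamma within 3 standard errors of the uniform mean 0.75
  se <- (0.5 / sqrt(12)) / sqrt(1000)
  expect_lt(abs(mean(gam) - 0.75), 3 * se)
})
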