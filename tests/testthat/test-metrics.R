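test_that("confusion counts match a brute-force double loop", {
  set.seed(1)
  m <- random_mask_pair()
  cc <- confusion_counts(m$pred, m$gold)
  oracle <- confusion_loop(m$pred, m$gold)
  expect_equal(cc$TP, oracle$TP); expect_equal(cc$TN, oracle$TN)
  expect_equal(cc$FP, oracle$FP); expect_equal(cc$FN, oracle$FN)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, length(m$pred))

  # pred == gold and pred == !gold limiting cases
  cs <- confusion_counts(m$gold, m$gold)
  expect_equal(cs$FP + cs$FN, 0L)
  cn <- confusion_counts(!m$gold, m$gold)
  expect_equal(cn$TP + cn$TN, 0L)
  expect_error(confusion_counts(matrix(1, 2, 2), matrix(1, 3, 3)), "congruent")
})

test_that("DSC, MCC, precision and recall match hand-worked values", {
  # |G|=10, |P|=8, |G cap P|=6 -> 12/18
  gold <- c(rep(TRUE, 10), rep(FALSE, 20))
  pred <- c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 2), rep(FALSE, 18))
  expect_equal(dsc(pred, gold), 12 / 18)
  expect_equal(dsc(gold, gold), 1)
  expect_equal(dsc(c(TRUE, FALSE), c(FALSE, FALSE)), 0)

  # MCC printed-formula value: TP=6 TN=3 FP=1 FN=2 -> 16/sqrt(1120)
  cc <- structure(list(TP = 6L, TN = 3L, FP = 1L, FN = 2L),
                  class = "confusion_counts")
  expect_equal(mcc(cc), 16 / sqrt(1120))
  perfect <- structure(list(TP = 5L, TN = 7L, FP = 0L, FN = 0L),
                       class = "confusion_counts")
  expect_equal(mcc(perfect), 1)
  inverted <- structure(list(TP = 0L, TN = 0L, FP = 7L, FN = 5L),
                        class = "confusion_counts")
  expect_equal(mcc(inverted), -1)

  # precision 6/7, recall 6/8
  cc2 <- structure(list(TP = 6L, TN = 100L, FP = 1L, FN = 2L),
                   class = "confusion_counts")
  pr <- precision_recall(cc2)
  expect_equal(pr[["precision"]], 6 / 7)
  expect_equal(pr[["recall"]], 0.75)
  cc3 <- structure(list(TP = 3L, TN = 10L, FP = 0L, FN = 1L),
                   class = "confusion_counts")
  expect_equal(precision_recall(cc3)[["precision"]], 1)
})

test_that("metrics agree with brute-force loops on 200 random mask pairs", {
  dsc_loop <- function(p, g) {
    inter <- 0L; np <- 0L; ng <- 0L
    for (i in seq_along(p)) {
      if (p[i] && g[i]) inter <- inter + 1L
      if (p[i]) np <- np + 1L
      if (g[i]) ng <- ng + 1L
    }
    if (np + ng == 0L) 1 else 2 * inter / (np + ng)
  }
  mcc_loop <- function(o) {
    if (o$FP == 0 && o$FN == 0) return(1)
    if (o$TP == 0 && o$TN == 0) return(-1)
    den <- (o$TP + o$FP) * (o$TP + o$FN) * (o$TN + o$FP) * (o$TN + o$FN)
    if (den == 0) return(0)
    (o$TP * o$TN - o$FP * o$FN) / sqrt(den)
  }
  set.seed(2)
  for (i in 1:200) {
    m <- random_mask_pair(8L, runif(1, 0, 0.6), runif(1, 0, 0.6))
    cc <- confusion_counts(m$pred, m$gold)
    o <- confusion_loop(m$pred, m$gold)
    expect_equal(dsc(m$pred, m$gold), dsc_loop(m$pred, m$gold),
                 tolerance = 1e-12)
    expect_equal(mcc(cc), mcc_loop(o), tolerance = 1e-12)
    # symmetry and F1 identity where defined
    expect_equal(dsc(m$pred, m$gold), dsc(m$gold, m$pred))
    pr <- precision_recall(cc)
    if (pr[["precision"]] + pr[["recall"]] > 0 && (any(m$pred) || any(m$gold)))
      expect_equal(dsc(m$pred, m$gold),
                   2 * pr[["precision"]] * pr[["recall"]] /
                     (pr[["precision"]] + pr[["recall"]]),
                   tolerance = 1e-12)
    # MCC invariant under simultaneous complement
    expect_equal(mcc(confusion_counts(!m$pred, !m$gold)), mcc(cc),
                 tolerance = 1e-12)
  }
})

test_that("per-subject pooling equals summed per-slice confusion counts", {
  set.seed(3)
  pred <- array(runif(16 * 16 * 3) < 0.3, c(16, 16, 3))
  gold <- array(runif(16 * 16 * 3) < 0.3, c(16, 16, 3))
  pooled <- confusion_counts(pred, gold)
  acc <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (k in 1:3) {
    cs <- confusion_counts(pred[, , k], gold[, , k])
    acc <- acc + c(TP = cs$TP, TN = cs$TN, FP = cs$FP, FN = cs$FN)
  }
  expect_equal(unlist(pooled[c("TP", "TN", "FP", "FN")]),
               acc, ignore_attr = TRUE)
})

test_that("lesion volumes follow the voxel geometry", {
  lab <- array(0L, dim = c(64, 64, 4))
  lab[1:25, 1:40, 1] <- 1L   # 1000 px
  lm <- wmh_labelmap(lab, c(0.45, 0.45, 5.5))
  expect_equal(lesion_volume(lm, "wmh"), 1.11375)
  expect_equal(lesion_volume(lm, 1L), 1.11375)
  expect_equal(lesion_volume(lm, 2L), 0)
  empty <- wmh_labelmap(array(0L, c(8, 8, 1)), c(1, 1, 1))
  expect_equal(lesion_volume(empty, "wmh"), 0)
  expect_error(lesion_volume(lab, "wmh"), "spacing")
})

test_that("volume correlation reproduces a from-scratch OLS", {
  g <- c(1, 2, 3, 4)
  vc <- volume_correlation(g, g)
  expect_equal(vc$r_squared, 1)
  expect_equal(vc$slope, 1)
  expect_equal(vc$intercept, 0)

  vc2 <- volume_correlation(2 * g + 1, g)
  expect_equal(vc2$r_squared, 1); expect_equal(vc2$slope, 2)

  set.seed(4)
  gold <- runif(100, 0, 4)
  pred <- gold + rnorm(100, 0, 0.2)
  vc3 <- volume_correlation(pred, gold)
  # closed-form OLS oracle
  bx <- sum((gold - mean(gold)) * (pred - mean(pred))) /
    sum((gold - mean(gold))^2)
  a <- mean(pred) - bx * mean(gold)
  resid <- pred - (a + bx * gold)
  r2 <- 1 - sum(resid^2) / sum((pred - mean(pred))^2)
  expect_equal(vc3$slope, bx, tolerance = 1e-10)
  expect_equal(vc3$intercept, a, tolerance = 1e-10)
  expect_equal(vc3$r_squared, r2, tolerance = 1e-10)
  expect_lt(vc3$p_value, 1e-6)
  expect_error(volume_correlation(g, rep(2, 4)), "variance")
})

test_that("subject metrics and the stratified report have the Table layout", {
  set.seed(5)
  gold <- array(sample(0:2, 16 * 16 * 2, replace = TRUE, prob = c(.8, .1, .1)),
                c(16, 16, 2))
  pred <- gold
  pred[1:4, 1:4, 1] <- 0L  # a few misses
  m <- subject_metrics(pred, gold, c(1, 1, 5), "s1")
  expect_equal(m$class, c("wmh", "pv", "d"))
  expect_true(all(m$dsc >= 0 & m$dsc <= 1))
  expect_true(all(m$mcc >= -1 & m$mcc <= 1))

  m2 <- subject_metrics(gold, gold, c(1, 1, 5), "s2")
  grades <- tibble::tibble(subject_id = c("s1", "s2"),
                           pv_grade = c(1L, 2L), d_grade = c(0L, 1L))
  rep <- stratified_report(rbind(m, m2), grades)
  overall_wmh <- rep[rep$class == "wmh" & rep$stratum == "overall", ]
  # two-subject mean/sd check against hand arithmetic
  expect_equal(overall_wmh$dsc_mean,
               mean(c(m$dsc[m$class == "wmh"], 1)))
  expect_equal(overall_wmh$dsc_sd,
               sd(c(m$dsc[m$class == "wmh"], 1)))
  expect_equal(overall_wmh$n, 2L)
  # single-subject stratum: mean = value, sd = 0
  g1 <- rep[rep$class == "pv" & rep$stratum == "pv_grade" & rep$grade == 1, ]
  expect_equal(g1$dsc_mean, m$dsc[m$class == "pv"])
  expect_equal(g1$dsc_sd, 0)
})
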