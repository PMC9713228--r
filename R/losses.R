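#' Training losses
#'
#' The combined loss is the unweighted sum of a Dice similarity loss on the
#' segmentation stage's foreground probability and a cross-entropy loss on
#' the differentiation stage's 3-class softmax:
#' \deqn{CLoss = DSC\,Loss + CE\,Loss}
#' \deqn{DSC\,Loss = 1 - \frac{2\sum_n p_n g_n + \epsilon}{\sum_n (p_n + g_n) + \epsilon}}
#' \deqn{CE\,Loss = -\frac{1}{N}\sum_n \sum_i y_{ni} \log \hat y_{ni}}
#' with \eqn{p_n} the foreground softmax probability at pixel n, \eqn{g_n}
#' the binary target, N the pixel count and \eqn{\epsilon = 10^{-4}} guarding
#' the denominator. Cross-entropy runs over all N pixels of the slice, not
#' only inside the lesion mask.
#'
#' @name losses
NULL

CE_CLIP <- 1e-12

#' Dice similarity (DSC) loss
#'
#' @param p foreground probability values in [0, 1] (any shape).
#' @param g binary target, congruent with `p`.
#' @param eps denominator guard, default 1e-4.
#' @return scalar loss in [0, 1); exactly 0 when `p == g`, including the
#'   all-empty case.
#' @export
dsc_loss <- function(p, g, eps = 1e-4) {
  stopifnot(length(p) == length(g), eps > 0)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (!all(g %in% c(0, 1))) stop("g must be binary")
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

# gradient of dsc_loss with respect to p (same shape as p)
dsc_loss_grad <- function(p, g, eps = 1e-4) {
  A <- 2 * sum(p * g) + eps
  B <- sum(p) + sum(g) + eps
  -(2 * g * B - A) / B^2
}

#' Cross-entropy (CE) loss
#'
#' Mean over pixels of the negative log-probability of the true class.
#' Probabilities are clipped to `[1e-12, 1]` before the log.
#'
#' @param y_hat probability matrix, one row per pixel, one column per class;
#'   rows sum to 1.
#' @param y one-hot target matrix congruent with `y_hat`.
#' @return scalar loss, non-negative.
#' @export
ce_loss <- function(y_hat, y) {
  stopifnot(is.matrix(y_hat), all(dim(y_hat) == dim(y)))
  if (!all(y %in% c(0, 1)) || any(abs(rowSums(y) - 1) > 1e-9))
    stop("y must be one-hot encoded")
  -sum(y * log(pmax(y_hat, CE_CLIP))) / nrow(y)
}

# gradient of ce_loss with respect to y_hat
ce_loss_grad <- function(y_hat, y) {
  -(y / pmax(y_hat, CE_CLIP)) / nrow(y)
}

#' One-hot encode an integer label vector
#'
#' @param labels integer vector with values in `0:(n_classes-1)`.
#' @param n_classes number of classes.
#' @return matrix `length(labels)` x `n_classes` of 0/1.
#' @export
one_hot <- function(labels, n_classes) {
  stopifnot(all(labels %in% 0:(n_classes - 1L)))
  out <- matrix(0, length(labels), n_classes)
  out[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  out
}

#' Combined loss of the cascade model
#'
#' `dsc_component` scores the segmentation stage's foreground probability
#' against the binary WMH target; `ce_component` scores the differentiation
#' stage's 3-class probabilities against the 0/1/2 target; `total` is their
#' unweighted sum.
#'
#' @param seg_prob stage-1 probability matrix (pixels x 2), column 2 =
#'   WMH foreground.
#' @param class_prob stage-2 probability matrix (pixels x 3).
#' @param class_target integer vector of per-pixel labels in \{0, 1, 2\}.
#' @param wmh_target optional binary vector; must equal
#'   `class_target %in% c(1, 2)` and defaults to it.
#' @param eps DSC denominator guard.
#' @return list with `total`, `dsc_component`, `ce_component`.
#' @export
combined_loss <- function(seg_prob, class_prob, class_target,
                          wmh_target = NULL, eps = 1e-4) {
  stopifnot(nrow(seg_prob) == nrow(class_prob),
            nrow(class_prob) == length(class_target))
  union_target <- as.numeric(class_target %in% c(1L, 2L))
  if (is.null(wmh_target)) {
    wmh_target <- union_target
  } else if (!isTRUE(all.equal(as.numeric(wmh_target), union_target))) {
    stop("wmh_target must equal the union of the pv/d class targets")
  }
  d <- dsc_loss(seg_prob[, 2L], wmh_target, eps = eps)
  ce <- ce_loss(class_prob, one_hot(class_target, 3L))
  list(total = d + ce, dsc_component = d, ce_component = ce)
}

# Per-slice mean of losses over a batch: targets grouped by slice so the
# DSC term is computed slice-wise, as in per-slice training.
batch_dsc_loss <- function(p_fg, g, n_slices, eps = 1e-4) {
  px <- length(p_fg) %/% n_slices
  vals <- vapply(seq_len(n_slices), function(s) {
    r <- (s - 1L) * px + seq_len(px)
    dsc_loss(p_fg[r], g[r], eps = eps)
  }, numeric(1))
  mean(vals)
}

batch_dsc_loss_grad <- function(p_fg, g, n_slices, eps = 1e-4) {
  px <- length(p_fg) %/% n_slices
  out <- numeric(length(p_fg))
  for (s in seq_len(n_slices)) {
    r <- (s - 1L) * px + seq_len(px)
    out[r] <- dsc_loss_grad(p_fg[r], g[r], eps = eps) / n_slices
  }
  out
}
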