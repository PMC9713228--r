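#' Model architectures
#'
#' Three architectures are compared for joint WMH segmentation and
#' periventricular/deep differentiation:
#' \itemize{
#'   \item \strong{cascade}: a segmentation U-net (1 channel in, 2-class
#'     softmax) whose foreground probability map, concatenated with the
#'     input slice, feeds a differentiation U-net (2 channels in, 3-class
#'     softmax). The two stages form one computation graph and train jointly
#'     under the combined loss, so the differentiation error back-propagates
#'     into the segmentation stage.
#'   \item \strong{pipeline}: the same two stages trained independently and
#'     chained only at inference.
#'   \item \strong{separate}: two independent binary U-nets, one per lesion
#'     class; their thresholded masks may overlap, which is reported, not
#'     resolved.
#' }
#'
#' @name architectures
NULL

#' Build a two-stage (cascade or pipeline) model
#'
#' @param base_channels first-layer channel count C of both U-nets.
#' @param depth U-net depth.
#' @param seed initialisation seed (stage seeds derived from it).
#' @param arch `"cascade"` or `"pipeline"`; the structure is identical, the
#'   training recipe differs.
#' @return a `wmh_model` list with `stage1` (binary segmentation U-net) and
#'   `stage2` (3-class differentiation U-net).
#' @export
build_cascade <- function(base_channels = 64L, depth = 4L, seed = 1L,
                          arch = c("cascade", "pipeline")) {
  arch <- match.arg(arch)
  structure(list(arch = arch,
                 stage1 = build_unet(1L, 2L, base_channels, depth, seed = seed,
                                     head_prior = c(0.98, 0.02)),
                 stage2 = build_unet(2L, 3L, base_channels, depth, seed = seed + 1L,
                                     head_prior = c(0.98, 0.012, 0.008))),
            class = "wmh_model")
}

#' Build a separate-binary-segmenters model
#'
#' @inheritParams build_cascade
#' @return a `wmh_model` with `pv_net` and `d_net`, each a binary U-net.
#' @export
build_separate <- function(base_channels = 64L, depth = 4L, seed = 1L) {
  structure(list(arch = "separate",
                 pv_net = build_unet(1L, 2L, base_channels, depth, seed = seed,
                                     head_prior = c(0.98, 0.02)),
                 d_net = build_unet(1L, 2L, base_channels, depth, seed = seed + 1L,
                                    head_prior = c(0.99, 0.01))),
            class = "wmh_model")
}

#' @export
print.wmh_model <- function(x, ...) {
  cat(sprintf("<wmh_model> arch=%s\n", x$arch))
  for (nm in setdiff(names(x), "arch")) { cat(" ", nm, ": "); print(x[[nm]]) }
  invisible(x)
}

#' Cascade forward pass
#'
#' Stage 1 consumes the normalized slice and emits the 2-class WMH
#' probability map; stage 2 consumes the slice concatenated with the stage-1
#' foreground probability channel and emits the 3-class map. Both stages
#' share one computation graph, so gradients from the stage-2 loss reach
#' stage-1 weights through the hand-off channel.
#'
#' @param model a cascade/pipeline `wmh_model`.
#' @param X pixel-major matrix (`H*W*N` x 1) of normalized intensities.
#' @param H,W,N geometry as in [unet_forward()].
#' @param train logical, batch-norm mode.
#' @return list with `seg_prob` (pixels x 2), `class_prob` (pixels x 3),
#'   updated `model`, and the two forward caches.
#' @export
cascade_forward <- function(model, X, H, W, N, train = FALSE) {
  stopifnot(inherits(model, "wmh_model"), model$arch %in% c("cascade", "pipeline"))
  f1 <- unet_forward(model$stage1, X, H, W, N, train = train)
  model$stage1 <- f1$net
  X2 <- cbind(X, f1$prob[, 2L])
  f2 <- unet_forward(model$stage2, X2, H, W, N, train = train)
  model$stage2 <- f2$net
  list(seg_prob = f1$prob, class_prob = f2$prob, model = model,
       cache1 = f1$cache, cache2 = f2$cache)
}

# Backward through the full cascade under CLoss. Returns grads for both
# stages. dLogits of stage 2 is the CE gradient; the stage-2 input gradient
# on the probability channel joins the DSC gradient at stage 1's softmax.
cascade_backward <- function(model, fwd, class_target, eps = 1e-4) {
  npix <- nrow(fwd$class_prob)
  N <- fwd$cache2$geom$N
  Y3 <- one_hot(class_target, 3L)
  dLogits2 <- (fwd$class_prob - Y3) / npix
  b2 <- unet_backward(model$stage2, fwd$cache2, dLogits2)
  g <- as.numeric(class_target %in% c(1L, 2L))
  p_fg <- fwd$seg_prob[, 2L]
  dP_fg <- batch_dsc_loss_grad(p_fg, g, N, eps = eps) + b2$dInput[, 2L]
  dl2 <- dP_fg * p_fg * (1 - p_fg)
  dLogits1 <- cbind(-dl2, dl2)
  b1 <- unet_backward(model$stage1, fwd$cache1, dLogits1)
  list(grads1 = b1$grads, grads2 = b2$grads)
}

# Backward for a standalone binary segmentation U-net trained with
# DSC loss + 2-class CE loss (pipeline/separate stage recipe).
binary_seg_backward <- function(net, fwd, target, eps = 1e-4) {
  npix <- nrow(fwd$prob)
  N <- fwd$cache$geom$N
  Y2 <- one_hot(as.integer(target), 2L)
  dLogits <- (fwd$prob - Y2) / npix
  p_fg <- fwd$prob[, 2L]
  dP_fg <- batch_dsc_loss_grad(p_fg, target, N, eps = eps)
  dl2 <- dP_fg * p_fg * (1 - p_fg)
  dLogits <- dLogits + cbind(-dl2, dl2)
  unet_backward(net, fwd$cache, dLogits)
}

binary_seg_loss <- function(prob, target, n_slices, eps = 1e-4) {
  batch_dsc_loss(prob[, 2L], target, n_slices, eps = eps) +
    ce_loss(prob, one_hot(as.integer(target), 2L))
}

#' Per-pixel class prediction from a 3-class probability map
#'
#' Argmax over \{background, pv, d\} with ties broken toward the lower class
#' index. The output is a partition: no pixel can be both pv and d.
#'
#' @param class_prob pixels x 3 probability matrix, or an `H x W x 3` array.
#' @return integer labels in \{0, 1, 2\}, as a vector (matrix input) or
#'   `H x W` matrix (array input).
#' @export
predict_labels <- function(class_prob) {
  if (is.array(class_prob) && length(dim(class_prob)) == 3L) {
    d <- dim(class_prob)
    m <- matrix(class_prob, d[1] * d[2], d[3])
    return(matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2]))
  }
  stopifnot(is.matrix(class_prob), ncol(class_prob) == 3L)
  max.col(class_prob, ties.method = "first") - 1L
}

#' Independent thresholding of two binary probability maps
#'
#' The separate architecture thresholds each lesion class on its own, so a
#' pixel can be claimed by both models; the overlap is reported as-is.
#'
#' @param pv_prob,d_prob foreground probability vectors/matrices, congruent.
#' @param threshold decision threshold in (0, 1), default 0.5.
#' @return list with logical `pv_mask`, `d_mask`, `overlap_mask`
#'   (`pv_mask & d_mask`).
#' @export
separate_predict <- function(pv_prob, d_prob, threshold = 0.5) {
  stopifnot(all(dim(pv_prob) == dim(d_prob)) || length(pv_prob) == length(d_prob),
            threshold > 0, threshold < 1)
  pv <- pv_prob > threshold
  d <- d_prob > threshold
  list(pv_mask = pv, d_mask = d, overlap_mask = pv & d)
}
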