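#' Training-time augmentation
#'
#' The five training transforms, applied jointly to an image slice and its
#' label map: rotation, shift, scale, horizontal flip (one composed affine
#' map about the image centre) and a gamma intensity change computed in raw
#' intensity space. Images are interpolated bilinearly, labels with
#' nearest-neighbour so codes stay categorical.
#'
#' @name augmentation
NULL

#' Augmentation configuration
#'
#' Defaults are the training ranges: rotation [-30, 30] degrees, shift
#' [-26, 26] pixels per axis (integer draws), scale [0.9, 1.1], horizontal
#' flip with probability 0.5, gamma drawn from [0.5, 1].
#'
#' @param rotate_deg numeric length-2 range in degrees.
#' @param shift_px numeric length-2 range in pixels.
#' @param scale numeric length-2 range.
#' @param hflip_prob flip probability in [0, 1].
#' @param gamma_range numeric length-2 range, positive.
#' @param enabled named logical vector switching individual transforms, for
#'   ablation; names among rotate, shift, scale, hflip, gamma.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotate_deg = c(-30, 30), shift_px = c(-26, 26),
                           scale = c(0.9, 1.1), hflip_prob = 0.5,
                           gamma_range = c(0.5, 1),
                           enabled = c(rotate = TRUE, shift = TRUE,
                                       scale = TRUE, hflip = TRUE, gamma = TRUE)) {
  stopifnot(hflip_prob >= 0, hflip_prob <= 1, all(gamma_range > 0),
            length(rotate_deg) == 2L, length(shift_px) == 2L, length(scale) == 2L)
  en <- c(rotate = TRUE, shift = TRUE, scale = TRUE, hflip = TRUE, gamma = TRUE)
  en[names(enabled)] <- enabled
  structure(list(rotate_deg = rotate_deg, shift_px = shift_px, scale = scale,
                 hflip_prob = hflip_prob, gamma_range = gamma_range,
                 enabled = en), class = "augment_config")
}

#' Gamma intensity transform
#'
#' Rescales the slice to [0, 1] over its own range, raises it to the power
#' gamma and maps back, so the minimum and maximum of the input are
#' preserved exactly:
#' \deqn{((x - \min x)/(\max x - \min x))^{\gamma} (\max x - \min x) + \min x.}
#' A constant slice is returned unchanged.
#'
#' @param image 2D numeric matrix.
#' @param gamma positive exponent.
#' @return matrix of the same shape, same min and max.
#' @export
gamma_intensity <- function(image, gamma) {
  stopifnot(gamma > 0)
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)
  ((image - lo) / (hi - lo))^gamma * (hi - lo) + lo
}

#' Composed spatial transform of an image/label pair
#'
#' Applies one affine map about the image centre: optional horizontal flip,
#' then scaling, then rotation, then translation. Sampling is by inverse
#' mapping; intensities are interpolated bilinearly with out-of-frame pixels
#' filled with the image minimum (background-like), labels with
#' nearest-neighbour filled with 0.
#'
#' @param image 2D numeric matrix.
#' @param labels congruent 2D integer matrix (may be NULL).
#' @param rotate_deg rotation angle in degrees (counter-clockwise in row/col
#'   coordinates).
#' @param shift_px numeric (rows, cols) translation in pixels.
#' @param scale isotropic scale factor (>1 enlarges).
#' @param hflip logical; mirror columns.
#' @return list with `image` and `labels`.
#' @export
spatial_transform <- function(image, labels = NULL, rotate_deg = 0,
                              shift_px = c(0, 0), scale = 1, hflip = FALSE) {
  stopifnot(is.matrix(image), scale > 0)
  if (!is.null(labels)) stopifnot(all(dim(labels) == dim(image)))
  H <- nrow(image); W <- ncol(image)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  th <- rotate_deg * pi / 180
  # inverse map: undo shift, rotation, scale, then flip
  r_out <- matrix(seq_len(H), H, W) - cr - shift_px[1]
  c_out <- matrix(seq_len(W), H, W, byrow = TRUE) - cc - shift_px[2]
  ca <- cos(th); sa <- sin(th)
  r_src <- (r_out * ca + c_out * sa) / scale
  c_src <- (-r_out * sa + c_out * ca) / scale
  if (hflip) c_src <- -c_src
  r_src <- r_src + cr
  c_src <- c_src + cc

  sample_nn <- function(m, fill) {
    r <- round(r_src); cc2 <- round(c_src)
    ok <- r >= 1 & r <= H & cc2 >= 1 & cc2 <= W
    out <- matrix(fill, H, W)
    out[ok] <- m[cbind(r[ok], cc2[ok])]
    storage.mode(out) <- storage.mode(m)
    out
  }
  sample_bilinear <- function(m, fill) {
    r0 <- floor(r_src); c0 <- floor(c_src)
    fr <- r_src - r0; fc <- c_src - c0
    get <- function(ri, ci) {
      ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
      v <- matrix(fill, H, W)
      v[ok] <- m[cbind(ri[ok], ci[ok])]
      v
    }
    get(r0, c0) * (1 - fr) * (1 - fc) + get(r0, c0 + 1) * (1 - fr) * fc +
      get(r0 + 1, c0) * fr * (1 - fc) + get(r0 + 1, c0 + 1) * fr * fc
  }
  list(image = sample_bilinear(image, fill = min(image)),
       labels = if (is.null(labels)) NULL else sample_nn(labels, fill = 0L))
}

#' Randomly augment a sample
#'
#' Draws rotation, shift (integer pixels), scale and gamma uniformly from
#' their configured ranges and the flip from a Bernoulli(hflip_prob), then
#' applies the gamma intensity change in raw intensity space followed by the
#' composed spatial transform. Consumes the session RNG stream, so results
#' are reproducible under `set.seed()`.
#'
#' @param image 2D numeric matrix (raw intensities, before normalization).
#' @param labels congruent label matrix or NULL.
#' @param config an [augment_config].
#' @return list with `image`, `labels`, and `draws` (the sampled parameters).
#' @export
augment <- function(image, labels = NULL, config = augment_config()) {
  stopifnot(inherits(config, "augment_config"))
  en <- config$enabled
  g <- if (en[["gamma"]]) stats::runif(1, config$gamma_range[1], config$gamma_range[2]) else 1
  rot <- if (en[["rotate"]]) stats::runif(1, config$rotate_deg[1], config$rotate_deg[2]) else 0
  sh <- if (en[["shift"]]) sample(seq.int(config$shift_px[1], config$shift_px[2]), 2, replace = TRUE) else c(0L, 0L)
  sc <- if (en[["scale"]]) stats::runif(1, config$scale[1], config$scale[2]) else 1
  fl <- if (en[["hflip"]]) stats::runif(1) < config$hflip_prob else FALSE
  out_img <- if (g != 1) gamma_intensity(image, g) else image
  if (rot != 0 || any(sh != 0) || sc != 1 || fl) {
    tr <- spatial_transform(out_img, labels, rotate_deg = rot, shift_px = sh,
                            scale = sc, hflip = fl)
  } else {
    tr <- list(image = out_img, labels = labels)
  }
  list(image = tr$image, labels = tr$labels,
       draws = list(gamma = g, rotate_deg = rot, shift_px = sh,
                    scale = sc, hflip = fl))
}
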