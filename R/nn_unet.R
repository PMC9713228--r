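#' U-net backbone
#'
#' A Ronneberger-style encoder-decoder with skip connections: `depth`
#' resolution levels with channel widths `C * 2^(level-1)` (level `depth` is
#' the bottleneck), two padded 3x3 convolutions with batch normalization and
#' ReLU per level, 2x2 max-pooling between encoder levels, factor-2 bilinear
#' upsampling with skip concatenation in the decoder, and a 1x1 convolution
#' head whose softmax yields per-pixel class probabilities. Padded
#' convolutions keep output size equal to input size.
#'
#' @name unet
NULL

#' Build a U-net
#'
#' @param in_channels input channels (1 for a FLAIR slice; 2 for the cascade
#'   differentiation stage).
#' @param out_channels classes of the softmax head (2 or 3).
#' @param base_channels first-level channel count C (64 in the full-scale
#'   configuration; tests run C = 8).
#' @param depth number of resolution levels including the bottleneck.
#' @param seed weight initialisation seed; two builds with the same seed have
#'   identical weights.
#' @param image_size optional (rows, cols) to validate divisibility by
#'   `2^(depth-1)` at build time.
#' @param head_prior optional class-prior vector of length `out_channels`;
#'   the head bias is initialised to its log, so the untrained network
#'   starts from the background-dominated class frequencies. Stabilises
#'   rare-foreground training.
#' @return an object of class `unet`.
#' @export
build_unet <- function(in_channels, out_channels, base_channels = 64L,
                       depth = 4L, seed = 1L, image_size = NULL,
                       head_prior = NULL) {
  stopifnot(base_channels >= 1, out_channels %in% c(2L, 3L), depth >= 2L,
            in_channels >= 1)
  if (!is.null(image_size) && any(image_size %% 2^(depth - 1L) != 0))
    stop("image size must be divisible by 2^(depth-1) = ", 2^(depth - 1L))
  ch <- base_channels * 2^(seq_len(depth) - 1L)
  params <- list(); states <- list()
  with_seed(seed, {
    for (l in seq_len(depth)) {
      cin <- if (l == 1L) in_channels else ch[l - 1L]
      params[[paste0("enc", l, "a")]] <- conv_init(cin, ch[l])
      params[[paste0("enc", l, "a_bn")]] <- bn_init(ch[l])
      params[[paste0("enc", l, "b")]] <- conv_init(ch[l], ch[l])
      params[[paste0("enc", l, "b_bn")]] <- bn_init(ch[l])
      states[[paste0("enc", l, "a_bn")]] <- bn_state_init(ch[l])
      states[[paste0("enc", l, "b_bn")]] <- bn_state_init(ch[l])
    }
    for (l in rev(seq_len(depth - 1L))) {
      cin <- ch[l] + ch[l + 1L]   # skip + upsampled
      params[[paste0("dec", l, "a")]] <- conv_init(cin, ch[l])
      params[[paste0("dec", l, "a_bn")]] <- bn_init(ch[l])
      params[[paste0("dec", l, "b")]] <- conv_init(ch[l], ch[l])
      params[[paste0("dec", l, "b_bn")]] <- bn_init(ch[l])
      states[[paste0("dec", l, "a_bn")]] <- bn_state_init(ch[l])
      states[[paste0("dec", l, "b_bn")]] <- bn_state_init(ch[l])
    }
    params[["head"]] <- head_init(ch[1L], out_channels, prior = head_prior)
  })
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 params = params, states = states),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<unet> in=%d out=%d C=%d depth=%d (%s parameters)\n",
              x$in_channels, x$out_channels, x$base_channels, x$depth,
              format(n_par, big.mark = ",")))
  invisible(x)
}

# One conv + BN + ReLU step. Returns activation plus everything backward needs.
.block_step <- function(X, net, name, idx, train) {
  par <- net$params[[name]]
  z <- conv_fwd(X, par, idx)
  bn <- bn_fwd(z, net$params[[paste0(name, "_bn")]],
               net$states[[paste0(name, "_bn")]], train)
  a <- relu_fwd(bn$out)
  list(a = a, X = X, bn_cache = bn$cache, state = bn$state)
}

#' Forward pass of a U-net
#'
#' @param net a [build_unet()] network.
#' @param X pixel-major activation matrix (`H*W*N` rows, `in_channels`
#'   columns).
#' @param H,W slice shape; must be divisible by `2^(depth-1)`.
#' @param N number of slices in the batch.
#' @param train logical; training mode uses batch statistics in the BN
#'   layers and updates their running moments.
#' @return list with `logits`, `prob` (softmax, rows sum to 1), updated
#'   `net`, and `cache` for [unet_backward()].
#' @export
unet_forward <- function(net, X, H, W, N, train = FALSE) {
  stopifnot(inherits(net, "unet"), ncol(X) == net$in_channels,
            nrow(X) == H * W * N)
  if (any(c(H, W) %% 2^(net$depth - 1L) != 0))
    stop("input size ", H, "x", W, " not divisible by 2^(depth-1)")
  depth <- net$depth
  cache <- list(geom = list(H = H, W = W, N = N))
  act <- X
  h <- H; w <- W
  for (l in seq_len(depth)) {
    idx <- conv_indices(h, w, N)
    sa <- .block_step(act, net, paste0("enc", l, "a"), idx, train)
    net$states[[paste0("enc", l, "a_bn")]] <- sa$state
    sb <- .block_step(sa$a, net, paste0("enc", l, "b"), idx, train)
    net$states[[paste0("enc", l, "b_bn")]] <- sb$state
    cache[[paste0("enc", l)]] <- list(a = sa, b = sb, h = h, w = w)
    act <- sb$a
    if (l < depth) {
      pidx <- pool_indices(h, w, N)
      pf <- pool_fwd(act, pidx)
      cache[[paste0("pool", l)]] <- list(arg = pf$arg, h = h, w = w)
      act <- pf$out
      h <- h %/% 2L; w <- w %/% 2L
    }
  }
  for (l in rev(seq_len(depth - 1L))) {
    up <- up_fwd(act, h, w, N)
    cache[[paste0("up", l)]] <- list(h = h, w = w)
    h <- h * 2L; w <- w * 2L
    skip <- cache[[paste0("enc", l)]]$b$a
    act <- cbind(skip, up)
    idx <- conv_indices(h, w, N)
    sa <- .block_step(act, net, paste0("dec", l, "a"), idx, train)
    net$states[[paste0("dec", l, "a_bn")]] <- sa$state
    sb <- .block_step(sa$a, net, paste0("dec", l, "b"), idx, train)
    net$states[[paste0("dec", l, "b_bn")]] <- sb$state
    cache[[paste0("dec", l)]] <- list(a = sa, b = sb, h = h, w = w)
    act <- sb$a
  }
  logits <- head_fwd(act, net$params[["head"]])
  cache[["head_in"]] <- act
  list(logits = logits, prob = softmax_rows(logits), net = net, cache = cache)
}

#' Backward pass of a U-net
#'
#' @param net the network used in the forward pass.
#' @param cache forward cache from [unet_forward()].
#' @param dLogits gradient of the loss with respect to the head logits.
#' @return list with `grads` (same structure as `net$params`) and `dInput`
#'   (gradient with respect to the input activation matrix).
#' @export
unet_backward <- function(net, cache, dLogits) {
  depth <- net$depth
  N <- cache$geom$N
  hb <- head_bwd(dLogits, cache[["head_in"]], net$params[["head"]])
  grads <- list(head = hb$grad)
  dact <- hb$dX

  step_bwd <- function(dA, name, blk, idx) {
    # relu -> bn -> conv
    dA <- relu_bwd(dA, blk$a)
    bb <- bn_bwd(dA, blk$bn_cache, net$params[[paste0(name, "_bn")]])
    cb <- conv_bwd(bb$dX, blk$X, net$params[[name]], idx)
    grads[[paste0(name, "_bn")]] <<- bb$grad
    grads[[name]] <<- cb$grad
    cb$dX
  }

  # decoder backward, finest level first; dact chains through the upsample
  # into the next-coarser decoder level, ending at the bottleneck output
  dskips <- vector("list", depth - 1L)
  for (l in seq_len(depth - 1L)) {
    blk <- cache[[paste0("dec", l)]]
    idx <- conv_indices(blk$h, blk$w, N)
    dact <- step_bwd(dact, paste0("dec", l, "b"), blk$b, idx)
    dact <- step_bwd(dact, paste0("dec", l, "a"), blk$a, idx)
    # split into skip and upsampled parts
    c_skip <- net$base_channels * 2^(l - 1L)
    dskips[[l]] <- dact[, seq_len(c_skip), drop = FALSE]
    dup <- dact[, -seq_len(c_skip), drop = FALSE]
    upg <- cache[[paste0("up", l)]]
    dact <- up_bwd(dup, upg$h, upg$w, N)
  }

  # encoder backward, bottleneck first
  denc_next <- NULL
  for (l in rev(seq_len(depth))) {
    blk <- cache[[paste0("enc", l)]]
    idx <- conv_indices(blk$h, blk$w, N)
    if (l == depth) {
      dA <- dact
    } else {
      dA <- dskips[[l]]
      pidx <- pool_indices(blk$h, blk$w, N)
      parg <- cache[[paste0("pool", l)]]$arg
      dA <- dA + pool_bwd(denc_next, parg, pidx, blk$h * blk$w * N)
    }
    dA <- step_bwd(dA, paste0("enc", l, "b"), blk$b, idx)
    dA <- step_bwd(dA, paste0("enc", l, "a"), blk$a, idx)
    denc_next <- dA
  }
  list(grads = grads, dInput = denc_next)
}
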