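# Shared fixtures: everything is generated in code at test time.

# Small easy-contrast phantom parameters used across tests.
tiny_params <- function(seed = 1L, pv = 1L, d = 1L, shape = 64L, slices = 2L) {
  synth_params(image_shape = c(shape, shape), n_slices = slices,
               pv_burden = pv, d_burden = d,
               lesion_intensity = 0.5, noise_sigma = 0.02, seed = seed)
}

# Random binary mask pair for metric oracles.
random_mask_pair <- function(n = 16L, p_pred = 0.3, p_gold = 0.3) {
  list(pred = matrix(stats::runif(n * n) < p_pred, n, n),
       gold = matrix(stats::runif(n * n) < p_gold, n, n))
}

# Brute-force confusion counts by explicit double loop.
confusion_loop <- function(pred, gold) {
  TP <- TN <- FP <- FN <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j]; g <- gold[i, j]
    if (p && g) TP <- TP + 1L
    else if (!p && !g) TN <- TN + 1L
    else if (p && !g) FP <- FP + 1L
    else FN <- FN + 1L
  }
  list(TP = TP, TN = TN, FP = FP, FN = FN)
}

# Brute-force minimum Euclidean distance from mask pixels to target pixels.
min_dist_loop <- function(from_mask, to_mask) {
  fr <- which(from_mask, arr.ind = TRUE)
  to <- which(to_mask, arr.ind = TRUE)
  if (nrow(fr) == 0 || nrow(to) == 0) return(Inf)
  best <- Inf
  for (i in seq_len(nrow(fr))) {
    d2 <- (to[, 1] - fr[i, 1])^2 + (to[, 2] - fr[i, 2])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# Numerical gradient of f at x (central differences).
num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
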