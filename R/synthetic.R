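#' Synthetic FLAIR phantom cohorts
#'
#' Generates 2D FLAIR-like phantoms with ground-truth periventricular/deep
#' lesion labels and Fazekas-like burden grades: an elliptical bright brain,
#' two dark ventricle lobes (CSF is nulled on FLAIR), hyperintense
#' periventricular lesions grown from the ventricle wall and deep lesions
#' placed strictly away from it. The generator exists so that training,
#' prediction and evaluation are exercised end-to-end without clinical data.
#'
#' @name synthetic_data
NULL

#' Phantom generation parameters
#'
#' @param image_shape integer (rows, cols); default 256 x 256, the FLAIR
#'   acquisition matrix. In-plane spacing is scaled as `0.9 * 256 / rows` mm
#'   so lesion volumes in ml are resolution-invariant.
#' @param n_slices slices per subject (default 10; lesions occupy the
#'   central slices).
#' @param pv_burden,d_burden Fazekas-like burden grade 0-3 per lesion type
#'   (0 none; 1 few small; 2 more/larger; 3 confluent).
#' @param lesion_intensity lesion contrast over white matter, relative units
#'   (white matter sits at 0.7, background at 0.02, CSF at 0.08).
#' @param noise_sigma additive Gaussian noise SD, relative units.
#' @param contiguity_tol_px max Euclidean pixel distance to the ventricle for
#'   a lesion to count as periventricular (default 1: "touching", with one
#'   pixel absorbing rasterization).
#' @param slice_thickness_mm slice thickness (default 5.5).
#' @param seed integer; the subject is deterministic given the seed.
#' @return A `synth_params` list.
#' @export
synth_params <- function(image_shape = c(256L, 256L), n_slices = 10L,
                         pv_burden = 1L, d_burden = 1L,
                         lesion_intensity = 0.3, noise_sigma = 0.05,
                         contiguity_tol_px = 1, slice_thickness_mm = 5.5,
                         seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16),
            n_slices >= 1,
            pv_burden %in% 0:3, d_burden %in% 0:3,
            noise_sigma >= 0, contiguity_tol_px >= 0, lesion_intensity > 0)
  structure(list(image_shape = as.integer(image_shape),
                 n_slices = as.integer(n_slices),
                 pv_burden = as.integer(pv_burden),
                 d_burden = as.integer(d_burden),
                 lesion_intensity = lesion_intensity,
                 noise_sigma = noise_sigma,
                 contiguity_tol_px = contiguity_tol_px,
                 slice_thickness_mm = slice_thickness_mm,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' 8-connected component labelling of a binary 2D mask
#'
#' In-plane 8-connectivity, no 3D merging across slices; lesions on 5.5 mm
#' slices are treated strictly slice-wise.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix; 0 background, components numbered from 1.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask != 0)
  lab <- integer(H * W)
  if (length(fg) == 0L) return(matrix(lab, H, W))
  offs <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
  is_fg <- logical(H * W); is_fg[fg] <- TRUE
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      rows <- ((frontier - 1L) %% H) + 1L
      nb <- rep(frontier, each = 8L) + offs
      nr <- rep(rows, each = 8L) + c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
      ok <- nb >= 1L & nb <= H * W & nr >= 1L & nr <= H
      nb <- nb[ok]
      nb <- unique(nb[is_fg[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  matrix(lab, H, W)
}

# Euclidean distance of every pixel to the nearest TRUE pixel of mask2d.
# Empty mask -> all Inf.
distance_to_mask <- function(mask2d) {
  if (!any(mask2d != 0)) return(matrix(Inf, nrow(mask2d), ncol(mask2d)))
  d <- EBImage::distmap(1 - (mask2d != 0), metric = "euclidean")
  matrix(as.numeric(d), nrow(mask2d), ncol(mask2d))
}

#' Classify lesion components as periventricular or deep
#'
#' Each 8-connected in-plane lesion component whose minimum Euclidean
#' distance to the ventricle mask is at most `contiguity_tol_px` is labelled
#' 1 (periventricular); every other component is labelled 2 (deep). This
#' rule defines phantom ground truth and doubles as a rule-based
#' post-processor for binary WMH predictions.
#'
#' @param lesion_mask binary 2D matrix or 3D array.
#' @param ventricle_mask binary mask congruent with `lesion_mask`.
#' @param contiguity_tol_px non-negative distance tolerance in pixels.
#' @return integer array congruent with the input, values in \{0, 1, 2\}.
#' @export
assign_lesion_classes <- function(lesion_mask, ventricle_mask,
                                  contiguity_tol_px = 1) {
  stopifnot(all(dim(lesion_mask) == dim(ventricle_mask)),
            contiguity_tol_px >= 0)
  if (!any(ventricle_mask != 0) && any(lesion_mask != 0))
    warning("empty ventricle mask: all lesions labelled deep (2)")
  one_slice <- function(les, vent) {
    out <- matrix(0L, nrow(les), ncol(les))
    if (!any(les != 0)) return(out)
    comp <- label_components(les != 0)
    dv <- distance_to_mask(vent)
    for (k in seq_len(max(comp))) {
      px <- comp == k
      out[px] <- if (min(dv[px]) <= contiguity_tol_px) 1L else 2L
    }
    out
  }
  if (is.matrix(lesion_mask)) return(one_slice(lesion_mask, ventricle_mask))
  out <- array(0L, dim = dim(lesion_mask))
  for (k in seq_len(dim(lesion_mask)[3]))
    out[, , k] <- one_slice(lesion_mask[, , k], ventricle_mask[, , k])
  out
}

# --- geometry helpers ------------------------------------------------------

mask_ellipse <- function(H, W, center, semi, angle = 0) {
  r <- matrix(seq_len(H), H, W) - center[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  ca <- cos(angle); sa <- sin(angle)
  u <- r * ca + cc * sa
  v <- -r * sa + cc * ca
  (u / semi[1])^2 + (v / semi[2])^2 <= 1
}

mask_disc <- function(H, W, center, radius) {
  mask_ellipse(H, W, center, c(radius, radius))
}

# one step of 8-neighbour binary dilation
dilate8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  m <- mask != 0
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    okr <- rs >= 1 & rs <= H; okc <- cs >= 1 & cs <= W
    out[rs[okr], cs[okc]] <- out[rs[okr], cs[okc]] | m[okr, okc]
  }
  out
}

# intensity tiers of the phantom (relative units)
PHANTOM_LEVELS <- c(background = 0.02, brain = 0.70, csf = 0.08)

# Fazekas-like burden tiers, in units of u = rows / 128 (linear image scale).
# Counts are per lesion-bearing slice (pv caps) or per subject (d blobs).
# Radii are floored at ~2 px so lesions stay resolvable on the small grids
# used for desk-scale runs; at the native 256 grid the floors never bind.
pv_tiers <- function(grade, u) {
  switch(grade + 1L,
         list(n_caps = 0L, radius = 0, halo = 0),
         list(n_caps = 2L, radius = max(2.2, 1.2 * u), halo = 0),
         list(n_caps = 4L, radius = max(2.6, 2.0 * u), halo = 0),
         list(n_caps = 6L, radius = max(3.0, 2.6 * u), halo = max(2.5, 3 * u)))
}

d_tiers <- function(grade, u) {
  switch(grade + 1L,
         list(n_blobs = 0L, r_min = 0, r_max = 0),
         list(n_blobs = 6L, r_min = max(1.8, 1.0 * u), r_max = max(2.4, 1.6 * u)),
         list(n_blobs = 10L, r_min = max(2.0, 1.6 * u), r_max = max(2.8, 2.4 * u)),
         list(n_blobs = 20L, r_min = max(2.4, 2.4 * u), r_max = max(3.4, 3.6 * u)))
}

#' Generate one phantom subject
#'
#' Deterministic given `params$seed`. Each slice holds an elliptical bright
#' brain and two dark ventricle lobes; periventricular lesions are caps (and,
#' at grade 3, a confluent halo) grown from the ventricle wall; deep lesions
#' are elliptical blobs placed strictly farther than the contiguity tolerance
#' from the ventricle and never touching a periventricular lesion, so the
#' distance rule reproduces the ground-truth partition exactly. Gaussian
#' noise is added last.
#'
#' @param params a [synth_params] object.
#' @param subject_id identifier stored in the output objects.
#' @return A list of class `phantom_subject`: `image` ([wmh_volume]), `truth`
#'   ([wmh_labelmap]), `ventricle_mask` (logical array), grades and true
#'   lesion volumes in ml.
#' @export
generate_subject <- function(params, subject_id = sprintf("phantom%04d", params$seed)) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    H <- params$image_shape[1]; W <- params$image_shape[2]
    nsl <- params$n_slices
    u <- H / 128
    spacing <- c(0.9 * 256 / H, 0.9 * 256 / W, params$slice_thickness_mm)
    tol <- params$contiguity_tol_px

    img <- array(PHANTOM_LEVELS[["background"]], dim = c(H, W, nsl))
    vent <- array(FALSE, dim = c(H, W, nsl))
    les_pv <- array(FALSE, dim = c(H, W, nsl))
    les_d <- array(FALSE, dim = c(H, W, nsl))

    mid <- (nsl + 1) / 2
    halfspan <- max(nsl / 2, 1)
    prof <- sqrt(pmax(1 - ((seq_len(nsl) - mid) / (halfspan + 0.5))^2, 0.30))
    lesion_slices <- which(prof > 0.8)     # central slices carry lesions
    if (!length(lesion_slices)) lesion_slices <- unique(round(mid))

    ptier <- pv_tiers(params$pv_burden, u)
    dtier <- d_tiers(params$d_burden, u)

    # distribute deep blobs over the lesion-bearing slices
    d_slice_of <- if (dtier$n_blobs > 0)
      sort(sample(rep(lesion_slices, length.out = max(dtier$n_blobs, length(lesion_slices)))[seq_len(dtier$n_blobs)]))
    else integer(0)

    brain_all <- vector("list", nsl)
    for (k in seq_len(nsl)) {
      f <- prof[k]
      brain <- mask_ellipse(H, W, c(H / 2, W / 2), c(0.42 * H * f, 0.37 * W * f))
      jit <- stats::runif(2, -0.6, 0.6) * u
      v1 <- mask_ellipse(H, W, c(H / 2 + jit[1], W / 2 - 0.085 * W + jit[2]),
                         c(0.16 * H * f, 0.040 * W * f + 0.6), angle = 0.12)
      v2 <- mask_ellipse(H, W, c(H / 2 + jit[1], W / 2 + 0.085 * W + jit[2]),
                         c(0.16 * H * f, 0.040 * W * f + 0.6), angle = -0.12)
      vk <- (v1 | v2) & brain
      vent[, , k] <- vk
      brain_all[[k]] <- brain
      img[, , k][brain] <- PHANTOM_LEVELS[["brain"]]
      img[, , k][vk] <- PHANTOM_LEVELS[["csf"]]
    }

    for (k in lesion_slices) {
      brain <- brain_all[[k]]
      vk <- vent[, , k]
      if (!any(vk)) next
      dv <- distance_to_mask(vk)
      wm <- brain & !vk
      # wall pixels: just outside the ventricle
      wall <- which(wm & dv <= max(tol, 1))
      if (params$pv_burden > 0) {
        if (!length(wall))
          stop("image too small to place periventricular lesions")
        pvk <- matrix(FALSE, H, W)
        centers <- sample(wall, min(ptier$n_caps, length(wall)))
        for (s in centers) {
          ctr <- c((s - 1) %% H + 1, (s - 1) %/% H + 1)
          pvk <- pvk | mask_disc(H, W, ctr, ptier$radius * stats::runif(1, 0.8, 1.25))
        }
        if (ptier$halo > 0) pvk <- pvk | (dv <= ptier$halo)
        pvk <- pvk & wm
        les_pv[, , k] <- pvk
      }
      if (params$d_burden > 0) {
        nd <- sum(d_slice_of == k)
        if (nd > 0) {
          # deep lesions live in mid-white-matter: keep their centres well
          # clear of the periventricular rim so the two classes' distance
          # distributions are separable, not merely disjoint
          margin <- max(dtier$r_max + tol + 2, 0.14 * H)
          d_edge <- distance_to_mask(!brain)
          allowed <- which(wm & dv > margin & d_edge > dtier$r_max + 1)
          # crowded grids: relax toward the hard minimum; the clip below
          # still enforces the distance invariant exactly
          if (!length(allowed))
            allowed <- which(wm & dv > max(tol + 1 + dtier$r_min, 0.09 * H) &
                               d_edge > 1)
          if (!length(allowed))
            allowed <- which(wm & dv > tol + 1 + dtier$r_min & d_edge > 1)
          if (!length(allowed))
            stop("image too small to place deep lesions at the required ",
                 "distance from the ventricle")
          dk <- matrix(FALSE, H, W)
          centers <- sample(allowed, min(nd, length(allowed)))
          for (s in centers) {
            ctr <- c((s - 1) %% H + 1, (s - 1) %/% H + 1)
            rr <- stats::runif(1, dtier$r_min, dtier$r_max)
            dk <- dk | mask_ellipse(H, W, ctr, c(rr, rr * stats::runif(1, 0.7, 1.3)),
                                    angle = stats::runif(1, 0, pi))
          }
          # keep deep lesions strictly beyond the tolerance and off pv lesions
          dk <- dk & wm & (dv > tol + 1) & !dilate8(les_pv[, , k])
          les_d[, , k] <- dk
        }
      }
    }

    union <- les_pv | les_d
    truth <- assign_lesion_classes(union, vent, tol)
    lesion_level <- PHANTOM_LEVELS[["brain"]] + params$lesion_intensity
    img[union] <- lesion_level
    # mild smoothing for soft tissue boundaries, then noise last
    sm <- max(0.5, 0.6 * u)
    for (k in seq_len(nsl))
      img[, , k] <- as.numeric(EBImage::gblur(img[, , k], sigma = sm))
    if (params$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), 0, params$noise_sigma), dim = dim(img))

    vol_px <- prod(spacing) / 1000   # ml per voxel
    structure(list(
      image = wmh_volume(img, spacing, subject_id),
      truth = wmh_labelmap(truth, spacing, subject_id),
      ventricle_mask = vent,
      pv_grade = params$pv_burden, d_grade = params$d_burden,
      pv_volume_ml = sum(truth == 1L) * vol_px,
      d_volume_ml = sum(truth == 2L) * vol_px,
      params = params), class = "phantom_subject")
  })
}

#' Default cohort grade distribution
#'
#' Joint probabilities over (pv, d) Fazekas-like grade pairs, skewed toward
#' low burden so that about 90 percent of subjects carry a total grade below
#' 3, mirroring an early-stage community cohort.
#'
#' @return 4 x 4 matrix, rows = pv grade 0-3, cols = d grade 0-3, summing to 1.
#' @export
default_grade_distribution <- function() {
  p_pv <- c(0.42, 0.46, 0.10, 0.02)
  p_d <- c(0.55, 0.38, 0.05, 0.02)
  m <- outer(p_pv, p_d)
  dimnames(m) <- list(pv = 0:3, d = 0:3)
  m / sum(m)
}

#' Generate a phantom cohort
#'
#' Per-subject seeds are derived deterministically from the cohort seed, so
#' the same seed always yields the same cohort and manifest.
#'
#' @param n_subjects positive integer.
#' @param grade_distribution 4 x 4 matrix of probabilities over (pv, d) grade
#'   pairs (rows pv, cols d), summing to 1; default
#'   [default_grade_distribution()].
#' @param seed cohort seed.
#' @param base_params a [synth_params] supplying geometry/noise settings;
#'   its burdens and seed are overridden per subject.
#' @return list with `subjects` (list of `phantom_subject`) and `manifest`
#'   (tibble: subject_id, pv_grade, d_grade, pv_ml, d_ml, wmh_ml, seed).
#' @export
generate_cohort <- function(n_subjects, grade_distribution = default_grade_distribution(),
                            seed = 1L, base_params = synth_params()) {
  if (n_subjects <= 0) stop("n_subjects must be positive")
  stopifnot(all(dim(grade_distribution) == c(4L, 4L)),
            abs(sum(grade_distribution) - 1) < 1e-9,
            all(grade_distribution >= 0))
  draws <- with_seed(seed, {
    pair_idx <- sample.int(16L, n_subjects, replace = TRUE,
                           prob = as.numeric(grade_distribution))
    subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    list(pair_idx = pair_idx, subj_seeds = subj_seeds)
  })
  pv_g <- (draws$pair_idx - 1L) %% 4L
  d_g <- (draws$pair_idx - 1L) %/% 4L
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    p <- base_params
    p$pv_burden <- pv_g[i]; p$d_burden <- d_g[i]; p$seed <- draws$subj_seeds[i]
    subjects[[i]] <- generate_subject(p, subject_id = sprintf("phantom%04d", i))
  }
  manifest <- tibble::tibble(
    subject_id = vapply(subjects, function(s) s$image$subject_id, character(1)),
    pv_grade = pv_g, d_grade = d_g,
    pv_ml = vapply(subjects, function(s) s$pv_volume_ml, numeric(1)),
    d_ml = vapply(subjects, function(s) s$d_volume_ml, numeric(1)),
    wmh_ml = vapply(subjects, function(s) s$pv_volume_ml + s$d_volume_ml, numeric(1)),
    seed = draws$subj_seeds)
  list(subjects = subjects, manifest = manifest)
}

#' Write a phantom cohort to disk
#'
#' Writes per-subject `image.nii.gz`, `truth.nii.gz`, `ventricle.nii.gz`
#' and a cohort `manifest.csv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    d <- file.path(out_dir, s$image$subject_id)
    dir.create(d, showWarnings = FALSE)
    write_volume(s$image, file.path(d, "image.nii.gz"))
    write_labelmap(s$truth, file.path(d, "truth.nii.gz"))
    write_labelmap(wmh_labelmap(array(as.integer(s$ventricle_mask),
                                      dim = dim(s$ventricle_mask)),
                                s$image$spacing, s$image$subject_id),
                   file.path(d, "ventricle.nii.gz"), sidecar = FALSE)
  }
  mp <- file.path(out_dir, "manifest.csv")
  utils::write.csv(cohort$manifest, mp, row.names = FALSE)
  invisible(mp)
}
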