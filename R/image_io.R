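#' Image and label-map input/output
#'
#' Volumes are stacks of 2D FLAIR slices stored as 3D arrays with the slice
#' axis last (rows x cols x slices) together with the voxel geometry in mm.
#' Label maps use the integer encoding 0 = background, 1 = periventricular
#' WMH, 2 = deep WMH; the binary WMH mask is the set {1, 2}.
#'
#' @name image_io
NULL

LABEL_CODES <- c(background = 0L, pvWMH = 1L, dWMH = 2L)

# minimal header attribute list carrying the voxel geometry (qfactor + 3
# spacings; trailing pixdim entries unused for 3D volumes)
nifti_header <- function(spacing) {
  list(pixdim = c(-1, spacing, 0, 0, 0, 0))
}

#' Construct an image volume
#'
#' @param voxels 3D numeric array, rows x cols x slices.
#' @param spacing numeric length 3: in-plane row mm, in-plane col mm, slice
#'   thickness mm. All strictly positive.
#' @param subject_id character scalar.
#' @return An object of class `wmh_volume`.
#' @export
wmh_volume <- function(voxels, spacing, subject_id = "subject") {
  voxels <- as_volume_array(voxels)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing entries must be strictly positive and finite")
  if (any(!is.finite(voxels)))
    stop("all voxel intensities must be finite")
  structure(list(voxels = voxels, spacing = spacing, subject_id = subject_id),
            class = "wmh_volume")
}

#' Construct a label map
#'
#' @param labels 3D integer array congruent with an image volume; values in
#'   \{0, 1, 2\} (0 background, 1 pvWMH, 2 dWMH).
#' @inheritParams wmh_volume
#' @return An object of class `wmh_labelmap`.
#' @export
wmh_labelmap <- function(labels, spacing, subject_id = "subject") {
  labels <- as_volume_array(labels)
  if (!all(labels %in% c(0, 1, 2)))
    stop("label values must be in {0, 1, 2}")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(labels = labels, spacing = spacing, subject_id = subject_id),
            class = "wmh_labelmap")
}

as_volume_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop("expected a 2D slice or 3D (rows x cols x slices) array")
  x
}

#' @export
print.wmh_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<wmh_volume> %s: %d x %d x %d slices, spacing %.3g x %.3g x %.3g mm\n",
              x$subject_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
print.wmh_labelmap <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<wmh_labelmap> %s: %d x %d x %d slices; pv %d px, d %d px\n",
              x$subject_id, d[1], d[2], d[3],
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads intensities and voxel spacing from the header. The slice axis is
#' taken to be the lowest-resolution (largest-spacing) axis and moved last.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param subject_id optional id; defaults to the file name stem.
#' @return A [wmh_volume].
#' @export
read_volume <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  vox <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vox)) == 2L) vox <- array(vox, dim = c(dim(vox), 1L))
  if (length(dim(vox)) != 3L) stop("expected a 2D or 3D NIfTI volume: ", path)
  spacing <- as.numeric(RNifti::pixdim(img))[seq_len(3)]
  spacing[is.na(spacing) | spacing <= 0] <- 1
  spacing <- signif(spacing, 6)   # headers store float32 spacings
  slice_axis <- which.max(spacing)
  if (slice_axis != 3L) {
    perm <- c(setdiff(1:3, slice_axis), slice_axis)
    vox <- aperm(vox, perm)
    spacing <- spacing[perm]
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  wmh_volume(vox, spacing, subject_id)
}

#' Read a NIfTI label map
#'
#' @inheritParams read_volume
#' @return A [wmh_labelmap].
#' @export
read_labelmap <- function(path, subject_id = NULL) {
  vol <- read_volume(path, subject_id)
  lab <- round(vol$voxels)
  if (max(abs(vol$voxels - lab)) > 1e-6)
    stop("label file contains non-integer values: ", path)
  wmh_labelmap(lab, vol$spacing, vol$subject_id)
}

#' Write a label map as integer NIfTI with a code sidecar
#'
#' Stores codes losslessly in an int16 NIfTI carrying the source geometry,
#' plus a JSON sidecar mapping codes to class names.
#'
#' @param labels a [wmh_labelmap].
#' @param path output `.nii` / `.nii.gz` path.
#' @param sidecar write the codes JSON next to the image (default TRUE).
#' @export
write_labelmap <- function(labels, path, sidecar = TRUE) {
  stopifnot(inherits(labels, "wmh_labelmap"))
  img <- RNifti::asNifti(labels$labels, reference = nifti_header(labels$spacing),
                         datatype = "int16")
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) stop("cannot write label map to '", path,
                                          "': ", conditionMessage(e)))
  if (sidecar) {
    sc <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
    jsonlite::write_json(as.list(LABEL_CODES), sc, auto_unbox = TRUE)
  }
  invisible(ok)
}

#' Write an image volume as NIfTI
#'
#' @param vol a [wmh_volume].
#' @param path output path.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "wmh_volume"))
  img <- RNifti::asNifti(vol$voxels, reference = nifti_header(vol$spacing),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(TRUE)
}

#' Z-score normalize a slice
#'
#' Standardizes a 2D slice to zero mean and unit (population) standard
#' deviation over all of its pixels. A constant slice maps to all zeros so
#' that downstream arithmetic never sees NaN.
#'
#' @param slice 2D numeric matrix with at least 2 pixels.
#' @return matrix of the same shape.
#' @export
zscore_normalize <- function(slice) {
  stopifnot(is.matrix(slice), length(slice) >= 2L)
  mu <- mean(slice)
  sdev <- sqrt(mean((slice - mu)^2))
  if (sdev == 0) return(array(0, dim = dim(slice)))
  (slice - mu) / sdev
}

#' Resample a 2D slice between grids
#'
#' Maps the acquisition grid (e.g. 256 x 256) to and from the delineation
#' grid (512 x 512). Intensity slices are resampled bilinearly; label slices
#' with nearest-neighbour so codes stay categorical. Pixel centres follow the
#' half-pixel convention, so an integer upscaling factor k replicates each
#' input pixel into a k x k block under nearest-neighbour, and the
#' up-then-down round trip is exact for label grids.
#'
#' @param slice 2D numeric matrix.
#' @param target_shape integer (rows, cols).
#' @param kind `"intensity"` (bilinear) or `"label"` (nearest-neighbour).
#' @return matrix of shape `target_shape`.
#' @export
resample_slice <- function(slice, target_shape, kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(slice))
  if (length(target_shape) != 2L || any(target_shape != round(target_shape)) ||
      any(target_shape < 1))
    stop("target_shape must be two positive integers")
  target_shape <- as.integer(target_shape)
  src <- dim(slice)
  if (all(src == target_shape)) return(slice)
  # source coordinate of each target pixel centre (1-based)
  coord <- function(n_out, n_in) (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
  ri <- coord(target_shape[1], src[1])
  ci <- coord(target_shape[2], src[2])
  if (kind == "label") {
    r <- pmin(pmax(floor(ri + 0.5), 1L), src[1])
    cc <- pmin(pmax(floor(ci + 0.5), 1L), src[2])
    out <- slice[r, cc, drop = FALSE]
    storage.mode(out) <- storage.mode(slice)
    return(out)
  }
  r0 <- pmin(pmax(floor(ri), 1L), src[1]); r1 <- pmin(r0 + 1L, src[1])
  c0 <- pmin(pmax(floor(ci), 1L), src[2]); c1 <- pmin(c0 + 1L, src[2])
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(ci - c0, 0), 1)
  a00 <- slice[r0, c0, drop = FALSE]; a01 <- slice[r0, c1, drop = FALSE]
  a10 <- slice[r1, c0, drop = FALSE]; a11 <- slice[r1, c1, drop = FALSE]
  wr <- matrix(fr, target_shape[1], target_shape[2])
  wc <- matrix(fc, target_shape[1], target_shape[2], byrow = TRUE)
  a00 * (1 - wr) * (1 - wc) + a01 * (1 - wr) * wc +
    a10 * wr * (1 - wc) + a11 * wr * wc
}

#' Resample every slice of a volume or label map
#'
#' Spacing is rescaled so physical extent (and hence lesion volume in ml) is
#' resolution-invariant: a 256 grid at 0.9 mm becomes a 512 grid at 0.45 mm.
#'
#' @param x a [wmh_volume] or [wmh_labelmap].
#' @param target_shape integer (rows, cols).
#' @return object of the same class on the new grid.
#' @export
resample_volume <- function(x, target_shape) {
  is_lab <- inherits(x, "wmh_labelmap")
  arr <- if (is_lab) x$labels else x$voxels
  d <- dim(arr)
  out <- array(if (is_lab) 0L else 0,
               dim = c(as.integer(target_shape), d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- resample_slice(arr[, , k], target_shape,
                                 kind = if (is_lab) "label" else "intensity")
  sp <- x$spacing
  sp_new <- c(sp[1] * d[1] / target_shape[1], sp[2] * d[2] / target_shape[2], sp[3])
  if (is_lab) wmh_labelmap(out, sp_new, x$subject_id)
  else wmh_volume(out, sp_new, x$subject_id)
}
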