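#' Segmentation metric suite
#'
#' Per-subject Dice similarity coefficient, Matthews correlation
#' coefficient, precision and recall from pooled pixel confusion counts,
#' lesion volumes in ml, ordinary-least-squares volume correlation, and
#' Fazekas-stratified summary tables. Metrics are computed per subject over
#' all of that subject's slices, then summarized as mean +/- SD across
#' subjects.
#'
#' Empty-mask conventions: when gold and prediction are both empty every
#' metric is 1 (the subject is handled perfectly); when gold is empty but
#' the prediction is not, DSC and precision are 0 while recall is 1
#' (there are no lesion pixels to miss).
#'
#' @name metrics_eval
NULL

#' Pixelwise confusion counts
#'
#' @param pred,gold congruent binary grids (any shape); all slices of a
#'   subject pooled.
#' @return list of class `confusion_counts` with TP, TN, FP, FN.
#' @export
confusion_counts <- function(pred, gold) {
  if (length(pred) != length(gold) ||
      (!is.null(dim(pred)) && !is.null(dim(gold)) && !all(dim(pred) == dim(gold))))
    stop("pred and gold must be congruent")
  p <- pred != 0; g <- gold != 0
  structure(list(TP = sum(p & g), TN = sum(!p & !g),
                 FP = sum(p & !g), FN = sum(!p & g)),
            class = "confusion_counts")
}

#' Dice similarity coefficient
#'
#' \eqn{DSC = 2|G \cap P| / (|G| + |P|)}; both masks empty gives 1 by
#' convention.
#'
#' @inheritParams confusion_counts
#' @return scalar in [0, 1].
#' @export
dsc <- function(pred, gold) {
  p <- pred != 0; g <- gold != 0
  denom <- sum(p) + sum(g)
  if (denom == 0) return(1)
  2 * sum(p & g) / denom
}

#' Matthews correlation coefficient
#'
#' \eqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#' Degenerate denominators (any zero factor) return 0, except perfect
#' agreement (FP = FN = 0) which returns 1 and perfect disagreement
#' (TP = TN = 0) which returns -1.
#'
#' @param c a [confusion_counts] object.
#' @return scalar in [-1, 1].
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  TP <- as.numeric(c$TP); TN <- as.numeric(c$TN)
  FP <- as.numeric(c$FP); FN <- as.numeric(c$FN)
  if (FP == 0 && FN == 0) return(1)
  if (TP == 0 && TN == 0) return(-1)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den)
}

#' Precision and recall
#'
#' `Recall = TP/(TP+FN)`, `Precision = TP/(TP+FP)`. When a subject has no
#' gold lesion pixels (TP+FN = 0) recall is 1; when nothing is predicted
#' (TP+FP = 0) precision is 1.
#'
#' @param c a [confusion_counts] object.
#' @return named numeric vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  precision <- if (c$TP + c$FP == 0) 1 else c$TP / (c$TP + c$FP)
  recall <- if (c$TP + c$FN == 0) 1 else c$TP / (c$TP + c$FN)
  c(precision = precision, recall = recall)
}

#' Lesion volume in ml
#'
#' Pixel count times voxel volume: in-plane spacing squared times slice
#' thickness, divided by 1000.
#'
#' @param labels a [wmh_labelmap] (or integer array with `spacing` given).
#' @param class_code 1 (pv), 2 (d) or `"wmh"` for the union \{1, 2\}.
#' @param spacing voxel spacing in mm; taken from `labels` if absent.
#' @return volume in ml.
#' @export
lesion_volume <- function(labels, class_code = "wmh", spacing = NULL) {
  if (inherits(labels, "wmh_labelmap")) {
    if (is.null(spacing)) spacing <- labels$spacing
    labels <- labels$labels
  }
  if (is.null(spacing)) stop("spacing is required to compute a volume")
  n <- if (identical(class_code, "wmh")) sum(labels %in% c(1L, 2L))
       else sum(labels == class_code)
  n * prod(spacing) / 1000
}

#' Volume correlation by ordinary least squares
#'
#' Regresses predicted volumes on gold-standard volumes and reports the
#' coefficient of determination, slope, intercept and the two-sided p-value
#' for zero slope.
#'
#' @param pred_volumes,gold_volumes per-subject volumes, length >= 3.
#' @return tibble with `r_squared`, `slope`, `intercept`, `p_value`, `n`.
#' @export
volume_correlation <- function(pred_volumes, gold_volumes) {
  stopifnot(length(pred_volumes) == length(gold_volumes),
            length(gold_volumes) >= 3)
  if (stats::var(gold_volumes) == 0)
    stop("gold volumes have zero variance; correlation undefined")
  fit <- stats::lm(pred_volumes ~ gold_volumes)
  s <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  tibble::tibble(r_squared = s$r.squared,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = unname(s$coefficients[2, 4]),
                 n = length(gold_volumes))
}

#' Per-subject metrics for one prediction/gold pair
#'
#' One row per lesion class (`wmh` = union, `pv`, `d`), each from the
#' subject's pooled pixel counts.
#'
#' @param pred,gold congruent integer label grids coded 0/1/2.
#' @param spacing voxel spacing (mm) for the volume columns.
#' @param subject_id id stored in the rows.
#' @return tibble with columns subject_id, class, dsc, mcc, precision,
#'   recall, pred_volume_ml, gold_volume_ml.
#' @export
subject_metrics <- function(pred, gold, spacing, subject_id = "subject") {
  if (inherits(pred, "wmh_labelmap")) pred <- pred$labels
  if (inherits(gold, "wmh_labelmap")) gold <- gold$labels
  stopifnot(all(dim(pred) == dim(gold)))
  one <- function(class) {
    pm <- if (class == "wmh") pred %in% c(1L, 2L) else pred == switch(class, pv = 1L, d = 2L)
    gm <- if (class == "wmh") gold %in% c(1L, 2L) else gold == switch(class, pv = 1L, d = 2L)
    cc <- confusion_counts(pm, gm)
    pr <- precision_recall(cc)
    vox_ml <- prod(spacing) / 1000
    tibble::tibble(subject_id = subject_id, class = class,
                   dsc = dsc(pm, gm), mcc = mcc(cc),
                   precision = pr[["precision"]], recall = pr[["recall"]],
                   pred_volume_ml = sum(pm) * vox_ml,
                   gold_volume_ml = sum(gm) * vox_ml)
  }
  do.call(rbind, lapply(c("wmh", "pv", "d"), one))
}

#' Fazekas-stratified summary report
#'
#' Mean +/- SD of every metric per lesion class, overall and stratified by
#' the class-matched Fazekas-like grade (pv rows stratified by pv grade, d
#' rows by d grade, wmh rows by total grade). Empty grade groups are
#' omitted.
#'
#' @param records per-subject metric rows from [subject_metrics()], bound
#'   together.
#' @param grades tibble/data.frame with subject_id, pv_grade, d_grade.
#' @return tibble with class, stratum, grade, n and mean/sd columns per
#'   metric.
#' @export
stratified_report <- function(records, grades) {
  stopifnot(all(c("subject_id", "class", "dsc") %in% names(records)),
            all(c("subject_id", "pv_grade", "d_grade") %in% names(grades)))
  df <- merge(as.data.frame(records), as.data.frame(grades), by = "subject_id")
  df$total_grade <- df$pv_grade + df$d_grade
  metric_cols <- c("dsc", "mcc", "precision", "recall")
  summarize_group <- function(sub, class, stratum, grade) {
    out <- tibble::tibble(class = class, stratum = stratum, grade = grade,
                          n = nrow(sub))
    for (m in metric_cols) {
      out[[paste0(m, "_mean")]] <- mean(sub[[m]])
      out[[paste0(m, "_sd")]] <- if (nrow(sub) > 1) stats::sd(sub[[m]]) else 0
    }
    out
  }
  rows <- list()
  for (cl in unique(df$class)) {
    sub_cl <- df[df$class == cl, ]
    rows[[length(rows) + 1L]] <- summarize_group(sub_cl, cl, "overall", NA_integer_)
    gcol <- switch(cl, pv = "pv_grade", d = "d_grade", "total_grade")
    for (g in sort(unique(sub_cl[[gcol]]))) {
      sub_g <- sub_cl[sub_cl[[gcol]] == g, ]
      if (nrow(sub_g) == 0) next
      rows[[length(rows) + 1L]] <- summarize_group(sub_g, cl, gcol, as.integer(g))
    }
  }
  do.call(rbind, rows)
}

#' Pairwise model comparison by exact rank-sum test
#'
#' Optional report column comparing per-subject DSC between two models with
#' a Wilcoxon rank-sum test (exact for small n).
#'
#' @param dsc_a,dsc_b per-subject DSC vectors for the two models.
#' @return two-sided p-value.
#' @export
compare_models_dsc <- function(dsc_a, dsc_b) {
  stats::wilcox.test(dsc_a, dsc_b, exact = length(dsc_a) <= 20 &&
                       length(dsc_b) <= 20)$p.value
}
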