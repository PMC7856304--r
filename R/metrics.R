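#' Dice overlap coefficient
#'
#' 2|X intersect Y| / (|X| + |Y|) for two binary masks.  Two empty masks
#' are defined to have Dice 1 (perfect agreement on the absence of the
#' structure).
#'
#' @param x,y binary masks (logical/0-1 vectors or arrays of equal size).
#' @return scalar in [0,1].
#' @export
diceScore <- function(x, y) {
  x <- as.logical(x)
  y <- as.logical(y)
  if (length(x) != length(y)) stop("mask shapes differ")
  denom <- sum(x) + sum(y)
  if (denom == 0L) return(1)
  2 * sum(x & y) / denom
}

#' Voxelwise precision and recall
#'
#' TP/(TP+FP) and TP/(TP+FN) of a predicted mask against a reference.
#' An empty denominator yields `NA` (excluded from aggregates).
#'
#' @param pred,ref binary masks of equal size.
#' @return named numeric vector `c(precision=, recall=)`.
#' @export
precisionRecall <- function(pred, ref) {
  pred <- as.logical(pred)
  ref <- as.logical(ref)
  if (length(pred) != length(ref)) stop("mask shapes differ")
  tp <- sum(pred & ref)
  fp <- sum(pred & !ref)
  fn <- sum(!pred & ref)
  c(precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
}

#' Mask volume in cubic millimetres
#'
#' Counts mask voxels and multiplies by the voxel volume.
#'
#' @param mask binary mask.
#' @param voxelSize numeric voxel edge lengths in mm (scalar or per-axis).
#' @return volume in mm^3 (mm^2 per unit thickness for 2-D grids).
#' @export
maskVolume <- function(mask, voxelSize = 1) {
  sum(as.logical(mask)) * prod(voxelSize)
}

#' Pearson correlation of volume estimates
#'
#' @param a,b numeric vectors of volumes (same length, >= 2).
#' @return Pearson correlation coefficient.
#' @export
pearsonVolumes <- function(a, b) {
  if (length(a) != length(b)) stop("volume vectors differ in length")
  stats::cor(a, b, method = "pearson")
}

#' Leave-one-out tuning of the lesion threshold
#'
#' For each held-out subject, selects the threshold that maximizes the
#' mean Dice overlap between thresholded posteriors and reference masks
#' over all remaining subjects (ties broken by the smallest threshold).
#'
#' @param posteriors list of per-subject voxelwise lesion posteriors.
#' @param refs list of per-subject reference binary masks.
#' @param grid numeric vector of candidate thresholds.
#' @return numeric vector of per-subject tuned thresholds.
#' @export
tuneThresholdLOO <- function(posteriors, refs, grid = seq(0.05, 0.95,
                                                          by = 0.05)) {
  n <- length(posteriors)
  if (n < 2L) stop("leave-one-out tuning needs at least 2 subjects")
  if (length(refs) != n) stop("one reference per subject required")
  diceTable <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n))
    for (g in seq_along(grid))
      diceTable[i, g] <- diceScore(posteriors[[i]] > grid[g], refs[[i]])
  vapply(seq_len(n), function(i) {
    avg <- colMeans(diceTable[-i, , drop = FALSE])
    grid[which.max(avg)]          # which.max takes the first (smallest)
  }, numeric(1))
}

#' Per-subject lesion evaluation report
#'
#' Dice, precision, recall and volumes of predicted versus reference
#' lesion masks, with subjects stratified by reference lesion load:
#' (0,2], (2,10] and (10,Inf) millilitres.
#'
#' @param preds,refs lists of binary lesion masks.
#' @param voxelSize voxel edge lengths in mm.
#' @return data.frame with one row per subject (dice, precision, recall,
#'   predVolume and refVolume in mm^3, lesion-load stratum).
#' @export
evaluateLesions <- function(preds, refs, voxelSize = 1) {
  if (length(preds) != length(refs)) stop("prediction/reference mismatch")
  rows <- lapply(seq_along(preds), function(i) {
    pr <- precisionRecall(preds[[i]], refs[[i]])
    refVol <- maskVolume(refs[[i]], voxelSize)
    ml <- refVol / 1000
    stratum <- if (ml <= 2) "(0,2]" else if (ml <= 10) "(2,10]"
               else "(10,Inf)"
    data.frame(subject = i, dice = diceScore(preds[[i]], refs[[i]]),
               precision = pr[["precision"]], recall = pr[["recall"]],
               predVolume = maskVolume(preds[[i]], voxelSize),
               refVolume = refVol, stratum = stratum)
  })
  do.call(rbind, rows)
}
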