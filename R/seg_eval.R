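#' Voxel-overlap metrics between predicted and ground-truth masks
#'
#' Whole-image precision, recall and Dice: with `TP = |pred & truth|`,
#' precision is `TP/|pred|`, recall `TP/|truth|`, overall Dice
#' `2 TP / (|pred| + |truth|)`. Metrics whose denominator is zero are
#' returned as `NA` (missing, not 0); two empty masks yield all `NA`.
#'
#' @param pred,truth binary `voxel_grid`s on one grid.
#' @return List with `precision`, `recall`, `overall_dice`.
#' @export
overlap_metrics <- function(pred, truth) {
  assert_binary_grid(pred, "pred"); assert_binary_grid(truth, "truth")
  rep <- check_geometry(list(pred, truth))
  if (!rep$pass) stop(rep$message, call. = FALSE)
  np <- sum(pred$values); nt <- sum(truth$values)
  tp <- sum(pred$values == 1L & truth$values == 1L)
  list(precision = if (np > 0) tp / np else NA_real_,
       recall = if (nt > 0) tp / nt else NA_real_,
       overall_dice = if (np + nt > 0) 2 * tp / (np + nt) else NA_real_)
}

#' Per-lesion (voxel-wise) Dice
#'
#' For each ground-truth lesion L, Dice is computed between L and the
#' union P_L of all predicted components that overlap L,
#' `2|P_L & L| / (|P_L| + |L|)`; lesions with no overlapping prediction
#' contribute 0. The returned score is the mean over truth lesions.
#'
#' @param pred,truth binary `voxel_grid`s; `truth` must be nonempty.
#' @param connectivity component connectivity (default 26).
#' @return Mean per-lesion Dice in \[0, 1\].
#' @export
voxelwise_dice <- function(pred, truth, connectivity = 26) {
  cct <- connected_components(truth, connectivity)
  if (cct$n == 0L) stop("truth mask has no lesions", call. = FALSE)
  ccp <- connected_components(pred, connectivity)
  tl <- cct$labels; pl <- ccp$labels
  pred_sizes <- ccp$components$voxel_count
  scores <- numeric(cct$n)
  for (t in seq_len(cct$n)) {
    in_t <- tl == t
    plab <- unique(pl[in_t & pl > 0L])
    if (!length(plab)) { scores[t] <- 0; next }
    p_union <- sum(pred_sizes[plab])
    inter <- sum(pl[in_t] %in% plab)
    scores[t] <- 2 * inter / (p_union + sum(in_t))
  }
  mean(scores)
}

#' Lesion-wise Dice
#'
#' Counts lesions rather than voxels: a truth lesion is a true positive
#' if the prediction segments at least one of its voxels; a predicted
#' component overlapping no truth lesion is a false positive; a truth
#' lesion with no overlap is a false negative. Returns
#' `2 TP / (2 TP + FP + FN)`.
#'
#' @inheritParams voxelwise_dice
#' @return Lesion-count Dice in \[0, 1\].
#' @export
lesionwise_dice <- function(pred, truth, connectivity = 26) {
  cct <- connected_components(truth, connectivity)
  ccp <- connected_components(pred, connectivity)
  if (cct$n == 0L && ccp$n == 0L)
    stop("both masks are empty", call. = FALSE)
  tl <- cct$labels; pl <- ccp$labels
  overlap <- pl > 0L & tl > 0L
  tp_truth <- unique(tl[overlap])
  fp <- length(setdiff(seq_len(ccp$n), unique(pl[overlap])))
  tp <- length(tp_truth)
  fn <- cct$n - tp
  2 * tp / (2 * tp + fp + fn)
}

#' Rank and concordance agreement between paired measurements
#'
#' Spearman's rho (Pearson correlation of average ranks) and Lin's
#' concordance correlation coefficient,
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`
#' with population (1/n) moments, which penalizes location and scale
#' disagreement as well as imperfect correlation.
#'
#' @param pred_values,truth_values paired numeric vectors, length >= 3.
#' @return List with `spearman_rho` (`NA` if either input is constant)
#'   and `lin_ccc`.
#' @export
agreement_stats <- function(pred_values, truth_values) {
  if (length(pred_values) != length(truth_values))
    stop("length mismatch", call. = FALSE)
  n <- length(pred_values)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  rho <- if (sd(pred_values) == 0 || sd(truth_values) == 0) NA_real_
    else cor(rank(pred_values), rank(truth_values))
  mx <- mean(pred_values); my <- mean(truth_values)
  vx <- mean((pred_values - mx)^2)
  vy <- mean((truth_values - my)^2)
  cxy <- mean((pred_values - mx) * (truth_values - my))
  list(spearman_rho = rho,
       lin_ccc = 2 * cxy / (vx + vy + (mx - my)^2))
}

#' Full segmentation-agreement report for paired mask lists
#'
#' Computes all overlap metrics per subject plus cohort-level count and
#' volume agreement between predicted and ground-truth segmentations.
#'
#' @param pred_masks,truth_masks lists of binary `voxel_grid`s, paired.
#' @param connectivity component connectivity.
#' @return List with `per_subject` (data.frame of precision, recall and
#'   the three Dice variants plus component counts/volumes) and
#'   `agreement` (count and volume Spearman rho and Lin's CCC).
#' @export
evaluate_segmentation <- function(pred_masks, truth_masks,
                                  connectivity = 26) {
  stopifnot(length(pred_masks) == length(truth_masks),
            length(pred_masks) >= 1L)
  n <- length(pred_masks)
  per <- data.frame(precision = numeric(n), recall = numeric(n),
                    overall_dice = numeric(n), voxelwise_dice = numeric(n),
                    lesionwise_dice = numeric(n),
                    n_pred_lesions = integer(n), n_truth_lesions = integer(n),
                    pred_volume_mm3 = numeric(n), truth_volume_mm3 = numeric(n))
  for (i in seq_len(n)) {
    p <- pred_masks[[i]]; t <- truth_masks[[i]]
    om <- overlap_metrics(p, t)
    per$precision[i] <- om$precision
    per$recall[i] <- om$recall
    per$overall_dice[i] <- om$overall_dice
    per$voxelwise_dice[i] <- voxelwise_dice(p, t, connectivity)
    per$lesionwise_dice[i] <- lesionwise_dice(p, t, connectivity)
    per$n_pred_lesions[i] <- connected_components(p, connectivity)$n
    per$n_truth_lesions[i] <- connected_components(t, connectivity)$n
    per$pred_volume_mm3[i] <- mask_volume_mm3(p)
    per$truth_volume_mm3[i] <- mask_volume_mm3(t)
  }
  agreement <- if (n >= 3L) {
    cnt <- agreement_stats(per$n_pred_lesions, per$n_truth_lesions)
    vol <- agreement_stats(per$pred_volume_mm3, per$truth_volume_mm3)
    data.frame(measure = c("count", "volume"),
               spearman_rho = c(cnt$spearman_rho, vol$spearman_rho),
               lin_ccc = c(cnt$lin_ccc, vol$lin_ccc))
  } else NULL
  list(per_subject = per, agreement = agreement)
}
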