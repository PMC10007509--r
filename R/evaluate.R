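# Evaluation protocol: reconstruction RMSE, pixel-overlap metrics
# (Dice / TPR / FPR), threshold sweeps, lesion-size stratification and
# cross-model comparison.

#' Root-mean-square reconstruction error
#'
#' `sqrt(mean((xhat - x)^2))`. Low values on normal images indicate good
#' reconstruction; high values on abnormal images indicate the model could
#' not reproduce the anomalous content - the regime that makes
#' reconstruction error usable as an anomaly score.
#'
#' @param x,xhat input image and reconstruction, same shape.
#' @return Non-negative scalar.
#' @export
rmse <- function(x, xhat) {
  check_same_shape(x, xhat, "x", "xhat")
  sqrt(mean((xhat - x)^2))
}

#' Mean reconstruction RMSE of a model over an image set
#'
#' Reconstructs every image in evaluation mode and returns the macro
#' average (mean of per-image RMSE). The pooled-pixel (micro) RMSE and the
#' per-image values are attached as attributes `"micro"` and `"per_image"`.
#'
#' @param object fitted [anomaly_autoencoder()].
#' @param images nonempty list of images (test items
#'   `list(image, mask, ...)` are accepted).
#' @return Scalar macro-average RMSE.
#' @export
dataset_rmse <- function(object, images) {
  stopifnot(inherits(object, "anomaly_autoencoder"))
  if (!is.list(images) || length(images) < 1)
    stop_invalid("images must be a nonempty list")
  images <- lapply(images, function(im) if (is.list(im)) im$image else im)
  recon <- predict(object, images, type = "reconstruction")
  per <- mapply(rmse, images, recon)
  sq <- mapply(function(x, xh) sum((xh - x)^2), images, recon)
  structure(mean(per),
            per_image = per,
            micro = sqrt(sum(sq) / sum(vapply(images, length, 0))))
}

#' Pixel confusion counts between predicted and true masks
#'
#' @param pred,truth binary masks of identical shape.
#' @return Named integer vector `c(TP, FP, FN, TN)` summing to the pixel
#'   count.
#' @export
confusion_counts <- function(pred, truth) {
  check_mask(pred, "pred"); check_mask(truth, "truth")
  check_same_shape(pred, truth, "pred", "truth")
  p <- as.numeric(pred); t <- as.numeric(truth)
  c(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
    FN = sum(p == 0 & t == 1), TN = sum(p == 0 & t == 0))
}

#' Overlap metrics from confusion counts
#'
#' `dice = 2TP / (2TP + FN + FP)`, `tpr = TP / (TP + FN)`,
#' `fpr = FP / (FP + TN)`. Degenerate denominators follow fixed
#' conventions: when prediction and truth are both empty the masks agree
#' perfectly, so `dice = 1` (and `fpr = 0` falls out of the formula); `tpr`
#' is `NA` whenever the truth is empty, and `fpr` is `NA` in the (all-ones
#' truth) case `FP + TN = 0`. `NA` values are excluded from averages
#' downstream.
#'
#' @param counts named vector from [confusion_counts()] (or any vector
#'   with elements `TP`, `FP`, `FN`, `TN`).
#' @return `list(dice =, tpr =, fpr =)`.
#' @export
overlap_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  if (any(c(tp, fp, fn, tn) < 0)) stop_invalid("counts must be non-negative")
  list(
    dice = if (2 * tp + fn + fp == 0) 1 else 2 * tp / (2 * tp + fn + fp),
    tpr = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    fpr = if (fp + tn == 0) NA_real_ else fp / (fp + tn))
}

# per-image metric records of a model on a lesioned test set at one
# threshold, given precomputed anomaly maps
records_from_maps <- function(maps, truths, areas, threshold) {
  rows <- lapply(seq_along(maps), function(i) {
    cc <- confusion_counts(binarize(maps[[i]], threshold), truths[[i]])
    m <- overlap_metrics(cc)
    data.frame(id = i, dice = m$dice, tpr = m$tpr, fpr = m$fpr,
               TP = cc[["TP"]], FP = cc[["FP"]], FN = cc[["FN"]],
               TN = cc[["TN"]],
               lesion_area_px = areas[i], threshold = as.numeric(threshold))
  })
  do.call(rbind, rows)
}

#' Per-image overlap metrics of a model on a lesioned test set
#'
#' @param object fitted [anomaly_autoencoder()].
#' @param testset list of `list(image, mask, ...)` items (as produced in
#'   the `test` split of [generate_dataset()]).
#' @param threshold binarization threshold.
#' @return Data frame with one row per image: `dice`, `tpr`, `fpr`, the
#'   raw confusion counts, `lesion_area_px` and the threshold used.
#' @export
metric_records <- function(object, testset, threshold = object$threshold) {
  if (!is.list(testset) || length(testset) < 1)
    stop_invalid("testset must be a nonempty list")
  if (is.null(threshold)) stop_invalid("threshold required")
  maps <- predict(object, lapply(testset, `[[`, "image"), type = "anomaly")
  truths <- lapply(testset, `[[`, "mask")
  areas <- vapply(truths, sum, 0)
  records_from_maps(maps, truths, areas, threshold)
}

mean_defined <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)

sweep_from_maps <- function(maps, truths, areas, thresholds, model = NA) {
  thresholds <- sort(as.numeric(thresholds))
  rows <- lapply(thresholds, function(th) {
    rec <- records_from_maps(maps, truths, areas, th)
    data.frame(model = model, threshold = th,
               dice = mean_defined(rec$dice), tpr = mean_defined(rec$tpr),
               fpr = mean_defined(rec$fpr),
               dice_micro = overlap_metrics(c(TP = sum(rec$TP), FP = sum(rec$FP),
                                              FN = sum(rec$FN), TN = sum(rec$TN)))$dice,
               tpr_micro = sum(rec$TP) / max(1, sum(rec$TP) + sum(rec$FN)),
               fpr_micro = sum(rec$FP) / max(1, sum(rec$FP) + sum(rec$TN)))
  })
  do.call(rbind, rows)
}

#' Overlap metrics across a grid of thresholds
#'
#' Computes each test image's anomaly map once, then binarizes at every
#' threshold and averages Dice/TPR/FPR over images (macro mean over
#' defined values; pooled micro variants alongside). Because raising the
#' threshold can only shrink predicted masks, mean TPR and FPR are
#' non-increasing in the threshold.
#'
#' @param object fitted [anomaly_autoencoder()].
#' @param testset list of `list(image, mask, ...)` items.
#' @param thresholds numeric thresholds; the conventional sweep grid is
#'   `c(0.1, 0.2, 0.3)`.
#' @return Data frame sorted by ascending threshold with columns `model`,
#'   `threshold`, `dice`, `tpr`, `fpr` and micro counterparts.
#' @export
threshold_sweep <- function(object, testset, thresholds = c(0.1, 0.2, 0.3)) {
  stopifnot(inherits(object, "anomaly_autoencoder"))
  if (length(thresholds) < 1) stop_invalid("thresholds must be nonempty")
  if (!is.list(testset) || length(testset) < 1)
    stop_invalid("testset must be a nonempty list")
  maps <- predict(object, lapply(testset, `[[`, "image"), type = "anomaly")
  truths <- lapply(testset, `[[`, "mask")
  areas <- vapply(truths, sum, 0)
  sweep_from_maps(maps, truths, areas, thresholds, model = object$kind)
}

#' Overlap metrics stratified by lesion size
#'
#' Bins the per-image records into lesion-area quantile ranges and reports
#' per-bin means, to examine how detectability varies with tumor size.
#' Quantile bins keep every bin populated regardless of the area
#' distribution; when fewer distinct quantiles than `n_bins` exist, bins
#' are merged with a warning.
#'
#' @param records data frame from [metric_records()].
#' @param n_bins number of quantile bins (>= 1; default 5).
#' @return Data frame with one row per bin: `size_range`, `area_min`,
#'   `area_max`, `mean_dice`, `mean_tpr`, `n`. Bin counts sum to
#'   `nrow(records)`.
#' @export
size_stratified_metrics <- function(records, n_bins = 5) {
  if (!is.data.frame(records) || nrow(records) < 1)
    stop_invalid("records must be a nonempty data frame")
  if (n_bins < 1) stop_invalid("n_bins must be >= 1")
  a <- records$lesion_area_px
  br <- unique(quantile(a, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) - 1 < n_bins && n_bins > 1)
    warning("fewer distinct lesion areas than bins; bins merged")
  if (length(br) == 1) br <- c(br - 0.5, br + 0.5)
  bin <- cut(a, breaks = br, include.lowest = TRUE)
  # interpolated quantiles can produce empty ranges; drop them (the
  # remaining counts still partition the records)
  keep <- levels(bin)[tabulate(bin, nbins = nlevels(bin)) > 0]
  rows <- lapply(keep, function(lv) {
    r <- records[bin == lv, ]
    data.frame(size_range = lv,
               area_min = min(r$lesion_area_px),
               area_max = max(r$lesion_area_px),
               mean_dice = mean_defined(r$dice),
               mean_tpr = mean_defined(r$tpr),
               n = nrow(r))
  })
  do.call(rbind, rows)
}

#' Compare fitted models on one dataset
#'
#' The cross-model report: for every fitted model, the normal-validation
#' and abnormal-test reconstruction RMSE, the ReLU-max validation
#' threshold, and Dice/TPR/FPR (macro and micro) at each fixed threshold
#' plus the ReLU-max one.
#'
#' @param fits named list of fitted [anomaly_autoencoder()] objects.
#' @param dataset a `split_dataset` with `val` and `test` splits.
#' @param thresholds fixed thresholds to evaluate (besides ReLU-max).
#' @param include_relu_max also evaluate each model's own validation-set
#'   ReLU-max threshold.
#' @return Data frame with one row per model x threshold; columns `model`,
#'   `threshold_source`, `threshold`, `val_rmse`, `test_rmse`, `relu_max`,
#'   `dice`, `tpr`, `fpr` and micro variants.
#' @export
compare_models <- function(fits, dataset, thresholds = c(0.1, 0.2, 0.3),
                           include_relu_max = TRUE) {
  if (inherits(fits, "anomaly_autoencoder")) fits <- list(fits)
  if (length(fits) < 1) stop_invalid("need at least one fitted model")
  stopifnot(inherits(dataset, "split_dataset"))
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, `[[`, "", "kind")

  out <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    val_maps <- predict(fit, dataset$val, type = "anomaly")
    relu_max <- as.numeric(find_threshold(val_maps))
    v_rmse <- as.numeric(dataset_rmse(fit, dataset$val))
    t_rmse <- as.numeric(dataset_rmse(fit, dataset$test))
    maps <- predict(fit, lapply(dataset$test, `[[`, "image"), type = "anomaly")
    truths <- lapply(dataset$test, `[[`, "mask")
    areas <- vapply(truths, sum, 0)
    th <- sort(as.numeric(thresholds))
    src <- rep("fixed", length(th))
    if (include_relu_max) { th <- c(th, relu_max); src <- c(src, "relu_max") }
    sw <- sweep_from_maps(maps, truths, areas, th, model = nm)
    # sweep sorts by threshold; re-attach sources by value
    sw$threshold_source <- src[match(sw$threshold, th)]
    sw$val_rmse <- v_rmse
    sw$test_rmse <- t_rmse
    sw$relu_max <- relu_max
    sw
  })
  res <- do.call(rbind, out)
  res[, c("model", "threshold_source", "threshold", "val_rmse", "test_rmse",
          "relu_max", "dice", "tpr", "fpr",
          "dice_micro", "tpr_micro", "fpr_micro")]
}
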