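# From trained model to pixel-level detector: anomaly maps, threshold
# selection on normal validation images, binarization.

#' Pixel-wise anomaly map
#'
#' Per-pixel absolute difference between an input image and its
#' reconstruction; regions the model could not reconstruct light up.
#' 3-channel inputs are reduced by the per-pixel mean of the channel
#' absolute differences, so the map is always a single \[0, 1\] plane that
#' matches single-channel behavior on replicated channels.
#'
#' @param x,xhat image and reconstruction, same shape, values in \[0, 1\].
#' @return `H x W` numeric matrix in \[0, 1\]. Symmetric in its arguments.
#' @export
anomaly_map <- function(x, xhat) {
  check_image(x, "x"); check_image(xhat, "xhat")
  check_same_shape(x, xhat, "x", "xhat")
  collapse_channels(abs(x - xhat))
}

#' Select the binarization threshold from normal validation anomaly maps
#'
#' The ReLU-max rule: compute the average anomaly map over the validation
#' set, rectify each map's excess over that average (`ReLU(map - average)`),
#' and return the maximum rectified excess over all maps and pixels. Any
#' test-map pixel exceeding this threshold deviates from its reconstruction
#' more than any normal validation pixel deviated from the validation
#' average, so the rule is a conservative, data-driven choice. Because it
#' tends to come out large (anomalies below it pass as normal), fixed
#' thresholds such as 0.1, 0.2, 0.3 are commonly swept alongside it; see
#' [threshold_sweep()].
#'
#' @param maps list of validation anomaly maps (equal-size matrices), or a
#'   3-D array with maps along the third dimension.
#' @param average `"pixelwise"` (default) measures each map against the
#'   per-pixel mean map; `"scalar"` against the single grand-mean value of
#'   all validation maps.
#' @return Threshold value (>= 0) with attribute `source = "relu_max"`.
#' @examples
#' find_threshold(list(matrix(c(0.1, 0.3), 1), matrix(c(0.5, 0.1), 1)))  # 0.2
#' @export
find_threshold <- function(maps, average = c("pixelwise", "scalar")) {
  average <- match.arg(average)
  if (is.array(maps) && length(dim(maps)) == 3)
    maps <- lapply(seq_len(dim(maps)[3]), function(i) maps[, , i])
  if (!is.list(maps) || length(maps) < 1)
    stop_invalid("maps must be a nonempty list of anomaly maps")
  d <- dim(maps[[1]])
  for (m in maps) {
    if (!is.matrix(m) || !identical(dim(m), d))
      stop_invalid("all anomaly maps must be matrices of identical size")
    if (any(!is.finite(m)) || min(m) < 0)
      stop_invalid("anomaly maps must be finite and non-negative")
  }
  avg <- if (average == "pixelwise")
    Reduce(`+`, maps) / length(maps)
  else
    mean(vapply(maps, mean, 0))
  mx <- 0
  for (m in maps) mx <- max(mx, pmax(m - avg, 0))
  structure(mx, source = "relu_max", average = average)
}

#' Binarize an anomaly map
#'
#' A pixel is flagged anomalous iff its map value is strictly larger than
#' the threshold.
#'
#' @param map anomaly map (non-negative matrix).
#' @param threshold threshold value (>= 0).
#' @return Binary integer matrix (predicted ROI mask).
#' @export
binarize <- function(map, threshold) {
  if (!is.matrix(map) || any(!is.finite(map)) || min(map) < 0)
    stop_invalid("map must be a finite non-negative matrix")
  threshold <- as.numeric(threshold)
  if (length(threshold) != 1 || threshold < 0)
    stop_invalid("threshold must be a single value >= 0")
  matrix(as.integer(map > threshold), nrow(map), ncol(map))
}

#' Detect the anomalous region of an image
#'
#' Runs the full inference chain of a trained model on one image:
#' reconstruct, form the anomaly map, binarize. Inference is deterministic;
#' the variational model uses its posterior mean (no sampling).
#'
#' @param object a fitted [anomaly_autoencoder()].
#' @param x image in \[0, 1\] matching the trained input size.
#' @param threshold binarization threshold; defaults to the fit's stored
#'   validation threshold.
#' @return `list(reconstruction =, map =, mask =)`.
#' @export
detect <- function(object, x, threshold = object$threshold) {
  stopifnot(inherits(object, "anomaly_autoencoder"))
  if (is.null(threshold))
    stop_invalid("no threshold given and none stored on the fit")
  xhat <- predict(object, x, type = "reconstruction")
  map <- anomaly_map(x, xhat)
  list(reconstruction = xhat, map = map,
       mask = binarize(map, threshold))
}
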