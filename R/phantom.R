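# Synthetic ultrasound-phantom generator: speckled tissue-like backgrounds,
# hypoechoic elliptical lesions with ground-truth masks, and the image
# preprocessing chain (0-255 normalization, Gaussian denoising, gamma
# correction) applied to real scans.

#' Generate a smooth tissue-like background field
#'
#' Produces a low-frequency intensity field emulating the large-scale
#' echogenicity variation of soft tissue, before speckle is applied. White
#' noise is smoothed with a Gaussian kernel of scale `smoothness` and
#' rescaled linearly to the range \[0.2, 0.8\], leaving headroom for
#' multiplicative speckle and dark lesions on either side.
#'
#' @param height,width image dimensions in pixels (>= 8).
#' @param seed integer seed; identical seeds give bit-identical fields.
#' @param smoothness Gaussian smoothing scale in pixels (> 0); larger values
#'   give flatter, more homogeneous tissue.
#' @return A `height` x `width` numeric matrix with values in \[0.2, 0.8\].
#' @examples
#' bg <- generate_background(64, 64, seed = 1)
#' range(bg)
#' @export
generate_background <- function(height, width, seed = 1, smoothness = 8) {
  if (!is.numeric(height) || !is.numeric(width) || height < 8 || width < 8)
    stop_invalid("height and width must be >= 8")
  if (smoothness <= 0) stop_invalid("smoothness must be positive")
  noise <- with_seed(seed, matrix(runif(height * width), height, width))
  f <- gaussian_denoise(noise, smoothness)
  rng <- range(f)
  if (rng[2] - rng[1] < .Machine$double.eps) return(matrix(0.5, height, width))
  0.2 + 0.6 * (f - rng[1]) / (rng[2] - rng[1])
}

#' Apply multiplicative ultrasound speckle
#'
#' First-order speckle surrogate: each pixel is multiplied by a unit-mean
#' factor `(1 - scale) + scale * R` where `R` is Rayleigh-distributed with
#' mean 1 (Rayleigh scale `sqrt(2/pi)`), then clipped to \[0, 1\]. Before
#' clipping the expected value of every pixel equals its input value, so
#' speckle adds granularity without changing mean echogenicity.
#'
#' @param img an image in \[0, 1\].
#' @param seed integer seed.
#' @param scale mixing weight in (0, 1\]; `scale -> 0` recovers the input.
#' @return Image of the same shape, values in \[0, 1\].
#' @export
apply_speckle <- function(img, seed = 1, scale = 0.3) {
  check_image(img)
  if (!is.numeric(scale) || scale <= 0)
    stop_invalid("scale must be positive")
  n <- length(img)
  fac <- with_seed(seed, {
    r <- sqrt(2 / pi) * sqrt(-2 * log(runif(n)))
    (1 - scale) + scale * r
  })
  out <- clip01(img * array(fac, dim = dim(img)))
  out
}

#' Specify an elliptical hypoechoic lesion
#'
#' @param center numeric `(row, col)` center in pixels.
#' @param semi_axes numeric `(a, b)` semi-axes in pixels.
#' @param rotation rotation of the `a` axis in radians.
#' @param intensity_drop fraction in (0, 1\] by which intensity inside the
#'   lesion is reduced (pixel <- pixel * (1 - intensity_drop)); hypoechoic
#'   masses appear darker than surrounding tissue. 0 is allowed and yields
#'   a visible-mask, zero-effect lesion.
#' @param edge_softness Gaussian blur scale (pixels) applied to the lesion
#'   boundary; 0 gives a hard edge.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, semi_axes, rotation = 0,
                        intensity_drop = 0.5, edge_softness = 0) {
  stopifnot(length(center) == 2, length(semi_axes) == 2)
  if (any(semi_axes <= 0)) stop_invalid("semi_axes must be positive")
  if (intensity_drop < 0 || intensity_drop > 1)
    stop_invalid("intensity_drop must be in [0, 1]")
  if (edge_softness < 0) stop_invalid("edge_softness must be >= 0")
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation),
                 intensity_drop = as.numeric(intensity_drop),
                 edge_softness = as.numeric(edge_softness)),
            class = "lesion_spec")
}

# axis-aligned half-extents of a rotated ellipse
ellipse_extent <- function(spec) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; th <- spec$rotation
  c(row = sqrt((a * sin(th))^2 + (b * cos(th))^2),
    col = sqrt((a * cos(th))^2 + (b * sin(th))^2))
}

#' Insert a hypoechoic lesion into an image
#'
#' Darkens the interior of the (optionally edge-softened) ellipse
#' multiplicatively: `pixel <- pixel * (1 - intensity_drop * w)` where `w`
#' is 1 inside the hard ellipse and, for `edge_softness > 0`, a Gaussian
#' blur of that indicator. The returned ground-truth mask always marks the
#' hard ellipse interior. The operation is deterministic; `seed` is
#' accepted for interface symmetry with the other generators and ignored.
#'
#' @param img an image in \[0, 1\].
#' @param spec a [lesion_spec()].
#' @param seed ignored (reserved).
#' @return `list(image =, mask =)`: the lesioned image and the binary
#'   integer ROI mask.
#' @examples
#' les <- insert_lesion(matrix(0.6, 64, 64),
#'                      lesion_spec(c(32, 32), c(10, 10), intensity_drop = 0.5))
#' sum(les$mask)
#' @export
insert_lesion <- function(img, spec, seed = NULL) {
  check_image(img)
  stopifnot(inherits(spec, "lesion_spec"))
  h <- dim(img)[1]; w <- dim(img)[2]
  ext <- ellipse_extent(spec)
  if (spec$center[1] - ext["row"] < 1 || spec$center[1] + ext["row"] > h ||
      spec$center[2] - ext["col"] < 1 || spec$center[2] + ext["col"] > w)
    stop_invalid("ellipse exceeds image bounds")

  rr <- matrix(seq_len(h), h, w) - spec$center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - spec$center[2]
  ct <- cos(spec$rotation); st <- sin(spec$rotation)
  u <- (ct * cc + st * rr) / spec$semi_axes[1]
  v <- (-st * cc + ct * rr) / spec$semi_axes[2]
  mask <- matrix(as.integer(u^2 + v^2 <= 1), h, w)
  if (sum(mask) < 1) stop_invalid("lesion mask is empty; enlarge semi_axes")

  wgt <- if (spec$edge_softness > 0)
    gaussian_denoise(mask + 0, spec$edge_softness) else mask + 0
  shade <- 1 - spec$intensity_drop * wgt
  out <- if (is.matrix(img)) img * shade else {
    o <- img
    for (c in seq_len(dim(img)[3])) o[, , c] <- img[, , c] * shade
    o
  }
  list(image = out, mask = mask)
}

#' Rescale 8-bit pixel values to the unit interval
#'
#' @param raw numeric matrix/array with values in \[0, 255\].
#' @return The same shape divided by 255.
#' @export
normalize_pixels <- function(raw) {
  if (!is.numeric(raw)) stop_invalid("raw must be numeric")
  if (any(!is.finite(raw)) || min(raw) < 0 || max(raw) > 255)
    stop_invalid("raw values must lie in [0, 255]")
  raw / 255
}

#' Gaussian denoising with reflective boundary handling
#'
#' Separable Gaussian convolution truncated at radius `ceiling(3 * sigma)`,
#' with mirror (symmetric) padding at the borders so that smoothing neither
#' darkens the frame nor leaks intensity out of the image.
#'
#' @param img an image in \[0, 1\] (or any numeric matrix/array).
#' @param sigma kernel standard deviation in pixels; 0 is the identity.
#' @return Smoothed image, same shape.
#' @export
gaussian_denoise <- function(img, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop_invalid("sigma must be a non-negative number")
  if (!is.numeric(img) || !(is.matrix(img) || is.array(img)))
    stop_invalid("img must be a numeric matrix or array")
  if (sigma == 0) return(img)
  if (!is.matrix(img)) {
    out <- img
    for (c in seq_len(dim(img)[3])) out[, , c] <- gaussian_denoise(img[, , c], sigma)
    return(out)
  }
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  img <- conv_sep_1d(img, k, r)         # along rows
  t(conv_sep_1d(t(img), k, r))          # along columns
}

# 1-D convolution down the rows of m with mirror (symmetric) padding;
# out-of-range row i maps to its reflection about the nearest border.
conv_sep_1d <- function(m, k, r) {
  n <- nrow(m)
  reflect <- function(i) {
    j <- (i - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  idx <- reflect(seq.int(1L - r, n + r))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * mp[seq_len(n) + (j - 1L), , drop = FALSE]
  out
}

#' Gamma correction
#'
#' Per-pixel power transform `out = in^gamma`. The augmentation protocol
#' uses gamma values 0.5 (brightens dark regions, bringing out detail in
#' hypoechoic areas) and 1.5 (darkens) on training images.
#'
#' @param img an image in \[0, 1\].
#' @param gamma positive exponent.
#' @return Corrected image, same shape, in \[0, 1\].
#' @export
gamma_correct <- function(img, gamma) {
  check_image(img)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop_invalid("gamma must be positive")
  img^gamma
}

#' Append gamma-corrected copies of a training set
#'
#' @param images list of images in \[0, 1\].
#' @param gammas gamma values for the appended copies.
#' @return List of the originals followed by one corrected copy per gamma.
#' @export
augment_gamma <- function(images, gammas = c(0.5, 1.5)) {
  stopifnot(is.list(images))
  out <- images
  for (g in gammas) out <- c(out, lapply(images, gamma_correct, gamma = g))
  out
}

#' Generate a synthetic normal/abnormal ultrasound dataset
#'
#' Builds the three splits used by reconstruction-based anomaly detection:
#' normal images for training, normal images for validation (threshold
#' selection), and abnormal test images each carrying exactly one
#' hypoechoic elliptical lesion with its ground-truth ROI mask. Every image
#' is an independent smooth background with multiplicative speckle; lesions
#' are darkened ellipses inserted before speckling, with pixel area drawn
#' uniformly from `lesion_area`, intensity drop uniform in `lesion_drop`,
#' aspect ratio uniform in `lesion_aspect` and uniform random orientation
#' and (feasible) position. The default split sizes mirror a clinical
#' breast-ultrasound study design (853/94 normal, 200 abnormal); the
#' default image grid is a desk-scale 64 x 64 single channel.
#'
#' @param n_train,n_val,n_test split sizes (all >= 1).
#' @param height,width,channels image geometry; `channels` 1 or 3
#'   (3 replicates the grayscale plane).
#' @param lesion_area `(min, max)` lesion area range in pixels.
#' @param lesion_drop `(min, max)` intensity-drop range in (0, 1\].
#' @param lesion_aspect `(min, max)` semi-axis ratio range in (0, 1\].
#' @param lesion_softness lesion edge blur scale in pixels.
#' @param speckle_scale speckle mixing weight, see [apply_speckle()].
#' @param smoothness background smoothing scale, see [generate_background()].
#' @param seed global seed; the full dataset is a deterministic function of
#'   the configuration and this seed.
#' @return A `split_dataset`: list with `train`, `val` (lists of images),
#'   `test` (list of `list(image, mask, area_px)`), and the resolved
#'   configuration.
#' @examples
#' ds <- generate_dataset(5, 2, 3, height = 32, width = 32, seed = 1)
#' length(ds$train); ds$test[[1]]$area_px
#' @export
generate_dataset <- function(n_train = 853, n_val = 94, n_test = 200,
                             height = 64, width = 64, channels = 1,
                             lesion_area = c(50, 400),
                             lesion_drop = c(0.4, 0.7),
                             lesion_aspect = c(0.4, 1),
                             lesion_softness = 1,
                             speckle_scale = 0.3,
                             smoothness = 8,
                             seed = 1) {
  if (any(c(n_train, n_val, n_test) < 1))
    stop_invalid("all split counts must be >= 1")
  if (!channels %in% c(1, 3)) stop_invalid("channels must be 1 or 3")
  if (length(lesion_area) != 2 || lesion_area[1] > lesion_area[2] ||
      lesion_area[1] < 1)
    stop_invalid("lesion_area must be an increasing positive range")
  # feasibility: the largest, most elongated ellipse must fit with margin
  a_max <- sqrt(lesion_area[2] / (pi * lesion_aspect[1]))
  margin <- 2 + ceiling(2 * lesion_softness)
  if (2 * a_max + 2 * margin >= min(height, width))
    stop_invalid("lesion size range infeasible for image size ",
                 height, "x", width)

  make_normal <- function(tag, i) {
    bg <- generate_background(height, width,
                              seed = derive_seed(seed, paste0(tag, i, "bg")),
                              smoothness = smoothness)
    img <- apply_speckle(bg, seed = derive_seed(seed, paste0(tag, i, "sp")),
                         scale = speckle_scale)
    if (channels == 3) array(rep(img, 3), dim = c(height, width, 3)) else img
  }

  make_abnormal <- function(i) {
    bg <- generate_background(height, width,
                              seed = derive_seed(seed, paste0("test", i, "bg")),
                              smoothness = smoothness)
    spec <- with_seed(derive_seed(seed, paste0("test", i, "les")), {
      area <- runif(1, lesion_area[1], lesion_area[2])
      q <- runif(1, lesion_aspect[1], lesion_aspect[2])
      a <- sqrt(area / (pi * q)); b <- q * a
      th <- runif(1, 0, pi)
      ext <- ellipse_extent(lesion_spec(c(0, 0), c(a, b), th, 0.5, 0))
      lesion_spec(center = c(runif(1, 1 + ext["row"] + margin,
                                      height - ext["row"] - margin),
                             runif(1, 1 + ext["col"] + margin,
                                      width - ext["col"] - margin)),
                  semi_axes = c(a, b), rotation = th,
                  intensity_drop = runif(1, lesion_drop[1], lesion_drop[2]),
                  edge_softness = lesion_softness)
    })
    les <- insert_lesion(bg, spec)
    img <- apply_speckle(les$image,
                         seed = derive_seed(seed, paste0("test", i, "sp")),
                         scale = speckle_scale)
    if (channels == 3) img <- array(rep(img, 3), dim = c(height, width, 3))
    list(image = img, mask = les$mask, area_px = sum(les$mask))
  }

  ds <- list(
    train = lapply(seq_len(n_train), function(i) make_normal("train", i)),
    val   = lapply(seq_len(n_val),   function(i) make_normal("val", i)),
    test  = lapply(seq_len(n_test), make_abnormal),
    height = height, width = width, channels = channels, seed = seed,
    config = list(n_train = n_train, n_val = n_val, n_test = n_test,
                  lesion_area = lesion_area, lesion_drop = lesion_drop,
                  lesion_aspect = lesion_aspect,
                  lesion_softness = lesion_softness,
                  speckle_scale = speckle_scale, smoothness = smoothness))
  class(ds) <- "split_dataset"
  ds
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("Synthetic ultrasound phantom dataset\n")
  cat(sprintf("  image grid : %d x %d x %d\n", x$height, x$width, x$channels))
  cat(sprintf("  splits     : %d train / %d val (normal), %d test (lesioned)\n",
              length(x$train), length(x$val), length(x$test)))
  if (length(x$test))
    cat(sprintf("  lesion area: %d-%d px (realized)\n",
                min(vapply(x$test, `[[`, 0, "area_px")),
                max(vapply(x$test, `[[`, 0, "area_px"))))
  cat(sprintf("  seed       : %d\n", x$seed))
  invisible(x)
}
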