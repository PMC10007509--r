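# Internal helpers: seeded evaluation, seed derivation, argument checks.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps a global integer seed and a character tag (stage
#' or item name) to a 31-bit integer seed, so that every stochastic stage of
#' an experiment gets its own independent, reproducible stream while the
#' user only ever chooses one number. Changing the global seed changes every
#' derived seed.
#'
#' @param seed integer global seed.
#' @param tag character label of the stage ("generate", "train_swae", ...).
#' @return An integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "train") != derive_seed(2, "train")
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647          # 2^31 - 1 (prime)
  s <- as.double(seed %% m)
  for (code in utf8ToInt(tag)) s <- (s * 31 + code) %% m
  # one multiplicative mix so that consecutive seeds decorrelate
  as.integer((s * 48271) %% m)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("aedetect_invalid", "error")))
}

# An Image is a numeric matrix (H x W) or an H x W x 3 array with finite
# values in [0,1].
check_image <- function(img, name = "img", unit = TRUE) {
  if (!is.numeric(img) || !(is.matrix(img) || (is.array(img) && length(dim(img)) == 3)))
    stop_invalid(name, " must be a numeric matrix or H x W x C array")
  if (is.array(img) && !is.matrix(img) && !dim(img)[3] %in% c(1L, 3L))
    stop_invalid(name, " must have 1 or 3 channels")
  if (any(!is.finite(img)))
    stop_invalid(name, " contains non-finite values")
  if (unit && (min(img) < 0 || max(img) > 1))
    stop_invalid(name, " must have values in [0, 1]")
  invisible(img)
}

check_same_shape <- function(x, y, nx = "x", ny = "y") {
  dx <- if (is.matrix(x) || is.array(x)) dim(x) else length(x)
  dy <- if (is.matrix(y) || is.array(y)) dim(y) else length(y)
  if (!identical(dx, dy))
    stop_invalid(nx, " and ", ny, " must have the same shape")
  invisible(TRUE)
}

check_mask <- function(mask, name = "mask") {
  if (!is.numeric(mask) && !is.logical(mask))
    stop_invalid(name, " must be numeric or logical")
  v <- as.numeric(mask)
  if (!all(v %in% c(0, 1)))
    stop_invalid(name, " must be binary (values in {0, 1})")
  invisible(mask)
}

# channel-mean of an H x W x C array; matrices pass through
collapse_channels <- function(img) {
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3 && d[3] == 1) return(img[, , 1])
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# list of images (matrices or HxWxC arrays) -> H x W x C x N array
stack_images <- function(images, channels = NULL) {
  stopifnot(length(images) >= 1)
  d1 <- dim(images[[1]])
  h <- d1[1]; w <- d1[2]
  ch <- if (length(d1) == 3) d1[3] else 1L
  if (!is.null(channels) && ch != channels)
    stop_invalid("images have ", ch, " channels, expected ", channels)
  out <- array(0, dim = c(h, w, ch, length(images)))
  for (i in seq_along(images)) {
    im <- images[[i]]
    di <- dim(im)
    if (di[1] != h || di[2] != w ||
        (if (length(di) == 3) di[3] else 1L) != ch)
      stop_invalid("image ", i, " has inconsistent dimensions")
    out[, , , i] <- im
  }
  out
}

unstack_images <- function(x4) {
  d <- dim(x4)
  lapply(seq_len(d[4]), function(i) {
    if (d[3] == 1L) x4[, , 1, i] else x4[, , , i]
  })
}
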