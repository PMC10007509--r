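# S3 methods for the fitted model object.

#' Predict method for anomaly autoencoders
#'
#' Runs trained encoder and decoder in evaluation mode (BatchNorm running
#' statistics; the variational model uses the posterior mean unless
#' `sample = TRUE`).
#'
#' @param object fitted [anomaly_autoencoder()].
#' @param newdata a single image, a list of images, or a `split_dataset`
#'   split (list); images must match the trained input size.
#' @param type `"reconstruction"` (decoded images), `"anomaly"`
#'   (absolute-difference maps), `"mask"` (binarized maps) or `"latent"`
#'   (latent codes, one column per image).
#' @param threshold threshold for `type = "mask"`; defaults to the stored
#'   validation threshold.
#' @param sample draw a latent sample instead of using the posterior mean
#'   (variational model only).
#' @param seed seed used when `sample = TRUE`.
#' @param ... unused.
#' @return For a single image input, a single image/map/mask (or latent
#'   vector); for a list input, a list (for `"latent"`, a matrix with one
#'   column per image).
#' @export
predict.anomaly_autoencoder <- function(object, newdata,
                                        type = c("reconstruction", "anomaly",
                                                 "mask", "latent"),
                                        threshold = object$threshold,
                                        sample = FALSE, seed = 1, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "split_dataset"))
    stop_invalid("pass one split (e.g. x$val), not the whole dataset")
  if (is.list(newdata) && !is.null(newdata$image))
    newdata <- newdata$image                    # a single test item
  single <- !is.list(newdata)
  images <- if (single) list(newdata) else newdata
  images <- lapply(images, function(im) if (is.list(im)) im$image else im)
  for (im in images) check_image(im)
  X <- stack_images(images, channels = object$config$input_shape[3])

  run <- function(X4) {
    if (sample && object$kind == "vae")
      with_seed(derive_seed(seed, "predict"),
                net_forward(object$net, X4, train = FALSE, sample = TRUE))
    else net_forward(object$net, X4, train = FALSE)
  }
  fw <- run(X)

  out <- switch(type,
    reconstruction = unstack_images(fw$xhat),
    anomaly = ,
    mask = {
      maps <- Map(anomaly_map, images, unstack_images(fw$xhat))
      if (type == "anomaly") maps else {
        if (is.null(threshold))
          stop_invalid("type = 'mask' needs a threshold")
        lapply(maps, binarize, threshold = threshold)
      }
    },
    latent = fw$Z)
  if (single && type != "latent") out[[1]]
  else if (single) drop(out)
  else out
}

#' Encode images into the latent space
#'
#' @param object fitted [anomaly_autoencoder()].
#' @param x a single image or list of images.
#' @return For the plain and sliced-Wasserstein models, the latent code(s)
#'   (vector, or `d x N` matrix for a list). For the variational model, a
#'   list with `z` (posterior mean), `mu` and `sigma`.
#' @export
encode <- function(object, x) {
  stopifnot(inherits(object, "anomaly_autoencoder"))
  if (is.list(x) && !is.null(x$image)) x <- x$image
  single <- !is.list(x)
  images <- if (single) list(x) else x
  for (im in images) check_image(im)
  X <- stack_images(images, channels = object$config$input_shape[3])
  fw <- net_forward(object$net, X, train = FALSE)
  if (object$kind == "vae") {
    out <- list(z = fw$MU, mu = fw$MU, sigma = fw$cache$SIG)
    if (single) lapply(out, drop) else out
  } else {
    if (single) drop(fw$Z) else fw$Z
  }
}

#' Decode latent codes into images
#'
#' @param object fitted [anomaly_autoencoder()].
#' @param z latent vector, or matrix with one code per column.
#' @return A single image (or list of images), every pixel strictly in
#'   (0, 1) by the sigmoid output layer.
#' @export
decode <- function(object, z) {
  stopifnot(inherits(object, "anomaly_autoencoder"))
  if (is.vector(z)) z <- matrix(z, ncol = 1)
  cfg <- object$net$cfg
  if (nrow(z) != cfg$d_z)
    stop_invalid("latent dimension mismatch: expected ", cfg$d_z)
  net <- object$net; par <- net$par; N <- ncol(z)
  if (!is.null(cfg$latent_dim)) {
    h0 <- leaky_fwd(par$dec_fc_W %*% z + par$dec_fc_b, cfg$slope)
    a <- array(h0, dim = c(cfg$hb, cfg$wb, cfg$cl, N))
  } else {
    a <- array(z, dim = c(cfg$hb, cfg$wb, cfg$cl, N))
  }
  for (l in seq_len(cfg$nb)) {
    hh <- cfg$hb * 2^l; ww <- cfg$wb * 2^l
    pre <- conv_bwd_input(a, par[[sprintf("dec%d_W", l)]], 2L, 1L, hh, ww)
    pre <- add_channel_bias(pre, par[[sprintf("dec%d_b", l)]])
    if (l < cfg$nb) {
      if (cfg$batchnorm) {
        bn <- bn_fwd(pre, par[[sprintf("dec%d_g", l)]],
                     par[[sprintf("dec%d_be", l)]],
                     net$state[[sprintf("dec%d_rm", l)]],
                     net$state[[sprintf("dec%d_rv", l)]], train = FALSE)
        pre <- bn$y
      }
      a <- leaky_fwd(pre, cfg$slope)
    } else a <- sigmoid(pre)
  }
  imgs <- unstack_images(a)
  if (N == 1) imgs[[1]] else imgs
}

#' @export
residuals.anomaly_autoencoder <- function(object, newdata, ...) {
  predict(object, newdata, type = "anomaly")
}

#' @export
coef.anomaly_autoencoder <- function(object, ...) object$net$par

#' @export
print.anomaly_autoencoder <- function(x, ...) {
  cfg <- x$net$cfg
  cat(sprintf("%s anomaly-detection autoencoder\n",
              switch(x$kind, ae = "Plain", vae = "Variational",
                     swae = "Sliced-Wasserstein")))
  cat(sprintf("  input %dx%dx%d, conv channels %s, latent %s\n",
              cfg$h, cfg$w, cfg$ci,
              paste(cfg$channels, collapse = "-"),
              if (is.null(cfg$latent_dim)) sprintf("spatial (%d)", cfg$d_z)
              else cfg$latent_dim))
  cat(sprintf("  trained %d epochs on %d images; final loss %.5f\n",
              nrow(x$history), x$n_train,
              x$history$loss[nrow(x$history)]))
  if (!is.null(x$threshold))
    cat(sprintf("  validation ReLU-max threshold: %.4f\n",
                as.numeric(x$threshold)))
  invisible(x)
}

#' @export
summary.anomaly_autoencoder <- function(object, ...) {
  structure(list(fit = object,
                 n_par = sum(vapply(object$net$par, length, 0L)),
                 n_conv_par = n_conv_parameters(object$net)),
            class = "summary.anomaly_autoencoder")
}

#' @export
print.summary.anomaly_autoencoder <- function(x, ...) {
  print(x$fit)
  h <- x$fit$history
  cat(sprintf("  parameters: %d (%d in conv stacks)\n", x$n_par, x$n_conv_par))
  cat(sprintf("  loss %.5f -> %.5f over %d epochs (recon %.5f, penalty %.5f)\n",
              h$loss[1], h$loss[nrow(h)], nrow(h),
              h$recon[nrow(h)], h$penalty[nrow(h)]))
  invisible(x)
}

#' Plot training history or an anomaly-map triptych
#'
#' `which = "history"` draws the per-epoch training loss with the learning
#' rate; `which = "detection"` shows an image, its anomaly map and the
#' binarized mask side by side (requires `x_img`).
#'
#' @param x fitted model.
#' @param which `"history"` or `"detection"`.
#' @param x_img image for `which = "detection"`.
#' @param threshold threshold for the mask panel.
#' @param ... passed to plotting primitives.
#' @export
plot.anomaly_autoencoder <- function(x, which = c("history", "detection"),
                                     x_img = NULL,
                                     threshold = x$threshold, ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$history
    op <- par(mar = c(4, 4, 2, 4))
    on.exit(par(op))
    plot(h$epoch, h$loss, type = "l", xlab = "epoch",
         ylab = "mean training loss", main = toupper(x$kind), ...)
    par(new = TRUE)
    plot(h$epoch, h$lr, type = "l", lty = 3, axes = FALSE,
         xlab = "", ylab = "")
    graphics::axis(4)
    graphics::mtext("learning rate", side = 4, line = 2.5)
  } else {
    if (is.null(x_img)) stop_invalid("which = 'detection' needs x_img")
    det <- detect(x, x_img, threshold)
    op <- par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
    on.exit(par(op))
    show <- function(m, main)
      image(t(m[nrow(m):1, ]), axes = FALSE, main = main,
            col = grDevices::gray.colors(256, 0, 1), zlim = c(0, 1))
    show(collapse_channels(x_img), "input")
    show(det$map, "anomaly map")
    show(det$mask, sprintf("mask (th=%.3g)", as.numeric(threshold)))
  }
  invisible(x)
}
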