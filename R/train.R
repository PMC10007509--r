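# Training: Adam optimization under a single-cycle cosine-annealed learning
# rate, on normal-only images.

#' Cosine-annealed learning rate
#'
#' Single-cycle cosine schedule without restarts, evaluated per epoch:
#' `lr(t) = lr_min + (lr_max - lr_min) * (1 + cos(pi * t / T)) / 2`,
#' so `lr(0) = lr_max` and `lr(T) = lr_min`.
#'
#' @param t epoch index (vectorized), `0 <= t <= T`.
#' @param T total number of epochs (>= 1).
#' @param lr_max maximum (initial) learning rate; default 2e-4.
#' @param lr_min final learning rate, `0 <= lr_min <= lr_max`.
#' @return Learning rate(s).
#' @examples
#' cosine_annealing_lr(0, 150)              # 2e-4
#' cosine_annealing_lr(75, 150)             # 1e-4
#' @export
cosine_annealing_lr <- function(t, T, lr_max = 2e-4, lr_min = 0) {
  if (!is.numeric(T) || T < 1) stop_invalid("T must be >= 1")
  if (lr_min < 0 || lr_min > lr_max)
    stop_invalid("need 0 <= lr_min <= lr_max")
  if (any(t < 0) || any(t > T)) stop_invalid("t must lie in [0, T]")
  lr_min + (lr_max - lr_min) * (1 + cos(pi * t / T)) / 2
}

# Adam step over flat named lists of parameter/gradient arrays
adam_update <- function(par, grads, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    par[[nm]] <- par[[nm]] - lr * (st$m[[nm]] / c1) /
      (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(par = par, st = st)
}

# sliced-Wasserstein distance with gradient w.r.t. Z (n x d, one point per
# row); directions drawn from the current RNG stream
swd_with_grad <- function(Z, P, L) {
  n <- nrow(Z); d <- ncol(Z)
  theta <- random_directions(d, L)
  pz <- Z %*% theta
  pp <- P %*% theta
  G <- matrix(0, n, d)
  loss <- 0
  for (l in seq_len(L)) {
    oz <- order(pz[, l]); op <- order(pp[, l])
    dif <- pz[oz, l] - pp[op, l]
    loss <- loss + sum(dif^2) / n
    gv <- numeric(n)
    gv[oz] <- 2 * dif / (n * L)
    G <- G + tcrossprod(gv, theta[, l])
  }
  list(value = loss / L, grad = G)
}

#' Fit a reconstruction-based anomaly-detection autoencoder
#'
#' Trains one of three convolutional autoencoder variants on normal-only
#' ultrasound images with Adam under a cosine-annealed learning rate:
#'
#' * `"ae"` - plain autoencoder, L1 reconstruction loss;
#' * `"vae"` - variational autoencoder, L1 reconstruction plus `beta` times
#'   the closed-form Gaussian KL divergence, trained with the
#'   reparameterization trick;
#' * `"swae"` - sliced-Wasserstein autoencoder, per-pixel MSE plus `lambda`
#'   times the sliced-Wasserstein distance between each latent batch and an
#'   equal-size standard-normal draw.
#'
#' All variants share an identical encoder/decoder topology
#' (`length(channels)` stride-2 conv blocks with BatchNorm and LeakyReLU,
#' mirrored transposed-conv decoder, sigmoid output) and differ only in
#' their latent heads and loss. Trained on normal anatomy only, the model
#' reconstructs healthy tissue well but fails on unseen lesions, so
#' per-pixel reconstruction error localizes anomalous regions.
#'
#' @param x training images: a list of images in \[0, 1\], or a
#'   `split_dataset` from [generate_dataset()] (its `train` split is used;
#'   if a validation split is present, the ReLU-max validation threshold is
#'   computed and stored on the fit).
#' @param kind model variant, one of `"ae"`, `"vae"`, `"swae"`.
#' @param epochs,batch_size,lr,lr_min training protocol; defaults follow
#'   the reference protocol (batch 16, maximum learning rate 2e-4 annealed
#'   to `lr_min` over `epochs`). The last incomplete batch is kept.
#' @param latent_dim latent bottleneck dimension; `NULL` selects the
#'   no-reduction spatial bottleneck (conv features used as the latent).
#' @param channels channel widths of the conv blocks; the image sides must
#'   be divisible by `2^length(channels)`.
#' @param beta KL weight (VAE).
#' @param lambda sliced-Wasserstein weight (SWAE).
#' @param n_projections random projections per SWD evaluation (SWAE).
#' @param batchnorm,leaky_slope backbone details.
#' @param augment_gamma append gamma-corrected (`gamma_values`) copies of
#'   the training images before training; validation data are never
#'   augmented.
#' @param gamma_values gamma exponents for the augmentation copies.
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param seed integer seed; fixes initialization, shuffling, noise draws
#'   and projections, making the fit bit-reproducible.
#' @param verbose print per-epoch loss lines.
#' @return An object of class `anomaly_autoencoder` with components
#'   `kind`, `net` (parameters), `history` (per-epoch data frame with
#'   `epoch`, `loss`, `recon`, `penalty`, `lr`), `config`, `threshold`
#'   (ReLU-max validation threshold, when a validation split was given)
#'   and `seed`. Supports [predict()][predict.anomaly_autoencoder()],
#'   `residuals()`, `coef()`, `plot()`, `print()` and `summary()`.
#' @seealso [detect()], [anomaly_map()], [find_threshold()],
#'   [compare_models()]
#' @examples
#' \donttest{
#' ds <- generate_dataset(20, 5, 5, height = 32, width = 32, seed = 1)
#' fit <- anomaly_autoencoder(ds, "ae", epochs = 3, verbose = FALSE)
#' fit
#' }
#' @export
anomaly_autoencoder <- function(x, kind = c("ae", "vae", "swae"),
                                epochs = 150, batch_size = 16,
                                lr = 2e-4, lr_min = 0,
                                latent_dim = 32, channels = c(8, 16, 32, 64),
                                beta = 1, lambda = 10, n_projections = 50,
                                batchnorm = TRUE, leaky_slope = 0.2,
                                augment_gamma = TRUE,
                                gamma_values = c(0.5, 1.5),
                                adam_beta1 = 0.9, adam_beta2 = 0.999,
                                seed = 1, verbose = FALSE) {
  kind <- match.arg(kind)
  if (epochs < 1 || batch_size < 1)
    stop_invalid("epochs and batch_size must be >= 1")
  cl <- match.call()

  val_images <- NULL
  if (inherits(x, "split_dataset")) {
    if (length(x$val)) val_images <- x$val
    images <- x$train
  } else if (is.list(x)) {
    images <- x
  } else stop_invalid("x must be a split_dataset or a list of images")
  if (length(images) < 1) stop_invalid("training split is empty")
  for (im in images) check_image(im)
  if (augment_gamma) images <- augment_gamma(images, gamma_values)

  X <- stack_images(images)
  dX <- dim(X)
  cfg <- net_config(kind, dX[1:3], channels, latent_dim,
                    batchnorm, leaky_slope)

  npix_img <- prod(dX[1:3])
  n_img <- dX[4]

  h_loss <- h_recon <- h_pen <- h_lr <- numeric(epochs)

  net <- with_seed(derive_seed(seed, "fit"), {
    net <- init_network(cfg)
    adam <- list(t = 0L,
                 m = lapply(net$par, function(p) p * 0),
                 v = lapply(net$par, function(p) p * 0))

    for (ep in seq_len(epochs)) {
      lr_ep <- cosine_annealing_lr(ep - 1, epochs, lr, lr_min)
      ord <- sample.int(n_img)
      ep_loss <- ep_recon <- ep_pen <- 0
      nb_seen <- 0
      for (start in seq(1, n_img, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n_img)]
        Xb <- X[, , , idx, drop = FALSE]
        Nb <- length(idx)
        fw <- net_forward(net, Xb, train = TRUE)
        net <- fw$net
        diff <- fw$xhat - Xb

        if (kind == "ae") {
          recon <- sum(abs(diff)) / Nb
          pen <- 0
          obj <- recon
          dxhat <- sign(diff) / Nb
          grads <- net_backward(net, fw, dxhat)
        } else if (kind == "vae") {
          recon <- sum(abs(diff)) / Nb
          kld <- 0.5 * sum(fw$MU^2 + cache_sig2(fw) - 1 - fw$LV) / Nb
          pen <- beta * kld
          obj <- recon + pen
          dxhat <- sign(diff) / Nb
          dMU <- beta * fw$MU / Nb
          dLV <- beta * 0.5 * (cache_sig2(fw) - 1) / Nb
          grads <- net_backward(net, fw, dxhat,
                                dMU_extra = dMU, dLV_extra = dLV)
        } else {
          recon <- sum(diff^2) / (npix_img * Nb)
          Zr <- t(fw$Z)                       # points in rows
          P <- matrix(rnorm(length(Zr)), nrow(Zr))
          sw <- swd_with_grad(Zr, P, n_projections)
          pen <- lambda * sw$value
          obj <- recon + pen
          dxhat <- 2 * diff / (npix_img * Nb)
          grads <- net_backward(net, fw, dxhat,
                                dZ_extra = lambda * t(sw$grad))
        }
        if (!is.finite(obj))
          stop(errorCondition(
            sprintf("training diverged (non-finite loss) at epoch %d", ep),
            class = c("aedetect_divergence", "error")))

        up <- adam_update(net$par, grads, adam, lr_ep,
                          adam_beta1, adam_beta2)
        net$par <- up$par
        adam <- up$st

        ep_loss <- ep_loss + obj * Nb
        ep_recon <- ep_recon + recon * Nb
        ep_pen <- ep_pen + pen * Nb
        nb_seen <- nb_seen + Nb
      }
      h_loss[ep] <- ep_loss / nb_seen
      h_recon[ep] <- ep_recon / nb_seen
      h_pen[ep] <- ep_pen / nb_seen
      h_lr[ep] <- lr_ep
      if (verbose)
        message(sprintf("[%s] epoch %3d/%d  loss %.6f  lr %.3g",
                        kind, ep, epochs, ep_loss / nb_seen, lr_ep))
    }
    net
  })

  history <- data.frame(epoch = seq_len(epochs), loss = h_loss,
                        recon = h_recon, penalty = h_pen, lr = h_lr)

  fit <- structure(list(
    kind = kind, net = net, history = history,
    config = list(epochs = epochs, batch_size = batch_size, lr = lr,
                  lr_min = lr_min, latent_dim = latent_dim,
                  channels = channels, beta = beta, lambda = lambda,
                  n_projections = n_projections, batchnorm = batchnorm,
                  leaky_slope = leaky_slope, augment_gamma = augment_gamma,
                  gamma_values = gamma_values,
                  input_shape = dX[1:3]),
    n_train = n_img, seed = seed, call = cl),
    class = "anomaly_autoencoder")

  if (!is.null(val_images)) {
    maps <- lapply(val_images, function(im)
      anomaly_map(im, predict(fit, im, type = "reconstruction")))
    fit$threshold <- find_threshold(maps)
  }
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cache_sig2 <- function(fw) fw$cache$SIG^2
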