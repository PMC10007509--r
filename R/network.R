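# Convolutional encoder/decoder backbone shared by the three model
# variants, with hand-written forward and backward passes.
#
# Layout conventions:
#   activations  H x W x C x N arrays (column-major, as returned by the
#                C++ conv primitives)
#   latent codes d x N matrices
#   trainable parameters: a flat named list net$par; BatchNorm running
#                statistics live in net$state (not trained)
#
# The encoder is `nb = length(channels)` stride-2 conv blocks
# (conv 3x3 -> BatchNorm -> LeakyReLU), followed by a dense bottleneck to
# `latent_dim` (or no reduction when latent_dim is NULL); the decoder
# mirrors it with transposed convolutions and a final sigmoid, so every
# reconstructed pixel lies strictly in (0, 1). A transposed convolution is
# the adjoint of a strided convolution, so conv_bwd_input doubles as the
# transposed-conv forward pass and conv_fwd as its input-backward.

net_config <- function(kind, input_shape, channels, latent_dim,
                       batchnorm = TRUE, slope = 0.2) {
  h <- input_shape[1]; w <- input_shape[2]; ci <- input_shape[3]
  nb <- length(channels)
  if (nb < 1) stop_invalid("channels must name at least one conv block")
  if (h %% 2^nb != 0 || w %% 2^nb != 0 || h / 2^nb < 1 || w / 2^nb < 1)
    stop_invalid("image size ", h, "x", w, " incompatible with ", nb,
                 " stride-2 blocks; dimensions must be divisible by ", 2^nb)
  hb <- h / 2^nb; wb <- w / 2^nb
  list(kind = kind, h = h, w = w, ci = ci, channels = channels, nb = nb,
       hb = hb, wb = wb, cl = channels[nb], dflat = hb * wb * channels[nb],
       latent_dim = if (is.null(latent_dim)) NULL else as.integer(latent_dim),
       d_z = if (is.null(latent_dim)) hb * wb * channels[nb]
             else as.integer(latent_dim),
       batchnorm = isTRUE(batchnorm), slope = slope)
}

# He-style init; draws come from the caller's RNG stream
init_network <- function(cfg) {
  par <- list(); state <- list()
  conv_w <- function(k, cin, cout)
    array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
          dim = c(k, k, cin, cout))
  dense_w <- function(nout, nin)
    matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)

  cins <- c(cfg$ci, cfg$channels[-cfg$nb])
  for (l in seq_len(cfg$nb)) {
    par[[sprintf("enc%d_W", l)]] <- conv_w(3, cins[l], cfg$channels[l])
    par[[sprintf("enc%d_b", l)]] <- numeric(cfg$channels[l])
    if (cfg$batchnorm) {
      par[[sprintf("enc%d_g", l)]] <- rep(1, cfg$channels[l])
      par[[sprintf("enc%d_be", l)]] <- numeric(cfg$channels[l])
      state[[sprintf("enc%d_rm", l)]] <- numeric(cfg$channels[l])
      state[[sprintf("enc%d_rv", l)]] <- rep(1, cfg$channels[l])
    }
  }
  if (!is.null(cfg$latent_dim)) {
    if (cfg$kind == "vae") {
      par$enc_mu_W <- dense_w(cfg$latent_dim, cfg$dflat)
      par$enc_mu_b <- numeric(cfg$latent_dim)
      par$enc_lv_W <- dense_w(cfg$latent_dim, cfg$dflat)
      par$enc_lv_b <- numeric(cfg$latent_dim)
    } else {
      par$enc_fc_W <- dense_w(cfg$latent_dim, cfg$dflat)
      par$enc_fc_b <- numeric(cfg$latent_dim)
    }
    par$dec_fc_W <- dense_w(cfg$dflat, cfg$latent_dim)
    par$dec_fc_b <- numeric(cfg$dflat)
  } else if (cfg$kind == "vae") {
    par$enc_mu_W <- conv_w(1, cfg$cl, cfg$cl)
    par$enc_mu_b <- numeric(cfg$cl)
    par$enc_lv_W <- conv_w(1, cfg$cl, cfg$cl)
    par$enc_lv_b <- numeric(cfg$cl)
  }
  # decoder block l upsamples channels couts[l] -> couts[l+1]
  couts <- c(rev(cfg$channels), cfg$ci)
  for (l in seq_len(cfg$nb)) {
    par[[sprintf("dec%d_W", l)]] <- conv_w(3, couts[l + 1], couts[l])
    par[[sprintf("dec%d_b", l)]] <- numeric(couts[l + 1])
    if (cfg$batchnorm && l < cfg$nb) {
      par[[sprintf("dec%d_g", l)]] <- rep(1, couts[l + 1])
      par[[sprintf("dec%d_be", l)]] <- numeric(couts[l + 1])
      state[[sprintf("dec%d_rm", l)]] <- numeric(couts[l + 1])
      state[[sprintf("dec%d_rv", l)]] <- rep(1, couts[l + 1])
    }
  }
  list(cfg = cfg, par = par, state = state)
}

n_conv_parameters <- function(net) {
  nm <- grep("^(enc|dec)[0-9]+_(W|b)$", names(net$par), value = TRUE)
  sum(vapply(net$par[nm], length, 0L))
}

## ---- elementwise pieces ---------------------------------------------------

leaky_fwd <- function(x, slope) x * (slope + (1 - slope) * (x > 0))
leaky_bwd <- function(g, pre, slope) g * (slope + (1 - slope) * (pre > 0))
sigmoid <- function(x) 1 / (1 + exp(-x))

# per-channel vector expanded over one H x W plane; elementwise arithmetic
# with an H x W x C x N array then recycles it over the batch dimension
crep <- function(v, HW) rep(v, each = HW)

# per-channel sums over (H, W, N)
chan_sum <- function(x4) {
  d <- dim(x4)
  .rowSums(.colSums(x4, d[1] * d[2], d[3] * d[4]), d[3], d[4])
}

add_channel_bias <- function(x4, b) {
  d <- dim(x4)
  x4 + crep(b, d[1] * d[2])
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# batch normalization over (H, W, N) per channel; biased batch variance
bn_fwd <- function(x4, gamma, beta, rm, rv, train) {
  d <- dim(x4)
  HW <- d[1] * d[2]
  m <- HW * d[4]
  if (train) {
    mu <- chan_sum(x4) / m
    va <- chan_sum(x4 * x4) / m - mu^2
    rm <- (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu
    rv <- (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * va
  } else {
    mu <- rm; va <- rv
  }
  inv_std <- 1 / sqrt(va + BN_EPS)
  a <- gamma * inv_std
  y <- x4 * crep(a, HW) + crep(beta - a * mu, HW)
  list(y = y, rm = rm, rv = rv,
       cache = list(x = x4, mu = mu, inv_std = inv_std, gamma = gamma,
                    HW = HW, m = m, train = train))
}

bn_bwd <- function(g4, cache) {
  HW <- cache$HW; m <- cache$m
  xh <- (cache$x - crep(cache$mu, HW)) * crep(cache$inv_std, HW)
  ggamma <- chan_sum(g4 * xh)
  gbeta <- chan_sum(g4)
  a <- cache$gamma * cache$inv_std
  gx <- if (cache$train)
    crep(a, HW) * (g4 - crep(gbeta / m, HW) - xh * crep(ggamma / m, HW))
  else
    g4 * crep(a, HW)
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

## ---- forward --------------------------------------------------------------

# eps: optional d_z x N matrix of standard-normal draws for the VAE
# reparameterization; drawn from the current RNG stream when NULL in
# training mode. Evaluation mode uses the posterior mean (no sampling)
# unless sample = TRUE.
net_forward <- function(net, X4, train = TRUE, eps = NULL, sample = FALSE) {
  cfg <- net$cfg; par <- net$par; state <- net$state
  if (dim(X4)[1] != cfg$h || dim(X4)[2] != cfg$w || dim(X4)[3] != cfg$ci)
    stop_invalid("image size ", dim(X4)[1], "x", dim(X4)[2], "x", dim(X4)[3],
                 " does not match the configured input ",
                 cfg$h, "x", cfg$w, "x", cfg$ci)
  N <- dim(X4)[4]
  cache <- list(conv_in = list(), pre = list(), bn = list(),
                dec_in = list(), dec_pre = list(), dec_bn = list())

  a <- X4
  for (l in seq_len(cfg$nb)) {
    cache$conv_in[[l]] <- a
    pre <- conv_fwd(a, par[[sprintf("enc%d_W", l)]],
                    par[[sprintf("enc%d_b", l)]], 2L, 1L)
    if (cfg$batchnorm) {
      bn <- bn_fwd(pre, par[[sprintf("enc%d_g", l)]],
                   par[[sprintf("enc%d_be", l)]],
                   state[[sprintf("enc%d_rm", l)]],
                   state[[sprintf("enc%d_rv", l)]], train)
      if (train) {
        state[[sprintf("enc%d_rm", l)]] <- bn$rm
        state[[sprintf("enc%d_rv", l)]] <- bn$rv
      }
      cache$bn[[l]] <- bn$cache
      act_in <- bn$y
    } else act_in <- pre
    cache$pre[[l]] <- act_in
    a <- leaky_fwd(act_in, cfg$slope)
  }
  feat <- a
  cache$featdim <- dim(feat)
  zf <- matrix(feat, cfg$dflat, N)
  cache$zf <- zf

  MU <- LV <- EPS <- NULL
  if (cfg$kind == "vae") {
    if (!is.null(cfg$latent_dim)) {
      MU <- par$enc_mu_W %*% zf + par$enc_mu_b
      LVr <- par$enc_lv_W %*% zf + par$enc_lv_b
    } else {
      mu4 <- conv_fwd(feat, par$enc_mu_W, par$enc_mu_b, 1L, 0L)
      lv4 <- conv_fwd(feat, par$enc_lv_W, par$enc_lv_b, 1L, 0L)
      MU <- matrix(mu4, cfg$d_z, N)
      LVr <- matrix(lv4, cfg$d_z, N)
    }
    # clamp the log-variance for numerical stability; gradients vanish
    # outside the clamp (subgradient of the clipped map)
    LV <- pmin(pmax(LVr, -10), 10)
    cache$lv_active <- (LVr > -10) & (LVr < 10)
    SIG <- exp(LV / 2)
    if (train || sample) {
      if (is.null(eps)) eps <- matrix(rnorm(cfg$d_z * N), cfg$d_z, N)
      EPS <- eps
      Z <- MU + EPS * SIG
    } else Z <- MU
    cache$SIG <- SIG
  } else if (!is.null(cfg$latent_dim)) {
    Z <- par$enc_fc_W %*% zf + par$enc_fc_b
  } else {
    Z <- zf
  }
  cache$Z <- Z

  if (!is.null(cfg$latent_dim)) {
    pre0 <- par$dec_fc_W %*% Z + par$dec_fc_b
    cache$dec_pre0 <- pre0
    h0 <- leaky_fwd(pre0, cfg$slope)
    a <- array(h0, dim = c(cfg$hb, cfg$wb, cfg$cl, N))
  } else {
    a <- array(Z, dim = c(cfg$hb, cfg$wb, cfg$cl, N))
  }

  for (l in seq_len(cfg$nb)) {
    cache$dec_in[[l]] <- a
    hh <- cfg$hb * 2^l; ww <- cfg$wb * 2^l
    pre <- conv_bwd_input(a, par[[sprintf("dec%d_W", l)]], 2L, 1L, hh, ww)
    pre <- add_channel_bias(pre, par[[sprintf("dec%d_b", l)]])
    if (l < cfg$nb) {
      if (cfg$batchnorm) {
        bn <- bn_fwd(pre, par[[sprintf("dec%d_g", l)]],
                     par[[sprintf("dec%d_be", l)]],
                     state[[sprintf("dec%d_rm", l)]],
                     state[[sprintf("dec%d_rv", l)]], train)
        if (train) {
          state[[sprintf("dec%d_rm", l)]] <- bn$rm
          state[[sprintf("dec%d_rv", l)]] <- bn$rv
        }
        cache$dec_bn[[l]] <- bn$cache
        act_in <- bn$y
      } else act_in <- pre
      cache$dec_pre[[l]] <- act_in
      a <- leaky_fwd(act_in, cfg$slope)
    } else {
      cache$dec_pre[[l]] <- pre
      a <- sigmoid(pre)
    }
  }
  net$state <- state
  list(xhat = a, Z = Z, MU = MU, LV = LV, EPS = EPS,
       cache = cache, net = net)
}

## ---- backward -------------------------------------------------------------

# dxhat: gradient of the loss at the reconstruction; dZ_extra / dMU_extra /
# dLV_extra: latent-space loss terms (sliced-Wasserstein, KLD).
net_backward <- function(net, fw, dxhat, dZ_extra = NULL,
                         dMU_extra = NULL, dLV_extra = NULL) {
  cfg <- net$cfg; par <- net$par; cache <- fw$cache
  grads <- list()
  N <- dim(dxhat)[4]

  g <- dxhat * fw$xhat * (1 - fw$xhat)   # sigmoid backward (last layer)
  for (l in rev(seq_len(cfg$nb))) {
    if (l < cfg$nb) {
      g <- leaky_bwd(g, cache$dec_pre[[l]], cfg$slope)
      if (cfg$batchnorm) {
        bb <- bn_bwd(g, cache$dec_bn[[l]])
        grads[[sprintf("dec%d_g", l)]] <- bb$ggamma
        grads[[sprintf("dec%d_be", l)]] <- bb$gbeta
        g <- bb$gx
      }
    }
    grads[[sprintf("dec%d_b", l)]] <- apply(g, 3, sum)
    grads[[sprintf("dec%d_W", l)]] <-
      conv_bwd_weight(g, cache$dec_in[[l]], 3L, 2L, 1L)$gw
    g <- conv_fwd(g, par[[sprintf("dec%d_W", l)]],
                  numeric(dim(cache$dec_in[[l]])[3]), 2L, 1L)
  }

  if (!is.null(cfg$latent_dim)) {
    gh0 <- matrix(g, cfg$dflat, N)
    gpre0 <- leaky_bwd(gh0, cache$dec_pre0, cfg$slope)
    grads$dec_fc_W <- gpre0 %*% t(cache$Z)
    grads$dec_fc_b <- rowSums(gpre0)
    dZ <- t(par$dec_fc_W) %*% gpre0
  } else {
    dZ <- matrix(g, cfg$d_z, N)
  }
  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra

  if (cfg$kind == "vae") {
    dMU <- dZ
    dLV <- if (!is.null(fw$EPS)) dZ * fw$EPS * 0.5 * cache$SIG
           else matrix(0, cfg$d_z, N)
    if (!is.null(dMU_extra)) dMU <- dMU + dMU_extra
    if (!is.null(dLV_extra)) dLV <- dLV + dLV_extra
    dLV <- dLV * cache$lv_active
    if (!is.null(cfg$latent_dim)) {
      grads$enc_mu_W <- dMU %*% t(cache$zf)
      grads$enc_mu_b <- rowSums(dMU)
      grads$enc_lv_W <- dLV %*% t(cache$zf)
      grads$enc_lv_b <- rowSums(dLV)
      gzf <- t(par$enc_mu_W) %*% dMU + t(par$enc_lv_W) %*% dLV
    } else {
      fd <- cache$featdim
      dmu4 <- array(dMU, dim = fd)
      dlv4 <- array(dLV, dim = fd)
      feat <- array(cache$zf, dim = fd)
      gm <- conv_bwd_weight(feat, dmu4, 1L, 1L, 0L)
      gl <- conv_bwd_weight(feat, dlv4, 1L, 1L, 0L)
      grads$enc_mu_W <- gm$gw; grads$enc_mu_b <- gm$gb
      grads$enc_lv_W <- gl$gw; grads$enc_lv_b <- gl$gb
      g4 <- conv_bwd_input(dmu4, par$enc_mu_W, 1L, 0L, fd[1], fd[2]) +
            conv_bwd_input(dlv4, par$enc_lv_W, 1L, 0L, fd[1], fd[2])
      gzf <- matrix(g4, cfg$dflat, N)
    }
  } else if (!is.null(cfg$latent_dim)) {
    grads$enc_fc_W <- dZ %*% t(cache$zf)
    grads$enc_fc_b <- rowSums(dZ)
    gzf <- t(par$enc_fc_W) %*% dZ
  } else {
    gzf <- dZ
  }

  g <- array(gzf, dim = cache$featdim)
  for (l in rev(seq_len(cfg$nb))) {
    g <- leaky_bwd(g, cache$pre[[l]], cfg$slope)
    if (cfg$batchnorm) {
      bb <- bn_bwd(g, cache$bn[[l]])
      grads[[sprintf("enc%d_g", l)]] <- bb$ggamma
      grads[[sprintf("enc%d_be", l)]] <- bb$gbeta
      g <- bb$gx
    }
    gw <- conv_bwd_weight(cache$conv_in[[l]], g, 3L, 2L, 1L)
    grads[[sprintf("enc%d_W", l)]] <- gw$gw
    grads[[sprintf("enc%d_b", l)]] <- gw$gb
    if (l > 1) {
      din <- dim(cache$conv_in[[l]])
      g <- conv_bwd_input(g, par[[sprintf("enc%d_W", l)]], 2L, 1L,
                          din[1], din[2])
    }
  }
  grads
}
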