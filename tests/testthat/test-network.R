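# Encoder/decoder contracts and backbone parity across model variants.

test_that("encoding yields configuration-sized, deterministic latent codes", {
  fit <- tiny_fit("ae")
  img <- tiny_dataset()$val[[1]]
  z <- encode(fit, img)
  expect_length(z, 32)
  expect_identical(z, encode(fit, img))
  img2 <- tiny_dataset(seed = 99)$val[[1]]
  expect_false(isTRUE(all.equal(z, encode(fit, img2))))
  expect_error(encode(fit, matrix(0.5, 31, 31)), class = "aedetect_invalid")
})

test_that("the variational encoder returns a positive-sigma posterior", {
  fit <- tiny_fit("vae")
  enc <- encode(fit, tiny_dataset()$val[[1]])
  expect_named(enc, c("z", "mu", "sigma"))
  expect_length(enc$mu, 32)
  expect_true(all(enc$sigma > 0))
  expect_identical(enc$z, enc$mu)   # inference uses the posterior mean
})

test_that("decoded images have the input size with all pixels in (0,1)", {
  fit <- tiny_fit("ae")
  z <- rnorm(32) * 5
  img <- decode(fit, z)
  expect_equal(dim(img), c(32, 32))
  expect_true(min(img) > 0 && max(img) < 1)
  # extreme latent inputs still map inside the open unit interval
  extreme <- decode(fit, rep(1e4, 32))
  expect_true(all(is.finite(extreme)))
  expect_true(min(extreme) >= 0 && max(extreme) <= 1)
  expect_error(decode(fit, rnorm(31)), class = "aedetect_invalid")
})

test_that("reconstruction reduces L1 loss relative to the untrained net", {
  # stochastic smoke contract: majority of seeds must improve
  ds <- tiny_dataset(50, 2, 2)
  ok <- 0
  for (s in 1:3) {
    trained <- anomaly_autoencoder(ds, "ae", epochs = 5, seed = s,
                                   augment_gamma = FALSE)
    if (trained$history$loss[5] < trained$history$loss[1]) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("all three variants share an identical conv backbone", {
  counts <- vapply(c("ae", "vae", "swae"), function(k) {
    cfg <- aedetect:::net_config(k, c(32, 32, 1), c(8, 16, 32, 64), 32)
    net <- aedetect:::with_seed(1, aedetect:::init_network(cfg))
    aedetect:::n_conv_parameters(net)
  }, 0L)
  expect_equal(length(unique(counts)), 1L)
})

test_that("spatial (no-reduction) bottlenecks work for all variants", {
  ds <- tiny_dataset(8, 2, 2, size = 16)
  for (k in c("ae", "vae", "swae")) {
    fit <- anomaly_autoencoder(ds, k, epochs = 2, latent_dim = NULL,
                               channels = c(4, 8), seed = 1,
                               augment_gamma = FALSE)
    expect_true(all(is.finite(fit$history$loss)))
    rec <- predict(fit, ds$val[[1]], type = "reconstruction")
    expect_equal(dim(rec), c(16, 16))
    expect_true(min(rec) > 0 && max(rec) < 1)
  }
})
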