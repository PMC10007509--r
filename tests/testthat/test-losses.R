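# Loss components: reconstruction errors, Gaussian KLD, reparameterization,
# sliced-Wasserstein distance.

test_that("L1 and MSE losses match hand values and basic identities", {
  expect_equal(l1_loss(c(0, 0.5), c(0.25, 0.25)), 0.5)
  expect_equal(l1_loss(c(0, 0.5), c(0.25, 0.25), reduction = "mean"), 0.25)
  expect_equal(l1_loss(matrix(0.3, 2, 2), matrix(0.3, 2, 2)), 0)
  x <- matrix(runif(9), 3); y <- matrix(runif(9), 3)
  expect_equal(l1_loss(x, y), l1_loss(y, x))
  expect_equal(mse_loss(c(0, 1), c(1, 1)), 0.5)
  expect_equal(mse_loss(x, x), 0)
  expect_lte(mse_loss(x, y), max(abs(x - y))^2)
  expect_error(l1_loss(1:3, 1:2), class = "aedetect_invalid")
  expect_error(mse_loss(matrix(1, 2, 2), matrix(1, 2, 3)),
               class = "aedetect_invalid")
})

test_that("Gaussian KLD matches closed-form hand values", {
  expect_equal(kld_gaussian(0, 1), 0)
  expect_equal(kld_gaussian(1, 1), 0.5)
  expect_equal(kld_gaussian(0, sqrt(2)), 0.5 * (1 - log(2)) + 0.5 * (2 - 1) - 0.5)
  # explicit: -1/2 (1 + log 2 - 0 - 2) = (1 - log 2)/2 + ... check directly
  expect_equal(kld_gaussian(0, sqrt(2)), -0.5 * (1 + log(2) - 0 - 2))
  expect_gte(kld_gaussian(runif(5, -2, 2), runif(5, 0.5, 2)), 0)
  expect_error(kld_gaussian(0, 0), class = "aedetect_invalid")
  expect_error(kld_gaussian(c(0, 0), 1), class = "aedetect_invalid")
})

test_that("KLD agrees with a Monte-Carlo log-density-ratio estimate", {
  # E_q[log q(z) - log p(z)] estimated by sampling q = N(mu, sigma^2)
  set.seed(42)
  for (rep in 1:5) {
    mu <- runif(3, -2, 2); sigma <- runif(3, 0.5, 2)
    z <- matrix(rnorm(3 * 2e5, mean = mu, sd = sigma), nrow = 3)
    mc <- mean(colSums(dnorm(z, mu, sigma, log = TRUE) -
                       dnorm(z, 0, 1, log = TRUE)))
    expect_equal(kld_gaussian(mu, sigma), mc, tolerance = 0.02)
  }
})

test_that("reparameterization has the right moments and determinism", {
  mu <- rep(0, 10); sig <- rep(1, 10)
  z <- reparameterize(rep(0, 1e5), rep(1, 1e5), seed = 1)
  expect_lt(abs(mean(z)), 3 / sqrt(1e5))
  expect_lt(abs(sd(z) - 1), 0.02)
  expect_identical(reparameterize(mu, sig, seed = 3),
                   reparameterize(mu, sig, seed = 3))
  z0 <- reparameterize(c(1, 2), c(1e-12, 1e-12), seed = 1)
  expect_lt(max(abs(z0 - c(1, 2))), 1e-6)
  expect_error(reparameterize(0, 0), class = "aedetect_invalid")
})

test_that("sliced-Wasserstein distance matches 1-D and point-mass oracles", {
  # identical sets -> 0 for any projection count
  A <- matrix(rnorm(20), 10, 2)
  expect_equal(sliced_wasserstein(A, A, n_projections = 3, seed = 1), 0)
  # 1-D: sort-matching closed form, independent of direction count
  expect_equal(sliced_wasserstein(c(0, 2), c(1, 3), n_projections = 7), 1)
  # point masses in d = 2: E[(theta . delta)^2] = |delta|^2 / 2
  v <- sliced_wasserstein(matrix(c(1, 0), 1), matrix(c(0, 0), 1),
                          n_projections = 1e5, seed = 2)
  expect_equal(v, 0.5, tolerance = 0.02)
  # symmetry under the same projection set
  B <- matrix(rnorm(20), 10, 2)
  expect_equal(sliced_wasserstein(A, B, 64, seed = 5),
               sliced_wasserstein(B, A, 64, seed = 5))
  expect_error(sliced_wasserstein(matrix(1, 2, 1), matrix(1, 3, 1)),
               class = "aedetect_invalid")
  expect_error(sliced_wasserstein(1, 1, power = 1), class = "aedetect_invalid")
})

test_that("1-D SWD equals the exact sorted W2^2 on random pairs", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(1:64, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(sliced_wasserstein(a, b, n_projections = 5, seed = i),
                 mean((sort(a) - sort(b))^2), tolerance = 1e-9)
  }
})

test_that("SWD Monte-Carlo error shrinks like 1/sqrt(projections)", {
  set.seed(4)
  A <- matrix(rnorm(64), 32, 2); B <- matrix(rnorm(64) + 1, 32, 2)
  est <- function(L) vapply(1:40, function(s)
    sliced_wasserstein(A, B, n_projections = L, seed = 1000 + s), 0)
  ratio <- sd(est(16)) / sd(est(64))
  expect_gt(ratio, 2 * 0.75)
  expect_lt(ratio, 2 * 1.25)
})

test_that("composite losses are the sum of their parts", {
  x <- matrix(runif(16), 4); xh <- matrix(runif(16), 4)
  mu <- rnorm(3); sig <- runif(3, 0.5, 2)
  expect_equal(vae_loss(x, xh, mu, sig, beta = 2),
               l1_loss(x, xh) + 2 * kld_gaussian(mu, sig), tolerance = 1e-9)
  expect_equal(vae_loss(x, xh, mu, sig, beta = 0), l1_loss(x, xh))
  expect_equal(vae_loss(x, x, rep(0, 3), rep(1, 3)), 0)

  z <- matrix(rnorm(8), 4, 2)
  p <- matrix(rnorm(8), 4, 2)
  expect_equal(swae_loss(x, xh, z, lambda = 3, n_projections = 10, seed = 2,
                         prior_sample = p),
               mse_loss(x, xh) +
                 3 * sliced_wasserstein(z, p, 10, seed = 2), tolerance = 1e-9)
  expect_equal(swae_loss(x, xh, z, lambda = 0), mse_loss(x, xh))
  expect_equal(swae_loss(x, x, z, prior_sample = z), 0)
})
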