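# Anomaly maps, the ReLU-max validation threshold, binarization.

test_that("anomaly maps are symmetric absolute differences in [0,1]", {
  expect_equal(anomaly_map(matrix(0.8), matrix(0.5)), matrix(0.3))
  x <- matrix(runif(16), 4); y <- matrix(runif(16), 4)
  expect_equal(anomaly_map(x, y), anomaly_map(y, x))
  expect_equal(anomaly_map(x, x), matrix(0, 4, 4))
  expect_true(max(anomaly_map(x, y)) <= 1)
  # 3-channel inputs reduce to the channel-mean plane; replicated
  # channels match single-channel behavior
  x3 <- array(rep(x, 3), c(4, 4, 3)); y3 <- array(rep(y, 3), c(4, 4, 3))
  expect_equal(anomaly_map(x3, y3), anomaly_map(x, y))
  expect_error(anomaly_map(x, matrix(0.1, 2, 2)), class = "aedetect_invalid")
})

test_that("the ReLU-max threshold reproduces the worked two-pixel case", {
  m1 <- matrix(c(0.1, 0.3), 1)
  m2 <- matrix(c(0.5, 0.1), 1)
  # mean map (0.3, 0.2); rectified residuals (0, 0.1) and (0.2, 0);
  # maximum 0.2
  expect_equal(as.numeric(find_threshold(list(m1, m2))), 0.2)
  # identical maps leave no residual
  expect_equal(as.numeric(find_threshold(list(m1, m1, m1))), 0)
  expect_error(find_threshold(list()), class = "aedetect_invalid")
  expect_error(find_threshold(list(m1, matrix(0.1, 2, 2))),
               class = "aedetect_invalid")
})

test_that("the ReLU-max threshold agrees with a brute-force recount", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    maps <- replicate(n, matrix(runif(24, 0, 0.6), 4, 6), simplify = FALSE)
    th <- as.numeric(find_threshold(maps))
    # brute force: per-pixel mean, then max positive residual
    avg <- apply(simplify2array(maps), c(1, 2), mean)
    brute <- max(0, unlist(lapply(maps, function(m) max(m - avg))))
    expect_equal(th, brute, tolerance = 1e-12)
    expect_gte(th, 0)
  }
})

test_that("the scalar-average variant measures against the grand mean", {
  m1 <- matrix(c(0.1, 0.3), 1)
  m2 <- matrix(c(0.5, 0.1), 1)
  expect_equal(as.numeric(find_threshold(list(m1, m2), average = "scalar")),
               0.5 - 0.25)
})

test_that("binarization is a strict comparison", {
  expect_equal(binarize(matrix(c(0.1, 0.3), 1), 0.2),
               matrix(c(0L, 1L), 1))
  m <- matrix(runif(16), 4)
  expect_equal(binarize(m, 1), matrix(0L, 4, 4))
  # threshold 0: exactly the nonzero pixels
  m0 <- matrix(c(0, 0.2, 0, 0.7), 2)
  expect_equal(binarize(m0, 0), matrix(as.integer(m0 > 0), 2))
  # the maximizing pixel itself is not flagged at its own value
  expect_equal(binarize(m, max(m)), matrix(0L, 4, 4))
})

test_that("thresholds applied back to their validation maps flag nothing at the max", {
  set.seed(8)
  maps <- replicate(4, matrix(runif(36, 0, 0.5), 6), simplify = FALSE)
  th <- find_threshold(maps)
  avg <- Reduce(`+`, maps) / length(maps)
  resid <- lapply(maps, function(m) pmax(m - avg, 0))
  # strict ">" means the pixel achieving the maximum residual is NOT
  # flagged when its own residual map is binarized at the threshold
  flagged <- vapply(resid, function(r) sum(binarize(r, th)), 0)
  expect_true(all(flagged == 0 | vapply(resid, max, 0) > as.numeric(th)))
  imax <- which.max(vapply(resid, max, 0))
  expect_equal(sum(binarize(resid[[imax]], th)), 0)
})

test_that("detect composes reconstruction, map and mask deterministically", {
  fit <- tiny_fit("ae")
  img <- tiny_dataset()$test[[1]]$image
  det <- detect(fit, img, threshold = 0.2)
  expect_named(det, c("reconstruction", "map", "mask"))
  expect_equal(dim(det$mask), dim(img))
  expect_true(all(det$mask %in% c(0L, 1L)))
  expect_equal(det$map, anomaly_map(img, det$reconstruction))
  det2 <- detect(fit, img, threshold = 0.2)
  expect_identical(det$mask, det2$mask)
  # raising the threshold can only shrink the mask
  det3 <- detect(fit, img, threshold = 0.3)
  expect_true(all(det3$mask <= det$mask))
})

test_that("variational inference is deterministic unless sampling is requested", {
  fit <- tiny_fit("vae")
  img <- tiny_dataset()$test[[1]]$image
  r1 <- predict(fit, img, type = "reconstruction")
  r2 <- predict(fit, img, type = "reconstruction")
  expect_identical(r1, r2)
  rs <- predict(fit, img, type = "reconstruction", sample = TRUE, seed = 4)
  expect_false(identical(r1, rs))
  expect_identical(rs, predict(fit, img, type = "reconstruction",
                               sample = TRUE, seed = 4))
})
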