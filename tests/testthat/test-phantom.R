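# Synthetic phantom generator and preprocessing chain.

test_that("background fields respect range, determinism and seed sensitivity", {
  bg <- generate_background(64, 64, seed = 1, smoothness = 8)
  expect_equal(dim(bg), c(64, 64))
  expect_true(min(bg) >= 0.2 && max(bg) <= 0.8)
  expect_identical(bg, generate_background(64, 64, seed = 1, smoothness = 8))
  bg2 <- generate_background(64, 64, seed = 2, smoothness = 8)
  expect_gt(mean(bg != bg2), 0.01)
  expect_error(generate_background(4, 64), class = "aedetect_invalid")
  expect_error(generate_background(64, 64, smoothness = 0),
               class = "aedetect_invalid")
})

test_that("speckle is unit-mean multiplicative noise clipped to [0,1]", {
  img <- matrix(0.5, 100, 100)
  # zero-noise limit
  out <- apply_speckle(img, seed = 1, scale = 1e-9)
  expect_lt(max(abs(out - img)), 1e-6)
  # unit-mean check: mean of factor is 1, sd of the Rayleigh mixture at
  # scale s is s * sqrt((4 - pi) / pi); 3 standard errors at n = 1e4
  out <- apply_speckle(img, seed = 7, scale = 0.3)
  se <- 0.5 * 0.3 * sqrt((4 - pi) / pi) / sqrt(1e4)
  expect_lt(abs(mean(out) - 0.5), 3 * se)
  # clipping holds at any scale
  strong <- apply_speckle(matrix(0.9, 50, 50), seed = 2, scale = 1)
  expect_true(min(strong) >= 0 && max(strong) <= 1)
  expect_identical(apply_speckle(img, 3, 0.3), apply_speckle(img, 3, 0.3))
  expect_error(apply_speckle(img, 1, 0), class = "aedetect_invalid")
})

test_that("lesion insertion darkens the ellipse and masks its interior", {
  img <- matrix(0.6, 64, 64)
  spec <- lesion_spec(c(32, 32), c(10, 10), intensity_drop = 0.5,
                      edge_softness = 0)
  les <- insert_lesion(img, spec)
  expect_equal(les$image[32, 32], 0.3)
  expect_equal(les$image[1, 1], 0.6)
  # brute-force rasterization oracle for the mask
  oracle <- outer(1:64, 1:64, function(r, c)
    as.integer(((r - 32)^2 + (c - 32)^2) / 100 <= 1))
  expect_identical(les$mask, oracle)
  expect_gt(sum(les$mask), 0)
  # zero-drop lesion changes nothing but still marks the ellipse
  les0 <- insert_lesion(img, lesion_spec(c(32, 32), c(10, 10),
                                         intensity_drop = 0))
  expect_identical(les0$image, img)
  expect_identical(les0$mask, oracle)
  expect_error(insert_lesion(img, lesion_spec(c(5, 32), c(10, 10))),
               class = "aedetect_invalid")
})

test_that("generated datasets honor counts, determinism and mask invariants", {
  ds <- tiny_dataset(5, 2, 3, seed = 11)
  expect_length(ds$train, 5)
  expect_length(ds$val, 2)
  expect_length(ds$test, 3)
  for (im in c(ds$train, ds$val)) {
    expect_true(min(im) >= 0 && max(im) <= 1)
    expect_true(all(is.finite(im)))
  }
  for (item in ds$test) {
    expect_true(all(item$mask %in% c(0L, 1L)))
    expect_gt(sum(item$mask), 0)
    expect_equal(item$area_px, sum(item$mask))
  }
  expect_identical(unclass(ds), unclass(tiny_dataset(5, 2, 3, seed = 11)))
  expect_false(identical(ds$train[[1]], tiny_dataset(5, 2, 3, seed = 12)$train[[1]]))
  expect_error(generate_dataset(1, 1, 1, height = 32, width = 32,
                                lesion_area = c(50, 400)),
               class = "aedetect_invalid")
  expect_error(generate_dataset(0, 1, 1), class = "aedetect_invalid")
})

test_that("lesions are darker than their surroundings in every abnormal image", {
  ds <- tiny_dataset(1, 1, 8, seed = 3, lesion_softness = 0)
  for (item in ds$test) {
    inside <- mean(item$image[item$mask == 1])
    # one-pixel-dilated annulus around the mask
    m <- item$mask
    dil <- m
    dil[-1, ] <- pmax(dil[-1, ], m[-nrow(m), ])
    dil[-nrow(m), ] <- pmax(dil[-nrow(m), ], m[-1, ])
    dil[, -1] <- pmax(dil[, -1], m[, -ncol(m)])
    dil[, -ncol(m)] <- pmax(dil[, -ncol(m)], m[, -1])
    ring <- dil == 1 & m == 0
    expect_lt(inside, mean(item$image[ring]))
  }
})

test_that("pixel normalization maps 0-255 to [0,1] exactly", {
  expect_equal(normalize_pixels(matrix(255, 2, 2)), matrix(1, 2, 2))
  expect_equal(normalize_pixels(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(normalize_pixels(matrix(51, 1, 1)), matrix(0.2, 1, 1))
  expect_error(normalize_pixels(matrix(256, 1, 1)), class = "aedetect_invalid")
  expect_error(normalize_pixels(matrix(-1, 1, 1)), class = "aedetect_invalid")
})

test_that("gaussian denoising matches an explicit kernel and conserves mass", {
  img <- matrix(runif(25), 5, 5)
  expect_identical(gaussian_denoise(img, 0), img)
  # constants are fixed points
  cst <- matrix(0.4, 8, 8)
  expect_equal(gaussian_denoise(cst, 2), cst, tolerance = 1e-12)
  # impulse response: center value equals the kernel center weight
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  sm <- gaussian_denoise(imp, 1)
  r <- 3  # ceiling(3 * sigma)
  k1 <- exp(-(-r:r)^2 / 2); k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  expect_equal(sm[5, 5], kern[r + 1, r + 1], tolerance = 1e-12)
  expect_equal(sm[3:7, 3:7], kern[2:6, 2:6], tolerance = 1e-12)
  # reflective padding conserves total intensity for separable kernels
  expect_equal(sum(gaussian_denoise(img, 1.5)), sum(img), tolerance = 1e-9)
  expect_error(gaussian_denoise(img, -1), class = "aedetect_invalid")
})

test_that("gamma correction is the power map with 0.5/1.5 augmentation", {
  img <- matrix(0.25, 3, 3)
  expect_identical(gamma_correct(img, 1), img)
  expect_equal(gamma_correct(img, 0.5), matrix(0.5, 3, 3))
  expect_error(gamma_correct(img, 0), class = "aedetect_invalid")
  imgs <- list(matrix(0.25, 2, 2), matrix(0.81, 2, 2))
  aug <- augment_gamma(imgs)            # default gammas 0.5 and 1.5
  expect_length(aug, 6)
  expect_equal(aug[[3]], matrix(0.5, 2, 2))
  expect_equal(aug[[6]], matrix(0.81^1.5, 2, 2))
})
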