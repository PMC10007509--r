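# Evaluation: RMSE, overlap metrics, sweeps, size stratification.

test_that("RMSE matches hand values", {
  expect_equal(rmse(c(0, 1), c(1, 1)), sqrt(0.5))
  x <- matrix(runif(16), 4)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x, x + 0.1), 0.1)
  expect_error(rmse(1:4, 1:5), class = "aedetect_invalid")
})

test_that("dataset RMSE is the mean of per-image RMSE, order-invariant", {
  fit <- tiny_fit("ae")
  ds <- tiny_dataset()
  imgs <- ds$val
  one <- dataset_rmse(fit, imgs[1])
  expect_equal(as.numeric(one), rmse(imgs[[1]],
               predict(fit, imgs[[1]], type = "reconstruction")))
  all3 <- dataset_rmse(fit, imgs[1:3])
  expect_equal(as.numeric(all3), mean(attr(all3, "per_image")))
  perm <- dataset_rmse(fit, imgs[c(3, 1, 2)])
  expect_equal(as.numeric(all3), as.numeric(perm))
  expect_error(dataset_rmse(fit, list()), class = "aedetect_invalid")
})

test_that("confusion counts cross-tabulate pixels exactly", {
  p <- matrix(c(1, 1, 0, 0), 2); t <- matrix(c(1, 0, 1, 0), 2)
  cc <- confusion_counts(p, t)
  expect_equal(cc, c(TP = 1, FP = 1, FN = 1, TN = 1))
  ones <- matrix(1, 2, 2)
  expect_equal(confusion_counts(ones, ones), c(TP = 4, FP = 0, FN = 0, TN = 0))
  # swapping arguments swaps FP and FN
  cc2 <- confusion_counts(t, p)
  expect_equal(cc2[["FP"]], cc[["FN"]])
  expect_equal(cc2[["FN"]], cc[["FP"]])
  expect_equal(cc2[["TP"]], cc[["TP"]])
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(1, 2, 2)),
               class = "aedetect_invalid")
})

test_that("overlap metrics follow the printed formulas and conventions", {
  m <- overlap_metrics(c(TP = 1, FP = 1, FN = 1, TN = 1))
  expect_equal(m$dice, 0.5)
  expect_equal(m$tpr, 0.5)
  expect_equal(m$fpr, 0.5)
  perfect <- overlap_metrics(c(TP = 7, FP = 0, FN = 0, TN = 9))
  expect_equal(perfect$dice, 1); expect_equal(perfect$tpr, 1)
  expect_equal(perfect$fpr, 0)
  # both masks empty: agreement; truth-empty TPR undefined
  empty <- overlap_metrics(c(TP = 0, FP = 0, FN = 0, TN = 16))
  expect_equal(empty$dice, 1)
  expect_true(is.na(empty$tpr))
  expect_equal(empty$fpr, 0)
  fp_only <- overlap_metrics(c(TP = 0, FP = 3, FN = 0, TN = 13))
  expect_equal(fp_only$dice, 0)
  expect_true(is.na(fp_only$tpr))
  expect_equal(fp_only$fpr, 3 / 16)
})

test_that("Dice identity 2*ppv*tpr/(ppv+tpr) holds on random counts", {
  set.seed(12)
  for (i in 1:100) {
    cc <- c(TP = sample(1:50, 1), FP = sample(1:50, 1),
            FN = sample(1:50, 1), TN = sample(1:50, 1))
    m <- overlap_metrics(cc)
    ppv <- cc[["TP"]] / (cc[["TP"]] + cc[["FP"]])
    expect_equal(m$dice, 2 * ppv * m$tpr / (ppv + m$tpr), tolerance = 1e-12)
  }
})

test_that("metrics equal a brute-force per-pixel recount on random masks", {
  set.seed(21)
  for (i in 1:100) {
    p <- random_mask(6, 6); t <- random_mask(6, 6)
    cc <- confusion_counts(p, t)
    brute <- c(TP = 0, FP = 0, FN = 0, TN = 0)
    for (r in 1:6) for (c in 1:6) {
      key <- if (p[r, c] == 1 && t[r, c] == 1) "TP"
        else if (p[r, c] == 1) "FP"
        else if (t[r, c] == 1) "FN" else "TN"
      brute[key] <- brute[key] + 1
    }
    expect_equal(cc, brute)
    expect_equal(sum(cc), 36)
  }
})

test_that("threshold sweeps are monotone in TPR and FPR", {
  fit <- tiny_fit("ae")
  ds <- tiny_dataset()
  sw <- threshold_sweep(fit, ds$test, thresholds = c(0.3, 0.1, 0.2))
  expect_equal(sw$threshold, c(0.1, 0.2, 0.3))   # sorted ascending
  expect_true(all(diff(sw$tpr) <= 1e-12))
  expect_true(all(diff(sw$fpr) <= 1e-12))
  expect_true(all(diff(sw$tpr_micro) <= 1e-12))
  # single image: sweep rows equal that image's metrics
  sw1 <- threshold_sweep(fit, ds$test[1], thresholds = 0.2)
  rec <- metric_records(fit, ds$test[1], threshold = 0.2)
  expect_equal(sw1$dice, rec$dice)
  expect_equal(sw1$tpr, rec$tpr)
})

test_that("size stratification partitions records into quantile bins", {
  rec <- data.frame(id = 1:4, dice = c(0.2, 0.4, 0.6, 0.8),
                    tpr = c(0.1, 0.3, 0.5, 0.7), fpr = 0,
                    lesion_area_px = c(10, 20, 30, 40), threshold = 0.2)
  s2 <- size_stratified_metrics(rec, n_bins = 2)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$n, c(2, 2))
  expect_equal(s2$mean_dice, c(0.3, 0.7))
  expect_equal(s2$mean_tpr, c(0.2, 0.6))
  s1 <- size_stratified_metrics(rec, n_bins = 1)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$mean_dice, 0.5)
  expect_equal(s1$n, 4)
  # counts always sum to the record count
  set.seed(2)
  rec2 <- data.frame(dice = runif(17), tpr = runif(17), fpr = 0,
                     lesion_area_px = sample(30:200, 17), threshold = 0.2)
  expect_equal(sum(size_stratified_metrics(rec2, 5)$n), 17)
  expect_warning(size_stratified_metrics(rec[1, ], n_bins = 3),
                 "merged")
})

test_that("the cross-model report has one row per model and threshold", {
  ds <- tiny_dataset()
  fits <- list(ae = tiny_fit("ae"), vae = tiny_fit("vae"))
  rep <- compare_models(fits, ds, thresholds = c(0.1, 0.3))
  expect_equal(nrow(rep), 2 * 3)   # 2 fixed + relu-max, per model
  expect_setequal(unique(rep$model), c("ae", "vae"))
  expect_true(all(c("val_rmse", "test_rmse", "dice", "tpr", "fpr",
                    "relu_max") %in% names(rep)))
  expect_true(all(rep$val_rmse > 0))
  rep2 <- compare_models(fits, ds, thresholds = c(0.1, 0.3))
  expect_identical(rep, rep2)
})
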