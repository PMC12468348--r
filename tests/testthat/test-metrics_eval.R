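# Confusion counts, rate metrics, image-quality measures and ROC AUC.

test_that("confusion_counts enumerates one-vs-rest counts correctly", {
  cc <- confusion_counts(c(0, 0, 1), c(0, 1, 1))
  expect_equal(cc$tp[["0"]], 1); expect_equal(cc$fn[["0"]], 1)
  expect_equal(cc$fp[["0"]], 0); expect_equal(cc$tn[["0"]], 1)
  expect_equal(cc$tp[["1"]], 1); expect_equal(cc$fp[["1"]], 1)
  expect_equal(cc$fn[["1"]], 0); expect_equal(cc$tn[["1"]], 1)
  # partition identity per class
  set.seed(3)
  yt <- sample(0:4, 60, TRUE); yp <- sample(0:4, 60, TRUE)
  cc2 <- confusion_counts(yt, yp)
  expect_true(all(cc2$tp + cc2$tn + cc2$fp + cc2$fn == 60))
  expect_equal(unname(rowSums(cc2$matrix)),
               as.integer(table(factor(yt, levels = 0:4))))
  # perfect prediction is diagonal
  cc3 <- confusion_counts(yt, yt)
  expect_equal(sum(cc3$matrix) - sum(diag(cc3$matrix)), 0L)
  expect_error(confusion_counts(1:3, 1:2), "length")
  expect_error(confusion_counts(c(0, 5), c(0, 0)), "0-4")
})

test_that("classification_metrics follows the count formulas", {
  # single-class worked example embedded in a 5-class table (class 0)
  yt <- c(rep(0, 9), rep(1, 11))
  yp <- c(rep(0, 8), 1, rep(1, 9), 0, 0)
  cc <- confusion_counts(yt, yp)
  expect_equal(cc$tp[["0"]], 8); expect_equal(cc$fp[["0"]], 2)
  expect_equal(cc$fn[["0"]], 1); expect_equal(cc$tn[["0"]], 9)
  suppressWarnings(rep <- classification_metrics(cc))
  row0 <- rep$per_class[1, ]
  expect_equal(row0$precision, 0.8)
  expect_equal(row0$recall, 8 / 9)
  expect_equal(row0$accuracy, 17 / 20)
  expect_equal(row0$f1, 2 * (0.8 * 8 / 9) / (0.8 + 8 / 9))
  expect_equal(row0$specificity, 9 / 11)
  # perfect classifier: everything 1 (absent classes give NaN ratios)
  cc2 <- confusion_counts(rep(0:4, each = 4), rep(0:4, each = 4))
  rep2 <- classification_metrics(cc2)
  expect_equal(rep2$overall_accuracy, 1)
  expect_true(all(rep2$per_class$f1 == 1))
  # degenerate single-prediction classifier triggers the NaN policy
  cc3 <- confusion_counts(rep(0:4, each = 2), rep(0L, 10))
  expect_warning(rep3 <- classification_metrics(cc3), "undefined")
  expect_true(is.nan(rep3$per_class$precision[2]))
  expect_equal(rep3$overall_accuracy, sum(diag(cc3$matrix)) / 10)
})

test_that("overall accuracy equals trace/n and macro-F1 is diagonal-bound", {
  set.seed(4)
  for (i in 1:5) {
    yt <- sample(0:4, 50, TRUE)
    yp <- ifelse(runif(50) < 0.7, yt, sample(0:4, 50, TRUE))
    cc <- confusion_counts(yt, yp)
    suppressWarnings(r <- classification_metrics(cc))
    expect_equal(r$overall_accuracy, sum(diag(cc$matrix)) / 50)
    expect_lte(max(r$macro["f1"], na.rm = TRUE), 1)
    if (isTRUE(all.equal(r$macro[["f1"]], 1)))
      expect_equal(sum(cc$matrix) - sum(diag(cc$matrix)), 0L)
  }
})

test_that("MSE/PSNR follow the printed formulas", {
  a <- rand_image(6, 6, seed = 11)
  expect_equal(image_mse(a, a), 0)
  expect_equal(psnr(a, a), Inf)
  b <- gray_image(a$pixels + 1, c(0, 256))
  expect_equal(image_mse(a, b), 1)
  expect_equal(psnr(a, b, max_i = 255), 10 * log10(255^2), tolerance = 1e-12)
  expect_equal(10 * log10(255^2), 48.13, tolerance = 0.01)
  # doubling the MSE costs 10*log10(2) dB
  c2 <- gray_image(a$pixels + sqrt(2), c(0, 260))
  expect_equal(psnr(a, b, 255) - psnr(a, c2, 255), 10 * log10(2),
               tolerance = 1e-9)
  expect_error(image_mse(a, rand_image(3, 3)), "shape")
})

test_that("global-moment SSIM matches the raw-moment oracle", {
  set.seed(12)
  x <- matrix(runif(25, 0, 255), 5, 5)
  y <- matrix(runif(25, 0, 255), 5, 5)
  L <- 255
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean(x^2) - mx^2; vy <- mean(y^2) - my^2
  cxy <- mean(x * y) - mx * my
  oracle <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  expect_equal(ssim(x, y, L = 255), oracle, tolerance = 1e-12)
  expect_equal(ssim(x, x, L = 255), 1, tolerance = 1e-12)
  expect_equal(ssim(x, y, L = 255), ssim(y, x, L = 255))
  gi <- gray_image(x); gj <- gray_image(y)
  expect_equal(ssim(gi, gj), oracle)         # L from the declared range
  # windowed variant returns a sane, generally different value
  xw <- matrix(runif(15 * 15, 0, 255), 15, 15)
  yw <- xw + rnorm(225, sd = 12)
  expect_lt(abs(ssim(xw, pmin(pmax(yw, 0), 255), L = 255, window = 11)), 1.0001)
})

test_that("roc_auc equals the concordant-pair-counting oracle", {
  # perfectly separated
  s <- matrix(0, 6, 5); s[, 1] <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.0)
  y <- c(0, 0, 0, 1, 2, 3)
  expect_equal(suppressWarnings(roc_auc(s, y))$per_class[["class0"]], 1)
  # all ties give 0.5
  s2 <- matrix(0.5, 6, 5)
  expect_equal(suppressWarnings(roc_auc(s2, y)$per_class[["class0"]]), 0.5)
  # 10-sample toy vs exhaustive pair enumeration
  set.seed(13)
  y3 <- c(rep(0, 4), rep(2, 6))
  sc <- matrix(runif(50), 10, 5)
  sc[3, 1] <- sc[7, 1]                        # force one tie
  a <- suppressWarnings(roc_auc(sc, y3)$per_class[["class0"]])
  pos <- which(y3 == 0); neg <- which(y3 != 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (sc[i, 1] > sc[j, 1]) + 0.5 * (sc[i, 1] == sc[j, 1])
  expect_equal(a, tot / (length(pos) * length(neg)), tolerance = 1e-12)
  # invariance under strictly increasing transforms
  a2 <- suppressWarnings(roc_auc(exp(3 * sc), y3)$per_class[["class0"]])
  expect_equal(a, a2)
  # class without positives is skipped with a warning
  w <- capture_warnings(roc_auc(sc, y3))
  expect_true(any(grepl("no positive", w)))
})

test_that("evaluate_predictions assembles the full report", {
  set.seed(14)
  yt <- rep(0:4, each = 6)
  yp <- ifelse(runif(30) < 0.8, yt, sample(0:4, 30, TRUE))
  sc <- matrix(runif(150), 30, 5)
  for (i in 1:30) sc[i, yt[i] + 1] <- sc[i, yt[i] + 1] + 1
  sc <- sc / rowSums(sc)
  suppressWarnings(rep <- evaluate_predictions(yt, yp, sc))
  expect_s3_class(rep, "eval_report")
  expect_true(all(rep$auc$per_class > 0.5))
  expect_true(rep$overall_accuracy >= 0 && rep$overall_accuracy <= 1)
})
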