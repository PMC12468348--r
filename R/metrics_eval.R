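# Evaluation machinery: 5x5 confusion matrix with one-vs-rest counts, the
# standard rate metrics (accuracy, precision, recall, F1, specificity),
# image-quality measures (MSE, PSNR, global-moment SSIM), and one-vs-rest
# ROC AUC via the rank statistic.

#' Confusion counts for five-grade classification
#'
#' @param y_true,y_pred Integer grade vectors (0-4) of equal length.
#' @return A `confusion_counts`: `matrix` (5x5 counts, rows = true grade),
#'   and per-class one-vs-rest `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("confusion_counts: length mismatch")
  if (!length(y_true)) stop("confusion_counts: empty input")
  if (any(y_true < 0L | y_true > 4L | y_pred < 0L | y_pred > 4L))
    stop("confusion_counts: grades must be in 0-4")
  m <- table(factor(y_true, levels = 0:4), factor(y_pred, levels = 0:4))
  m <- matrix(as.integer(m), 5, 5, dimnames = list(true = 0:4, pred = 0:4))
  n <- length(y_true)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- n - tp - fp - fn
  structure(list(matrix = m, tp = tp, fp = fp, fn = fn, tn = tn, n = n),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion matrix (rows = true grade):\n")
  print(x$matrix)
  invisible(x)
}

.safe_ratio <- function(num, den, what) {
  out <- num / den
  if (any(den == 0)) {
    warning(sprintf("%s undefined (0/0) for class(es) %s; reported as NaN",
                    what, paste(which(den == 0) - 1L, collapse = ", ")),
            call. = FALSE)
    out[den == 0] <- NaN
  }
  out
}

#' Classification metrics from confusion counts
#'
#' Per-class one-vs-rest accuracy, precision, recall, F1 and specificity
#' following the standard count formulas (Acc = (TP+TN)/(TP+TN+FP+FN),
#' Prc = TP/(TP+FP), Rcl = TP/(TP+FN), F1 = 2 Prc Rcl/(Prc+Rcl),
#' Spc = TN/(TN+FP)), macro averages (unweighted mean over classes with
#' defined values), and the overall accuracy trace(matrix)/n. Undefined 0/0
#' ratios are reported as NaN with a warning.
#'
#' @param counts A `confusion_counts`.
#' @param average `"macro"` (default) or `"weighted"` (by true-class support).
#' @return An `eval_report` list with `per_class` (data frame), `macro`,
#'   `overall_accuracy`.
#' @export
classification_metrics <- function(counts, average = c("macro", "weighted")) {
  stopifnot(inherits(counts, "confusion_counts"))
  average <- match.arg(average)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  acc <- (tp + tn) / counts$n
  prc <- .safe_ratio(tp, tp + fp, "precision")
  rcl <- .safe_ratio(tp, tp + fn, "recall")
  f1 <- 2 * prc * rcl / (prc + rcl)
  f1[is.finite(prc) & is.finite(rcl) & (prc + rcl) == 0] <- 0
  spc <- .safe_ratio(tn, tn + fp, "specificity")
  per_class <- data.frame(grade = 0:4, accuracy = acc, precision = prc,
                          recall = rcl, f1 = f1, specificity = spc,
                          support = rowSums(counts$matrix))
  wts <- if (average == "macro") rep(1, 5) else per_class$support
  avg <- function(v) {
    ok <- is.finite(v)
    if (!any(ok)) return(NaN)
    sum(v[ok] * wts[ok]) / sum(wts[ok])
  }
  macro <- c(accuracy = avg(acc), precision = avg(prc), recall = avg(rcl),
             f1 = avg(f1), specificity = avg(spc))
  structure(list(per_class = per_class, macro = macro,
                 overall_accuracy = sum(diag(counts$matrix)) / counts$n,
                 average = average),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("overall accuracy: %.4f\n", x$overall_accuracy))
  print(round(x$per_class, 4))
  cat(sprintf("%s averages:\n", x$average))
  print(round(x$macro, 4))
  invisible(x)
}

.pix <- function(x) if (is_gray_image(x)) x$pixels else as.matrix(x)

#' Mean squared error between two images
#' @param x,y [gray_image]s or matrices of identical size.
#' @export
image_mse <- function(x, y) {
  px <- .pix(x); py <- .pix(y)
  if (!identical(dim(px), dim(py))) stop("image_mse: shape mismatch")
  mean((px - py)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(MAX_I^2 / MSE)` in dB; identical images give `Inf`. `max_i`
#' defaults to the declared dynamic-range maximum of `x` and is never
#' inferred from the data.
#'
#' @param x,y Images of identical size.
#' @param max_i Peak representable intensity.
#' @export
psnr <- function(x, y, max_i = NULL) {
  if (is.null(max_i)) {
    if (!is_gray_image(x)) stop("psnr: supply max_i for plain matrices")
    max_i <- x$dynamic_range[2] - min(0, x$dynamic_range[1])
  }
  m <- image_mse(x, y)
  if (m == 0) Inf else 10 * log10(max_i^2 / m)
}

#' Structural similarity (global-moment form)
#'
#' `((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))` with
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, all moments computed over the whole
#' image (population denominators). The common 11x11 sliding-window variant
#' is available via `window = 11`; it generally yields lower values.
#'
#' @param x,y Images of identical size (at least 2 pixels).
#' @param L Dynamic range span; defaults to the declared range of `x`.
#' @param window `NULL` (default, global moments) or an odd window side for
#'   the sliding mean-SSIM variant.
#' @export
ssim <- function(x, y, L = NULL, window = NULL) {
  px <- .pix(x); py <- .pix(y)
  if (!identical(dim(px), dim(py))) stop("ssim: shape mismatch")
  if (length(px) < 2L) stop("ssim: need at least 2 pixels")
  if (is.null(L)) {
    if (!is_gray_image(x)) stop("ssim: supply L for plain matrices")
    L <- x$dynamic_range[2] - x$dynamic_range[1]
  }
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  stat <- function(ax, ay) {
    mx <- mean(ax); my <- mean(ay)
    vx <- mean(ax^2) - mx^2; vy <- mean(ay^2) - my^2
    cxy <- mean(ax * ay) - mx * my
    ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  if (is.null(window)) return(stat(px, py))
  r <- (window - 1L) %/% 2L
  H <- nrow(px); W <- ncol(px)
  vals <- c()
  for (i in seq(1L + r, H - r)) {
    for (j in seq(1L + r, W - r)) {
      vals <- c(vals, stat(px[(i - r):(i + r), (j - r):(j + r)],
                           py[(i - r):(i + r), (j - r):(j + r)]))
    }
  }
  mean(vals)
}

#' Combined image-quality metrics
#' @param x,y Images of identical size.
#' @param max_i Peak intensity for PSNR (defaults from `x`).
#' @return List with `mse`, `psnr`, `ssim`.
#' @export
quality_metrics <- function(x, y, max_i = NULL) {
  list(mse = image_mse(x, y), psnr = psnr(x, y, max_i), ssim = ssim(x, y))
}

#' One-vs-rest ROC AUC
#'
#' Computed with the rank statistic (equivalent to trapezoidal ROC
#' integration with ties counted half). Classes with no positive or no
#' negative samples are skipped with a warning.
#'
#' @param scores N x 5 matrix of per-class scores (e.g. softmax
#'   probabilities).
#' @param y_true Integer grades 0-4, length N.
#' @return List with `per_class` (length-5, NA where undefined) and `macro`.
#' @export
roc_auc <- function(scores, y_true) {
  scores <- as.matrix(scores)
  y_true <- as.integer(y_true)
  if (nrow(scores) != length(y_true)) stop("roc_auc: length mismatch")
  auc <- rep(NA_real_, 5)
  for (k in 0:4) {
    pos <- y_true == k
    np <- sum(pos); nn <- sum(!pos)
    if (np == 0L || nn == 0L) {
      warning(sprintf("roc_auc: class %d has no %s samples; skipped", k,
                      if (np == 0L) "positive" else "negative"), call. = FALSE)
      next
    }
    r <- rank(scores[, k + 1L])
    auc[k + 1L] <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  }
  names(auc) <- paste0("class", 0:4)
  list(per_class = auc, macro = mean(auc, na.rm = TRUE))
}

#' Evaluate predictions against ground truth
#'
#' Convenience wrapper building the confusion matrix, rate metrics, and
#' (when scores are given) per-class AUC.
#'
#' @param y_true,y_pred Integer grades 0-4.
#' @param scores Optional N x 5 score matrix for ROC AUC.
#' @param average Averaging scheme for [classification_metrics].
#' @return An `eval_report` augmented with `confusion` and optionally `auc`.
#' @export
evaluate_predictions <- function(y_true, y_pred, scores = NULL,
                                 average = "macro") {
  cc <- confusion_counts(y_true, y_pred)
  rep <- classification_metrics(cc, average = average)
  rep$confusion <- cc
  if (!is.null(scores)) rep$auc <- roc_auc(scores, y_true)
  rep
}
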