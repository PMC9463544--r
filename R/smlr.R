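#' Labeled spectra for classification
#'
#' A feature matrix of spectra on one common wavelength grid plus a class
#' label per row.
#'
#' @param x Numeric matrix, rows = spectra, columns = wavelengths. No
#'   missing values.
#' @param labels Class label per row (coerced to factor); at least two
#'   classes with at least two members each.
#' @param wavelengths_nm Optional wavelength of each column (nm).
#' @return An `ewdrs_labeled_spectra`.
#' @export
labeled_spectra <- function(x, labels, wavelengths_nm = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels)
  stopifnot(nrow(x) == length(labels))
  if (anyNA(x)) stop_ewdrs("feature matrix has missing values", "ewdrs_parameter")
  if (nlevels(labels) < 2L || any(table(labels) < 2L))
    stop_ewdrs("need >= 2 classes with >= 2 members each", "ewdrs_parameter")
  if (!is.null(wavelengths_nm)) stopifnot(length(wavelengths_nm) == ncol(x))
  structure(list(x = x, labels = labels, wavelengths_nm = wavelengths_nm),
            class = "ewdrs_labeled_spectra")
}

#' Prepare classifier features from spectra
#'
#' Restricts each merged spectrum to the requested band — `"full"`
#' (500-1500 nm) or `"visnir"` (500-1000 nm) — resamples it to a uniform
#' 5-nm grid, and AUC-normalizes *within the band* (a band-limited
#' instrument can only normalize over what it measures; normalizing before
#' restriction would leak out-of-band intensity into the features through
#' the normalization constant). Comparing the two bands on identical data
#' quantifies what the SWIR channel adds to classification.
#'
#' @param spectra List of [spectrum()] objects.
#' @param labels Class label per spectrum.
#' @param band `"full"` or `"visnir"`.
#' @param step_nm Feature grid step (default 5 nm).
#' @return An [labeled_spectra()].
#' @export
prepare_features <- function(spectra, labels, band = c("full", "visnir"),
                             step_nm = 5) {
  band <- match.arg(band)
  lo <- max(500, min(vapply(spectra, function(s) s$wavelengths_nm[1L], 0)))
  hi <- min(if (band == "visnir") 1000 else 1500,
            min(vapply(spectra, function(s) max(s$wavelengths_nm), 0)))
  grid <- seq(ceiling(lo / step_nm) * step_nm, floor(hi / step_nm) * step_nm,
              by = step_nm)
  feats <- t(vapply(spectra, function(s)
    auc_normalize(resample(s, grid))$values, grid))
  labeled_spectra(feats, labels, grid)
}

#' Train a sparse multinomial logistic regression model
#'
#' Maximizes the multinomial log-likelihood minus `lambda * sum(|w|)`
#' (Laplacian/L1 prior; intercepts unpenalized, last class pinned at zero)
#' by cyclic coordinate-wise bound optimization with soft-threshold
#' updates. Features are z-scored by default; the stored standardization is
#' reapplied at prediction. Convergence: maximum weight change per sweep
#' below `tol` or `max_sweeps` sweeps, after which a warning flag is set on
#' the model (no exception).
#'
#' @param data An [labeled_spectra()].
#' @param prior_scale Sparsity penalty `lambda >= 0` (default 0.1 on
#'   z-scored features).
#' @param standardize Z-score columns before fitting (default TRUE).
#' @param tol,max_sweeps Convergence controls.
#' @return An `ewdrs_smlr`: `weights` ((features+1) x classes, row 1 =
#'   intercepts), `classes`, `selected` (feature indices with any nonzero
#'   weight), `converged`, standardization parameters.
#' @export
train_smlr <- function(data, prior_scale = 0.1, standardize = TRUE,
                       tol = 1e-6, max_sweeps = 10000L) {
  stopifnot(inherits(data, "ewdrs_labeled_spectra"), prior_scale >= 0)
  x <- data$x
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    x <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  classes <- levels(data$labels)
  y <- outer(data$labels, classes, "==") * 1L
  fit <- smlr_fit_cpp(x, y, lambda = prior_scale, tol = tol,
                      max_sweeps = as.integer(max_sweeps))
  w <- fit$weights
  rownames(w) <- c("(intercept)",
                   if (!is.null(data$wavelengths_nm))
                     paste0(data$wavelengths_nm, "nm")
                   else paste0("f", seq_len(ncol(x))))
  colnames(w) <- classes
  structure(list(weights = w, classes = classes,
                 selected = which(rowSums(abs(w[-1L, , drop = FALSE])) > 0),
                 wavelengths_nm = data$wavelengths_nm,
                 prior_scale = prior_scale, center = ctr, scale = scl,
                 converged = fit$converged, sweeps = fit$sweeps),
            class = "ewdrs_smlr")
}

#' @export
print.ewdrs_smlr <- function(x, ...) {
  cat(sprintf("<SMLR model> %d classes, %d/%d features selected, lambda=%g%s\n",
              length(x$classes), length(x$selected), nrow(x$weights) - 1L,
              x$prior_scale,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Posterior class probabilities
#'
#' Softmax over the linear class scores of one or more feature rows. Rows
#' sum to 1; the predicted class is the argmax, ties broken toward the
#' lowest class index.
#'
#' @param model An [train_smlr()] model.
#' @param x Feature vector or matrix (columns matching the training
#'   features).
#' @return Matrix of per-class probabilities (rows sum to 1) with a
#'   `predicted` attribute holding the predicted labels.
#' @export
predict_posterior <- function(model, x) {
  stopifnot(inherits(model, "ewdrs_smlr"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(model$weights) - 1L)
    stop_ewdrs("feature length does not match the model", "ewdrs_parameter")
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  scores <- cbind(1, xs) %*% model$weights
  scores <- scores - apply(scores, 1L, max)
  p <- exp(scores)
  p <- p / rowSums(p)
  colnames(p) <- model$classes
  pred <- factor(model$classes[apply(p, 1L, which.max)], levels = model$classes)
  attr(p, "predicted") <- pred
  p
}

#' Leave-one-out cross-validation
#'
#' For each row, refits the model (including standardization) on the
#' remaining rows and predicts the held-out row. A fold whose training set
#' loses an entire class emits a warning but still predicts.
#'
#' @param data An [labeled_spectra()] with at least 3 rows.
#' @param prior_scale,... Passed to [train_smlr()].
#' @return Factor of predicted labels, one per row, with the same levels as
#'   the data's labels.
#' @export
loocv <- function(data, prior_scale = 0.1, ...) {
  stopifnot(inherits(data, "ewdrs_labeled_spectra"))
  n <- nrow(data$x)
  if (n < 3L) stop_ewdrs("need at least 3 rows for LOOCV", "ewdrs_parameter")
  lv <- levels(data$labels)
  preds <- character(n)
  for (i in seq_len(n)) {
    lab <- droplevels(data$labels[-i])
    if (nlevels(lab) < nlevels(data$labels))
      warning(sprintf("fold %d loses an entire class", i))
    fold <- structure(list(x = data$x[-i, , drop = FALSE], labels = lab,
                           wavelengths_nm = data$wavelengths_nm),
                      class = "ewdrs_labeled_spectra")
    m <- train_smlr(fold, prior_scale = prior_scale, ...)
    preds[i] <- as.character(attr(predict_posterior(m, data$x[i, ]), "predicted"))
  }
  factor(preds, levels = lv)
}

#' Confusion matrix and overall accuracy
#'
#' @param true_labels,predicted_labels Equal-length label vectors over the
#'   same class set.
#' @return An `ewdrs_confusion`: `table` (rows = truth), per-class
#'   `correct` and `total`, `accuracy` (trace/total), `misclassified`
#'   (off-diagonal sum).
#' @export
confusion_and_accuracy <- function(true_labels, predicted_labels) {
  stopifnot(length(true_labels) == length(predicted_labels))
  lv <- levels(factor(true_labels))
  if (!all(as.character(predicted_labels) %in% lv))
    stop_ewdrs("predicted labels outside the true label set", "ewdrs_parameter")
  tt <- factor(true_labels, levels = lv)
  pp <- factor(predicted_labels, levels = lv)
  tab <- table(truth = tt, predicted = pp)
  structure(list(table = tab,
                 correct = diag(tab), total = rowSums(tab),
                 accuracy = sum(diag(tab)) / length(tt),
                 misclassified = length(tt) - sum(diag(tab))),
            class = "ewdrs_confusion")
}

#' @export
print.ewdrs_confusion <- function(x, ...) {
  print(x$table)
  cat(sprintf("overall accuracy %.1f%% (%d/%d), %d misclassified\n",
              100 * x$accuracy, sum(x$correct), sum(x$total), x$misclassified))
  invisible(x)
}
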