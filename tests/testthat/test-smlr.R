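# Synthetic Gaussian-class datasets used throughout; built fresh per test
# under fixed seeds.
gauss_classes <- function(n_per = 15, p = 50, sep_feature = min(12, p),
                          delta = 4, seed = 202) {
  with_seed(seed, {
    x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
    x[seq_len(n_per), sep_feature] <- x[seq_len(n_per), sep_feature] + delta
    labeled_spectra(x, rep(c("a", "b"), each = n_per))
  })
}

test_that("total shrinkage zeroes all weights and posteriors become class frequencies", {
  d <- with_seed(1, labeled_spectra(matrix(rnorm(60), 20, 3),
                                    rep(c("a", "b"), c(5, 15))))
  m <- train_smlr(d, prior_scale = 1e6)
  expect_true(all(m$weights[-1L, ] == 0))
  p <- predict_posterior(m, rep(0, 3))
  expect_equal(as.numeric(p), c(0.25, 0.75), tolerance = 1e-4)
})

test_that("sparsity recovery: the informative feature is selected, noise features dropped", {
  d <- gauss_classes()
  m <- train_smlr(d, prior_scale = 1)
  expect_true(m$converged)
  expect_true(12L %in% m$selected)
  expect_gte(mean(rowSums(abs(m$weights[-1L, , drop = FALSE]))[-12L] == 0), 0.9)
})

test_that("duplicating rows with doubled penalty leaves weights unchanged", {
  # objective-scaling identity on the raw features (z-scoring would rescale
  # by the n-1 sample SD, which differs between n and 2n rows)
  d <- gauss_classes(n_per = 10, p = 8)
  m1 <- train_smlr(d, prior_scale = 0.5, standardize = FALSE, tol = 1e-9)
  d2 <- labeled_spectra(rbind(d$x, d$x), c(d$labels, d$labels))
  m2 <- train_smlr(d2, prior_scale = 1.0, standardize = FALSE, tol = 1e-9)
  expect_equal(m2$weights, m1$weights, tolerance = 1e-8)
})

test_that("posteriors are normalized softmax scores with deterministic tie-breaks", {
  d <- gauss_classes(n_per = 8, p = 5)
  m <- train_smlr(d, prior_scale = 0.2)
  x <- with_seed(7, matrix(rnorm(50 * 5), 50, 5))
  p <- predict_posterior(m, x)
  expect_equal(rowSums(p), rep(1, 50), tolerance = 1e-12)
  expect_error(predict_posterior(m, rep(0, 4)), class = "ewdrs_parameter")

  # all-zero model ties: argmax resolves to the first class
  m0 <- train_smlr(d, prior_scale = 1e6)
  m0$weights[] <- 0
  p0 <- predict_posterior(m0, rep(0, 5))
  expect_equal(as.numeric(p0), c(0.5, 0.5))
  expect_equal(as.character(attr(p0, "predicted")), "a")
})

test_that("monotone sparsity: nonzero weights do not increase with the penalty", {
  d <- gauss_classes(n_per = 12, p = 30, delta = 2)
  nnz <- vapply(c(0.01, 0.1, 0.5, 2, 10), function(lam)
    sum(train_smlr(d, prior_scale = lam)$weights[-1L, ] != 0), 0L)
  expect_true(all(diff(nnz) <= 0))
})

test_that("LOOCV separates distant Gaussians and stays near chance under permutation", {
  d <- gauss_classes(n_per = 15, p = 20, delta = 5)
  pred <- loocv(d, prior_scale = 0.1)
  acc <- mean(pred == d$labels)
  expect_gte(acc, 0.95)

  perm <- with_seed(303, labeled_spectra(d$x, sample(as.character(d$labels))))
  pred_p <- loocv(perm, prior_scale = 0.1)
  acc_p <- mean(pred_p == perm$labels)
  ci <- 0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / nrow(d$x))
  expect_gte(acc_p, ci[1L])
  expect_lte(acc_p, ci[2L])
})

test_that("LOOCV with a singleton class warns but predicts every row", {
  d <- structure(list(x = matrix(c(0, 0, 5, 5, 9, 9), 3, 2, byrow = TRUE),
                      labels = factor(c("a", "a", "b")), wavelengths_nm = NULL),
                 class = "ewdrs_labeled_spectra")
  expect_warning(pred <- loocv(d, prior_scale = 0.1), "loses an entire class")
  expect_length(pred, 3L)
})

test_that("confusion summary reproduces counts, accuracy and misclassifications", {
  truth <- rep(c("x", "y", "z"), each = 4)
  pred <- truth
  pred[1L] <- "y"
  cs <- confusion_and_accuracy(truth, pred)
  expect_equal(cs$accuracy, 11 / 12)
  expect_equal(cs$misclassified, 1L)
  expect_equal(unname(cs$total), c(4L, 4L, 4L))

  perfect <- confusion_and_accuracy(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$misclassified, 0L)
  expect_error(confusion_and_accuracy(truth, rep("q", 12)),
               class = "ewdrs_parameter")
})

test_that("predictions agree with an independent L1 multinomial fit (glmnet)", {
  skip_if_not_installed("glmnet")
  d <- gauss_classes(n_per = 20, p = 10, delta = 2.5, seed = 404)
  lam <- 0.5
  m <- train_smlr(d, prior_scale = lam)
  pred_own <- as.character(attr(predict_posterior(m, d$x), "predicted"))
  xs <- scale(d$x)
  gfit <- glmnet::glmnet(xs, d$labels, family = "multinomial",
                         lambda = lam / nrow(d$x), standardize = FALSE)
  pred_g <- as.character(predict(gfit, xs, type = "class"))
  expect_gte(mean(pred_own == pred_g), 0.9)
})
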