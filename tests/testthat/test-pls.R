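test_that("full-rank SIMPLS equals the OLS pseudoinverse oracle", {
  set.seed(10)
  X <- matrix(rnorm(18), 6, 3)
  Y <- matrix(rnorm(12), 6, 2)
  m <- pls_fit(X, Y, d = 3)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  expect_equal(m$B, MASS::ginv(Xc) %*% Yc, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("noise-free linear labels are reproduced exactly at full rank", {
  set.seed(11)
  X <- matrix(rnorm(80), 20, 4)
  C <- matrix(rnorm(8), 4, 2)
  Y <- X %*% C
  m <- pls_fit(X, Y, d = 4)
  expect_equal(pls_predict(m, X), Y, tolerance = 1e-8, ignore_attr = TRUE)
  # training reconstruction identity of the decomposition
  expect_equal(m$T_scores %*% t(m$Q_load) + rep(m$y_mean, each = 20),
               pls_predict(m, X), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the first weight vector follows the dominant cross-covariance direction", {
  set.seed(12)
  X <- matrix(rnorm(60), 15, 4)
  Y <- matrix(rnorm(30), 15, 2)
  m <- pls_fit(X, Y, d = 1)
  sv <- svd(crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE)))
  w <- m$W_weights[, 1]; w <- w / sqrt(sum(w^2))
  expect_lt(min(max(abs(w - sv$u[, 1])), max(abs(w + sv$u[, 1]))), 1e-8)
})

test_that("prediction is an affine map with the stated intercept behavior", {
  set.seed(13)
  X <- matrix(rnorm(48), 12, 4)
  Y <- matrix(rnorm(24), 12, 2)
  m <- pls_fit(X, Y, d = 2)
  # row of training means predicts the label means
  expect_equal(drop(pls_predict(m, matrix(m$x_mean, 1))), m$y_mean,
               tolerance = 1e-10, ignore_attr = TRUE)
  # hand-checkable matrix product
  m2 <- m
  m2$B <- matrix(c(1, 0, 0, 2), 2, 2)
  m2$intercept <- c(0, 1)
  m2$x_mean <- c(0, 0)
  expect_equal(unname(pls_predict(m2, matrix(c(3, 4), 1))),
               matrix(c(3, 9), 1))
  expect_error(pls_predict(m, X[, 1:3]), "features")
})

test_that("training MSE is non-increasing in d and scores are orthogonal", {
  set.seed(14)
  X <- matrix(rnorm(200), 20, 10)
  Y <- X %*% matrix(rnorm(20), 10, 2) + matrix(rnorm(40), 20, 2)
  mses <- vapply(1:8, function(d) {
    m <- pls_fit(X, Y, d)
    mean((pls_predict(m, X) - Y)^2)
  }, numeric(1))
  expect_true(all(diff(mses) <= 1e-10))
  m <- pls_fit(X, Y, 6)
  expect_equal(crossprod(m$T_scores), diag(6), tolerance = 1e-8)
})

test_that("fitting is invariant to shifting X columns and matches single-label columns", {
  set.seed(15)
  X <- matrix(rnorm(120), 20, 6)
  Y <- matrix(rnorm(20), 20, 1)
  m1 <- pls_fit(X, Y, 3)
  X2 <- sweep(X, 2, c(5, -2, 0, 100, 1, 3), "+")
  m2 <- pls_fit(X2, Y, 3)
  expect_equal(m1$B, m2$B, tolerance = 1e-8)
  Xnew <- matrix(rnorm(30), 5, 6)
  expect_equal(pls_predict(m1, Xnew), pls_predict(m2, sweep(Xnew, 2, c(5, -2, 0, 100, 1, 3), "+")),
               tolerance = 1e-8)
})

test_that("invalid d and degenerate labels are rejected; rank deficiency shrinks d", {
  set.seed(16)
  X <- matrix(rnorm(30), 10, 3)
  Y <- matrix(rnorm(20), 10, 2)
  expect_error(pls_fit(X, Y, 4), "out of range")
  expect_error(pls_fit(X, cbind(Y[, 1], 7), 2), "zero-variance")
  # X of rank 1: only one latent variable is extractable
  X1 <- outer(rnorm(10), c(1, 2, 3))
  expect_warning(m <- pls_fit(X1 + 1e-14, Y, 3), "rank deficient")
  expect_lt(m$d, 3)
})

test_that("single-response SIMPLS agrees with an independent NIPALS PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(17)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("e", 1:10)))
  y <- X %*% rnorm(10) + rnorm(20)
  d <- 3
  m <- pls_fit(X, y, d)
  ref <- mixOmics::pls(X, y, ncomp = d, scale = FALSE, mode = "regression")
  Xnew <- matrix(rnorm(50), 5, 10, dimnames = list(NULL, paste0("e", 1:10)))
  pred_ref <- predict(ref, Xnew)$predict[, 1, d]
  expect_equal(drop(pls_predict(m, Xnew)), unname(pred_ref), tolerance = 1e-6)
})

test_that("RBF gram has unit diagonal and kernel PLS matches linear PLS under a linear kernel", {
  set.seed(18)
  X <- matrix(rnorm(60), 15, 4)
  y <- matrix(X %*% rnorm(4) + 0.1 * rnorm(15), 15, 1)
  K <- plsconn:::rbf_gram(X, sigma = 2)
  expect_equal(diag(K), rep(1, 15))
  expect_true(all(K <= 1 & K > 0))
  km <- kernel_pls_fit(X, y, d = 3, kernel = "linear")
  lm <- pls_fit(X, y, d = 3)
  Xnew <- matrix(rnorm(24), 6, 4)
  expect_equal(kernel_pls_predict(km, Xnew), pls_predict(lm, Xnew),
               tolerance = 1e-6, ignore_attr = TRUE)
  # default bandwidth is the protocol value; invalid bandwidths rejected
  expect_equal(formals(kernel_pls_fit)$sigma, 150)
  expect_error(kernel_pls_fit(X, y, 2, sigma = 0), "sigma")
})

test_that("RBF kernel PLS interpolates a smooth nonlinear target better than chance", {
  set.seed(19)
  X <- matrix(runif(160, -2, 2), 80, 2)
  y <- matrix(sin(X[, 1]) + 0.5 * cos(2 * X[, 2]) + 0.05 * rnorm(80), 80, 1)
  km <- kernel_pls_fit(X[1:60, , drop = FALSE], y[1:60, , drop = FALSE],
                       d = 10, sigma = 1)
  pred <- kernel_pls_predict(km, X[61:80, , drop = FALSE])
  expect_gt(cor(pred, y[61:80, ]), 0.8)
})
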