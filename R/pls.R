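#' Multi-response partial least squares (SIMPLS)
#'
#' Fits the PLS decomposition \eqn{X = T P' + E}, \eqn{Y = U Q' + F} on
#' column-centered `X` and `Y`, extracting `d` score pairs that maximize
#' the covariance between successive X- and Y-scores, and returns the
#' explicit coefficient matrix `B` with intercept so that unseen subjects'
#' labels are estimated as `X %*% B + intercept`.  The extraction is the
#' SIMPLS algorithm (weight vectors taken from the deflated cross-covariance
#' matrix, no deflation of the data matrix itself).  Columns are centered
#' only, never scaled.
#'
#' `d` is the model's single hyper-parameter (number of latent variables).
#' If the cross-covariance becomes numerically rank-deficient before `d`
#' components are extracted, extraction stops early, `d` shrinks, and a
#' warning is issued.
#'
#' @param X Numeric matrix, subjects x features (n x N), no missing values.
#' @param Y Numeric matrix or vector, subjects x labels (n x M).
#' @param d Number of latent variables; must satisfy `d <= min(n - 1, N)`.
#' @return An object of class `pls_model`: `d` (components actually used),
#'   `x_mean`, `y_mean`, score matrices `T_scores` (orthonormal columns) and
#'   `U_scores`, loadings `P_load` (N x d) and `Q_load` (M x d), X-weights
#'   `W_weights` (N x d, `T_scores = Xc %*% W_weights`), coefficient matrix
#'   `B` (N x M) and `intercept` (length M).
#' @references de Jong, S. (1993) SIMPLS: an alternative approach to partial
#'   least squares regression. Chemometrics and Intelligent Laboratory
#'   Systems 18, 251-263.
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' Y <- X %*% matrix(c(1, -1, 0, 2, 0, 1), 3, 2) + rnorm(40, sd = 0.1)
#' m <- pls_fit(X, Y, d = 2)
#' head(pls_predict(m, X))
#' @export
pls_fit <- function(X, Y, d) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!is.numeric(X) || anyNA(X) || !is.numeric(Y) || anyNA(Y))
    stopf("X and Y must be numeric with no missing values")
  n <- nrow(X); N <- ncol(X); M <- ncol(Y)
  if (nrow(Y) != n) stopf("X and Y must have the same number of rows")
  if (n < 2L) stopf("need at least 2 samples")
  d <- check_count(d, "d")
  if (d > min(n - 1L, N))
    stopf("d = %d out of range: must be <= min(n - 1, N) = %d", d, min(n - 1L, N))
  ysd <- apply(Y, 2L, stats::sd)
  if (any(ysd == 0))
    stopf("zero-variance label column(s): %s",
          paste(if (!is.null(colnames(Y))) colnames(Y)[ysd == 0] else which(ysd == 0),
                collapse = ", "))
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2L, x_mean)
  Yc <- sweep(Y, 2L, y_mean)
  fit <- simpls_core(Xc, Yc, d)
  if (fit$d < d)
    warning(sprintf("cross-covariance rank deficient: extracted %d of %d requested latent variables",
                    fit$d, d), call. = FALSE)
  structure(list(d = fit$d, d_requested = d,
                 x_mean = x_mean, y_mean = y_mean,
                 T_scores = fit$T_scores, U_scores = fit$U_scores,
                 P_load = fit$P_load, Q_load = fit$Q_load,
                 W_weights = fit$W_weights,
                 B = fit$B, intercept = as.numeric(y_mean - crossprod(fit$B, x_mean)),
                 label_names = colnames(Y)),
            class = "pls_model")
}

# SIMPLS extraction on pre-centered Xc (n x N) and Yc (n x M).  Returns the
# full set of score/loading/weight matrices plus B on centered data.
simpls_core <- function(Xc, Yc, d, tol = 1e-12) {
  n <- nrow(Xc); N <- ncol(Xc); M <- ncol(Yc)
  S <- crossprod(Xc, Yc)
  W <- matrix(0, N, d); Tm <- matrix(0, n, d); P <- matrix(0, N, d)
  Q <- matrix(0, M, d); U <- matrix(0, n, d); V <- matrix(0, N, d)
  sv0 <- NA_real_
  used <- 0L
  for (a in seq_len(d)) {
    sv <- svd(S, nu = 1L, nv = 0L)
    if (a == 1L) sv0 <- sv$d[1L]
    if (!is.finite(sv$d[1L]) || sv$d[1L] <= tol * max(sv0, 1)) break
    r <- sv$u[, 1L]
    t <- drop(Xc %*% r)
    t <- t - mean(t)
    nt <- sqrt(sum(t * t))
    if (nt <= tol * max(sv0, 1)) break
    t <- t / nt
    r <- r / nt
    p <- drop(crossprod(Xc, t))
    q <- drop(crossprod(Yc, t))
    u <- drop(Yc %*% q)
    v <- p
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - drop(Vp %*% crossprod(Vp, p))
      Tp <- Tm[, seq_len(a - 1L), drop = FALSE]
      u <- u - drop(Tp %*% crossprod(Tp, u))
    }
    nv <- sqrt(sum(v * v))
    if (nv <= tol) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    W[, a] <- r; Tm[, a] <- t; P[, a] <- p; Q[, a] <- q; U[, a] <- u; V[, a] <- v
    used <- a
  }
  if (used == 0L) stopf("no latent variable could be extracted (X'Y is numerically zero)")
  keep <- seq_len(used)
  W <- W[, keep, drop = FALSE]; Tm <- Tm[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]; Q <- Q[, keep, drop = FALSE]
  U <- U[, keep, drop = FALSE]
  list(d = used, W_weights = W, T_scores = Tm, P_load = P, Q_load = Q,
       U_scores = U, B = W %*% t(Q))
}

# Fast path used inside permutation loops: only the coefficient matrix.
simpls_B <- function(Xc, Yc, d, tol = 1e-12) {
  simpls_core(Xc, Yc, d, tol)$B
}

#' Predict labels with a fitted PLS model
#'
#' @param model A `pls_model` from [pls_fit()].
#' @param X_new Numeric matrix, subjects x features; feature count must
#'   match the training data.
#' @return Numeric matrix of estimates, subjects x labels.
#' @export
pls_predict <- function(model, X_new) {
  if (!inherits(model, "pls_model")) stopf("`model` must be a pls_model")
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_mean))
    stopf("X_new has %d features; model was trained on %d", ncol(X_new),
          length(model$x_mean))
  out <- X_new %*% model$B + rep(model$intercept, each = nrow(X_new))
  colnames(out) <- model$label_names
  out
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d latent variables, %d features, %d label(s)\n",
              x$d, length(x$x_mean), length(x$y_mean)))
  invisible(x)
}

rbf_gram <- function(A, B = NULL, sigma) {
  sa <- rowSums(A * A)
  if (is.null(B)) { B <- A; sb <- sa } else sb <- rowSums(B * B)
  d2 <- outer(sa, sb, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Kernel partial least squares with an RBF kernel
#'
#' Nonlinear variant of [pls_fit()] operating on the double-centered Gram
#' matrix of the radial-basis-function kernel \eqn{k(x, x') =
#' \exp(-\|x-x'\|^2 / (2\sigma^2))}.  Score extraction follows the dual
#' (kernel) PLS algorithm of Rosipal & Trejo (2001); prediction uses the
#' retained training inputs and dual coefficients.
#'
#' @param X,Y Training features and labels as in [pls_fit()].
#' @param d Number of latent variables, `d <= n - 1`.
#' @param sigma RBF bandwidth (> 0); default 150, suited to raw
#'   connectivity features of a few thousand edges.
#' @param kernel `"rbf"` (default) or `"linear"` (mainly for validation
#'   against the linear fit).
#' @return An object of class `kernel_pls_model`.
#' @references Rosipal, R. and Trejo, L.J. (2001) Kernel partial least
#'   squares regression in reproducing kernel Hilbert space. JMLR 2, 97-123.
#' @export
kernel_pls_fit <- function(X, Y, d, sigma = 150, kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stopf("X and Y must have the same number of rows")
  d <- check_count(d, "d")
  if (d > n - 1L) stopf("d = %d out of range: must be <= n - 1 = %d", d, n - 1L)
  if (kernel == "rbf" && (length(sigma) != 1L || !is.numeric(sigma) || sigma <= 0))
    stopf("`sigma` must be a single positive number")
  y_mean <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_mean)
  K <- if (kernel == "rbf") rbf_gram(X, sigma = sigma) else tcrossprod(X)
  Kc <- center_gram(K)
  Kd <- Kc; Yd <- Yc
  Tm <- matrix(0, n, d); U <- matrix(0, n, d)
  used <- 0L
  for (a in seq_len(d)) {
    init <- which.max(colSums(Yd^2))
    u <- Yd[, init]
    if (sum(u * u) < 1e-300) break
    t_old <- rep(0, n)
    for (it in seq_len(500L)) {
      t <- drop(Kd %*% u)
      nt <- sqrt(sum(t * t))
      if (nt < 1e-14) break
      t <- t / nt
      cvec <- drop(crossprod(Yd, t))
      u <- drop(Yd %*% cvec)
      nu <- sqrt(sum(u * u))
      if (nu < 1e-14) break
      u <- u / nu
      if (max(abs(t - t_old)) < 1e-12) break
      t_old <- t
    }
    nt <- sqrt(sum(t * t))
    if (nt < 1e-14) break
    Tm[, a] <- t; U[, a] <- u
    # deflate the kernel and the labels by the extracted score
    Kt <- Kd %*% t
    Kd <- Kd - tcrossprod(t, Kt) - tcrossprod(Kt, t) +
      tcrossprod(t, t) * drop(crossprod(t, Kt))
    Yd <- Yd - tcrossprod(t, drop(crossprod(Yd, t)))
    used <- a
  }
  if (used == 0L) stopf("no latent variable could be extracted")
  Tm <- Tm[, seq_len(used), drop = FALSE]
  U <- U[, seq_len(used), drop = FALSE]
  M1 <- crossprod(Tm, Kc %*% U)
  dual <- U %*% solve(M1, crossprod(Tm, Yc))
  structure(list(d = used, sigma = if (kernel == "rbf") sigma else NA_real_,
                 kernel = kernel, X_train = X, K_colmeans = colMeans(K),
                 K_mean = mean(K), dual = dual, y_mean = y_mean,
                 label_names = colnames(Y)),
            class = "kernel_pls_model")
}

center_gram <- function(K) {
  n <- nrow(K)
  cm <- colMeans(K)
  K - matrix(cm, n, n, byrow = TRUE) - matrix(cm, n, n) + mean(K)
}

#' Predict labels with a fitted kernel PLS model
#'
#' @param model A `kernel_pls_model` from [kernel_pls_fit()].
#' @param X_new Numeric matrix of new subjects' features.
#' @return Numeric matrix of estimates, subjects x labels.
#' @export
kernel_pls_predict <- function(model, X_new) {
  if (!inherits(model, "kernel_pls_model")) stopf("`model` must be a kernel_pls_model")
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(model$X_train))
    stopf("X_new has %d features; model was trained on %d", ncol(X_new),
          ncol(model$X_train))
  Kt <- if (model$kernel == "rbf")
    rbf_gram(X_new, model$X_train, model$sigma)
  else
    tcrossprod(X_new, model$X_train)
  m <- nrow(Kt)
  Ktc <- Kt - matrix(model$K_colmeans, m, ncol(Kt), byrow = TRUE) -
    matrix(rowMeans(Kt), m, ncol(Kt)) + model$K_mean
  # centering of the test Gram rows uses training column means on both axes:
  # rowMeans(Kt) estimates the test-point/training-mass term
  out <- Ktc %*% model$dual + rep(model$y_mean, each = m)
  colnames(out) <- model$label_names
  out
}
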