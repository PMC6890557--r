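#' Edge index map for the upper triangle of a connectivity matrix
#'
#' Enumerates the \eqn{p(p-1)/2} unordered ROI pairs \eqn{(i, j)}, \eqn{i <
#' j}, in lexicographic order.  This fixed order defines the feature
#' dimension used throughout the package: edge \eqn{e} of every feature
#' vector refers to the same ROI pair for every subject.  Indices are
#' 1-based.
#'
#' @param p Number of ROIs (regions of interest).
#' @return A data frame of class `edge_map` with integer columns `i` and `j`
#'   (one row per edge) and attribute `p`.
#' @examples
#' edge_index_map(4)
#' @export
edge_index_map <- function(p) {
  p <- check_count(p, "p", min = 2L)
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(a) seq.int(a + 1L, p)))
  em <- data.frame(i = as.integer(i), j = as.integer(j))
  attr(em, "p") <- p
  class(em) <- c("edge_map", "data.frame")
  em
}

n_edges <- function(em) nrow(em)

new_conn_matrix <- function(values, method, rho = NA_real_) {
  structure(list(values = values, method = method, rho = rho),
            class = "conn_matrix")
}

check_timeseries <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts) || anyNA(ts)) stopf("time-series must be numeric with no missing values")
  if (nrow(ts) < 3L) stopf("need at least 3 timepoints, got %d", nrow(ts))
  if (ncol(ts) < 2L) stopf("need at least 2 ROIs, got %d", ncol(ts))
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) stopf("constant time-series for ROI(s): %s",
                           paste(which(sds == 0), collapse = ", "))
  ts
}

#' Full-correlation network matrix
#'
#' Pearson correlation between every pair of ROI time-series: the "full
#' correlation" connectivity definition, sensitive to both direct and
#' indirect connections.
#'
#' @param ts Numeric matrix, timepoints x ROIs.
#' @return A `conn_matrix` object: symmetric \eqn{p \times p} matrix with
#'   unit diagonal, `method = "full"`.
#' @seealso [partial_correlation()], [vectorize_upper()]
#' @export
full_correlation <- function(ts) {
  ts <- check_timeseries(ts)
  v <- stats::cor(ts)
  # guard against rounding drift outside [-1, 1]
  v[v > 1] <- 1; v[v < -1] <- -1
  diag(v) <- 1
  new_conn_matrix(v, "full")
}

# Partial correlation from a (possibly ridge-regularized) covariance matrix.
pcor_from_cov <- function(S, rho = 0) {
  p <- ncol(S)
  Sr <- S + rho * (sum(diag(S)) / p) * diag(p)
  Th <- tryCatch(solve(Sr), error = function(e)
    stopf("regularized covariance is singular; use rho > 0 (got rho = %g)", rho))
  d <- sqrt(diag(Th))
  if (any(!is.finite(d)))
    stopf("regularized covariance is not positive definite; use rho > 0")
  R <- -Th / tcrossprod(d)
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 1
  R
}

#' Ridge-regularized partial-correlation network matrix
#'
#' Partial correlation approximates direct connections by removing the
#' linear influence of all other ROIs.  With \eqn{\Sigma} the sample
#' covariance of the column-demeaned time-series (1/(T-1) estimator), the
#' precision matrix is taken as \eqn{\Theta = (\Sigma + \rho\,
#' \mathrm{tr}(\Sigma)/p \cdot I)^{-1}} and the partial correlation is
#' \eqn{r_{ij} = -\Theta_{ij} / \sqrt{\Theta_{ii}\Theta_{jj}}}.  Scaling the
#' ridge by the mean diagonal of \eqn{\Sigma} makes `rho` unit-free
#' (invariant to a common rescaling of all ROIs).
#'
#' @param ts Numeric matrix, timepoints x ROIs.
#' @param rho Non-negative ridge amount; default `0.01`.
#' @return A `conn_matrix` object with `method = "partial"`.
#' @export
partial_correlation <- function(ts, rho = 0.01) {
  ts <- check_timeseries(ts)
  if (length(rho) != 1L || !is.numeric(rho) || is.na(rho) || rho < 0)
    stopf("`rho` must be a single non-negative number")
  tsc <- scale(ts, center = TRUE, scale = FALSE)
  S <- crossprod(tsc) / (nrow(ts) - 1)
  new_conn_matrix(pcor_from_cov(S, rho), "partial", rho)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Flattens a symmetric unit-diagonal \eqn{p \times p} matrix into the
#' length-\eqn{p(p-1)/2} edge-feature vector whose order follows
#' [edge_index_map()].  For 200 ROIs this yields 19,900 edge features.
#'
#' @param cm A `conn_matrix` or a plain symmetric numeric matrix.
#' @param tol Maximum tolerated asymmetry.
#' @return Numeric vector of length \eqn{p(p-1)/2} with attribute
#'   `edge_map`.
#' @export
vectorize_upper <- function(cm, tol = 1e-10) {
  v <- if (inherits(cm, "conn_matrix")) cm$values else as.matrix(cm)
  if (nrow(v) != ncol(v)) stopf("connectivity matrix must be square")
  if (max(abs(v - t(v))) > tol) stopf("connectivity matrix is asymmetric beyond tol = %g", tol)
  em <- edge_index_map(ncol(v))
  out <- v[cbind(em$i, em$j)]
  attr(out, "edge_map") <- em
  out
}

# Inverse of vectorize_upper (unit diagonal assumed).
unvectorize <- function(vec, p) {
  em <- edge_index_map(p)
  m <- diag(p)
  m[cbind(em$i, em$j)] <- vec
  m[cbind(em$j, em$i)] <- vec
  m
}

new_feature_matrix <- function(values, edge_map, subject_ids, method = NA, rho = NA_real_) {
  dimnames(values) <- list(subject_ids, edge_names(edge_map))
  structure(list(values = values, edge_map = edge_map,
                 subject_ids = subject_ids, method = method, rho = rho),
            class = "feature_matrix")
}

edge_names <- function(em) paste0("roi", em$i, "__roi", em$j)

#' Build the subjects x edges feature matrix
#'
#' Computes one connectivity matrix per subject (full or ridge-regularized
#' partial correlation) and stacks the vectorized upper triangles into the
#' \eqn{n \times N} feature matrix that the PLS model consumes, with
#' \eqn{N = p(p-1)/2}.  No standardization or scaling is applied to the
#' connectivity values.
#'
#' @param timeseries List of per-subject timepoints x ROIs matrices, all
#'   sharing the same ROI count.
#' @param method `"partial"` (default) or `"full"`.
#' @param rho Ridge amount for partial correlation; default `0.01`.
#' @param subject_ids Optional character vector of subject identifiers.
#' @return A `feature_matrix` object: `values` (n x N), `edge_map`,
#'   `subject_ids`, and the connectivity configuration used.
#' @examples
#' ts <- replicate(3, matrix(rnorm(50 * 5), 50, 5), simplify = FALSE)
#' fm <- build_feature_matrix(ts, method = "full")
#' dim(fm$values)  # 3 x 10
#' @export
build_feature_matrix <- function(timeseries, method = c("partial", "full"),
                                 rho = 0.01, subject_ids = NULL) {
  method <- match.arg(method)
  if (!is.list(timeseries) || length(timeseries) == 0L)
    stopf("`timeseries` must be a non-empty list of matrices")
  ps <- vapply(timeseries, ncol, integer(1))
  if (length(unique(ps)) != 1L)
    stopf("inconsistent ROI counts across subjects: %s",
          paste(which(ps != ps[1L]), collapse = ", "))
  p <- ps[[1L]]
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_along(timeseries))
  em <- edge_index_map(p)
  rows <- lapply(timeseries, function(ts) {
    cm <- if (method == "full") full_correlation(ts) else partial_correlation(ts, rho)
    as.numeric(vectorize_upper(cm))
  })
  vals <- do.call(rbind, rows)
  new_feature_matrix(vals, em, subject_ids, method,
                     if (method == "partial") rho else NA_real_)
}
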