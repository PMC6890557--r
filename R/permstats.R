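#' Fold-averaged coefficient matrix
#'
#' Averages the per-fold PLS coefficient matrices elementwise into the
#' average weight matrix `B_bar`, whose entry (i, j) scores the
#' contribution of edge feature i to the estimation of label j.
#'
#' @param models List of `pls_model` objects (or plain matrices) sharing
#'   one shape.
#' @return Numeric matrix, features x labels.
#' @export
average_B <- function(models) {
  Bs <- lapply(models, function(m) if (inherits(m, "pls_model")) m$B else as.matrix(m))
  dims <- vapply(Bs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("coefficient matrices differ in shape")
  Reduce(`+`, Bs) / length(Bs)
}

#' Permutation p-value
#'
#' The permutation estimate \eqn{P = (1 + N_{exceed}) / (1 + N)} where
#' \eqn{N} is the number of permutations and \eqn{N_{exceed}} the number of
#' permuted statistics strictly exceeding the observed one.  With
#' \eqn{N = 5000} and no exceedance this gives \eqn{P = 1/5001 \approx
#' 0.0002}; the p-value can never be 0.
#'
#' @param n_stronger Number of permuted statistics exceeding the observed.
#' @param n_perm Number of permutations.
#' @return The p-value in `(0, 1]`.
#' @export
perm_pvalue <- function(n_stronger, n_perm) {
  n_perm <- check_count(n_perm, "n_perm")
  n_stronger <- check_count(n_stronger, "n_stronger", min = 0L)
  if (n_stronger > n_perm) stopf("n_stronger exceeds n_perm")
  (1 + n_stronger) / (1 + n_perm)
}

#' Jointly permute the rows of a label table
#'
#' Applies one random permutation of subjects to the whole label matrix, so
#' the correlation structure among labels is preserved while the
#' label-feature pairing is destroyed — the null hypothesis of the
#' permutation tests.
#'
#' @param labels A `label_table`.
#' @param seed Integer seed.
#' @param per_label If TRUE each label column is shuffled independently
#'   (breaks inter-label correlation under the null); default FALSE.
#' @return A `label_table` with permuted rows (original subject ids kept in
#'   original order, i.e. labels are reassigned across subjects).
#' @export
permute_labels <- function(labels, seed, per_label = FALSE) {
  if (!inherits(labels, "label_table")) stopf("`labels` must be a label_table")
  n <- nrow(labels$values)
  v <- if (per_label) {
    with_seed(seed, apply(labels$values, 2L, sample))
  } else {
    labels$values[with_seed(seed, sample.int(n)), , drop = FALSE]
  }
  label_table(structure(v, dimnames = list(NULL, labels$names)),
              labels$kinds, labels$subject_ids)
}

#' Permutation significance of accuracies and edge weights
#'
#' Runs the full permutation protocol: the observed cross-validated
#' estimation is re-run `n_perm` times with jointly shuffled labels, using
#' the identical fold plan each time, so the null distribution reflects
#' label-feature decoupling only.  Per label, the accuracy p-value counts
#' permuted statistics (Pearson R for continuous labels, accuracy for
#' binary ones) strictly exceeding the observed; per edge and label, the
#' weight p-value counts permuted fold-averaged coefficients strictly
#' exceeding the observed in absolute value.  Edges with weight p-value
#' strictly below `alpha` form the significant-contribution mask.
#'
#' @param features A `feature_matrix` (or matrix).
#' @param labels A `label_table`.
#' @param label_use Labels entered into the model (default: all).
#' @param d Latent variables.
#' @param folds A `fold_plan`, frozen across all permutations.
#' @param n_perm Number of permutations (5000 in the full protocol; smaller
#'   values suit desk-scale runs).
#' @param alpha Significance threshold for weights (default 0.05, strict).
#' @param seed Master seed for the permutation streams.
#' @param per_label Shuffle each label independently instead of jointly.
#' @return An object of class `perm_result`: `observed_stat` and
#'   `p_accuracy` per label, `null_stat` (n_perm x M), `B_bar`,
#'   `null_absB_exceed_counts`, `p_weight` (edges x labels), `sig_mask`,
#'   `alpha`, `n_perm`, `seed`, plus the observed `cv_result`.
#' @export
run_permutation_test <- function(features, labels, label_use = NULL, d = 50,
                                 folds, n_perm = 5000, alpha = 0.05, seed = 1L,
                                 per_label = FALSE) {
  n_perm <- check_count(n_perm, "n_perm")
  if (1 / (n_perm + 1) >= alpha)
    warning(sprintf("n_perm = %d cannot reach p < %g (minimum attainable p = %g)",
                    n_perm, alpha, 1 / (n_perm + 1)), call. = FALSE)
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  observed <- run_cv(features, labels, label_use, d, folds, keep_models = FALSE)
  if (is.null(label_use)) label_use <- labels$names
  sel <- match(label_use, labels$names)
  Y <- labels$values[, sel, drop = FALSE]
  kinds <- labels$kinds[sel]
  M <- ncol(Y)
  obs_stat <- vapply(seq_len(M), function(m) {
    if (kinds[m] == "continuous")
      metric_pearson_r(Y[, m], observed$predictions[, m])
    else mean(classify_binary(observed$predictions[, m]) == Y[, m])
  }, numeric(1))
  names(obs_stat) <- colnames(Y)
  absB_obs <- abs(observed$B_bar)

  pre <- prep_fold_features(X, folds)
  n <- nrow(Y)
  null_stat <- matrix(NA_real_, n_perm, M, dimnames = list(NULL, colnames(Y)))
  exceed_B <- matrix(0L, nrow(absB_obs), ncol(absB_obs))
  stronger <- integer(M)
  for (b in seq_len(n_perm)) {
    perm <- with_seed(sub_seed(seed, b), sample.int(n))
    Yp <- if (per_label) {
      apply_cols <- function(j) Y[with_seed(sub_seed(seed, b * 1000L + j), sample.int(n)), j]
      vapply(seq_len(M), apply_cols, numeric(n))
    } else Y[perm, , drop = FALSE]
    eng <- cv_engine(pre, Yp, d)
    st <- vapply(seq_len(M), function(m) {
      if (kinds[m] == "continuous") {
        if (stats::sd(eng$pred[, m]) == 0) 0 else stats::cor(Yp[, m], eng$pred[, m])
      } else mean(classify_binary(eng$pred[, m]) == Yp[, m])
    }, numeric(1))
    null_stat[b, ] <- st
    stronger <- stronger + (st > obs_stat)
    exceed_B <- exceed_B + (abs(eng$Bsum / folds$k) > absB_obs)
  }
  p_accuracy <- (1 + stronger) / (1 + n_perm)
  names(p_accuracy) <- colnames(Y)
  p_weight <- (1 + exceed_B) / (1 + n_perm)
  dimnames(p_weight) <- dimnames(observed$B_bar)
  structure(list(n_perm = n_perm, observed_stat = obs_stat,
                 null_stat = null_stat, p_accuracy = p_accuracy,
                 B_bar = observed$B_bar,
                 null_absB_exceed_counts = exceed_B,
                 p_weight = p_weight, alpha = alpha,
                 sig_mask = p_weight < alpha,
                 seed = as.integer(seed), observed = observed,
                 kinds = kinds),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test: %d permutations, alpha = %g\n", x$n_perm, x$alpha))
  df <- data.frame(label = names(x$observed_stat),
                   statistic = x$observed_stat,
                   p_accuracy = x$p_accuracy,
                   n_sig_edges = colSums(x$sig_mask), row.names = NULL)
  print(df, digits = 4)
  invisible(x)
}

#' Overlap of two significant-edge sets
#'
#' Compares the edges flagged significant by two analyses (e.g. multi- vs
#' single-label learning): counts, Jaccard index, and a hypergeometric
#' enrichment p-value for drawing at least the observed number of common
#' edges when `|A|` edges are drawn at random from the edge universe.
#'
#' @param mask_a,mask_b Equal-length logical vectors over the edge universe.
#' @return List: `n_a`, `n_b`, `n_common`, `jaccard`, `enrichment_p`.
#' @export
overlap_significant <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b)) stopf("mask lengths differ")
  mask_a <- as.logical(mask_a); mask_b <- as.logical(mask_b)
  n_a <- sum(mask_a); n_b <- sum(mask_b)
  n_common <- sum(mask_a & mask_b)
  uni <- sum(mask_a | mask_b)
  jac <- if (uni == 0) NA_real_ else n_common / uni
  # P(X >= n_common), X ~ Hypergeom(drawing n_a from length(mask) with n_b marked)
  enr <- stats::phyper(n_common - 1, n_b, length(mask_b) - n_b, n_a,
                       lower.tail = FALSE)
  list(n_a = n_a, n_b = n_b, n_common = n_common, jaccard = jac,
       enrichment_p = enr)
}
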