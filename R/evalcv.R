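#' Construct a label table
#'
#' Bundles the subjects x labels matrix with per-label kinds.  Binary
#' labels must be coded exactly 0/1 (e.g. female = 0, male = 1); missing
#' values are rejected, matching the convention of excluding subjects with
#' incomplete labels before analysis.
#'
#' @param values Numeric matrix or data frame, subjects x labels.
#' @param kinds Character vector, one of `"continuous"` or `"binary"` per
#'   label; recycled names from `colnames(values)` if unnamed.
#' @param subject_ids Optional subject identifiers.
#' @return An object of class `label_table` with fields `values`, `names`,
#'   `kinds`, `subject_ids`.
#' @export
label_table <- function(values, kinds, subject_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("label values must be numeric")
  if (anyNA(values)) {
    bad <- which(rowSums(is.na(values)) > 0)
    ids <- if (!is.null(subject_ids)) subject_ids[bad] else bad
    stopf("missing label values for subject(s): %s", paste(ids, collapse = ", "))
  }
  M <- ncol(values)
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("label", seq_len(M))
  if (length(kinds) == 1L) kinds <- rep(kinds, M)
  if (length(kinds) != M) stopf("`kinds` must have one entry per label")
  kinds <- match.arg(kinds, c("continuous", "binary"), several.ok = TRUE)
  for (m in which(kinds == "binary")) {
    if (!all(values[, m] %in% c(0, 1)))
      stopf("binary label '%s' must be coded exactly {0, 1}", nm[m])
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(nrow(values)))
  if (anyDuplicated(subject_ids)) stopf("duplicate subject ids")
  dimnames(values) <- list(subject_ids, nm)
  structure(list(values = values, names = nm, kinds = kinds,
                 subject_ids = subject_ids),
            class = "label_table")
}

#' Random (optionally family-aware) cross-validation folds
#'
#' Partitions `n` subjects into `k` folds whose sizes differ by at most
#' one.  With `family_id` given, whole families are kept together: families
#' are assigned greedily, largest first, onto the currently smallest fold,
#' so that no family is split across training and testing sets.
#'
#' @param n Number of subjects.
#' @param k Number of folds (e.g. 10; with n = 990 each test fold holds 99
#'   subjects and each training complement 891).
#' @param seed Integer seed; the plan is a pure function of `(n, k, seed,
#'   family_id)`.
#' @param family_id Optional per-subject family/group identifiers.
#' @return An object of class `fold_plan`: `k`, integer `assignment` in
#'   `1..k`, `grouped` flag and `seed`.
#' @export
make_folds <- function(n, k, seed = 1L, family_id = NULL) {
  n <- check_count(n, "n", 2L)
  k <- check_count(k, "k", 2L)
  if (k > n) stopf("k = %d exceeds n = %d", k, n)
  if (is.null(family_id)) {
    assignment <- with_seed(seed, sample(rep_len(seq_len(k), n)))
    grouped <- FALSE
  } else {
    if (length(family_id) != n) stopf("family_id must have length n")
    fam <- as.character(family_id)
    sizes <- table(fam)
    if (k > length(sizes))
      stopf("k = %d exceeds the number of families (%d)", k, length(sizes))
    # shuffle first so ties among equal-sized families are broken at random,
    # then largest-first onto the currently smallest fold
    ord <- with_seed(seed, sample(length(sizes)))
    sizes <- sizes[ord]
    sizes <- sizes[order(-as.integer(sizes))]
    fold_of_family <- integer(length(sizes))
    names(fold_of_family) <- names(sizes)
    load <- integer(k)
    for (f in seq_along(sizes)) {
      tgt <- which.min(load)
      fold_of_family[f] <- tgt
      load[tgt] <- load[tgt] + as.integer(sizes[f])
    }
    assignment <- unname(fold_of_family[fam])
    grouped <- TRUE
  }
  structure(list(k = k, assignment = as.integer(assignment),
                 grouped = grouped, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Threshold continuous estimates into a binary decision
#'
#' Estimates at or above 0.5 become class 1, below 0.5 class 0 (the
#' male/female decision rule for a 1/0-coded gender label).
#'
#' @param estimates Numeric vector of model estimates.
#' @return Integer vector of 0/1 decisions.
#' @export
classify_binary <- function(estimates) {
  if (any(!is.finite(estimates))) stopf("non-finite estimate(s)")
  as.integer(estimates >= 0.5)
}

#' Estimation metrics
#'
#' `metric_pearson_r` and `metric_rmse` score continuous labels by the
#' Pearson correlation and root-mean-square error between actual and
#' estimated values; `metric_auc` scores binary labels by the area under
#' the ROC curve computed from the rank statistic (ties count 1/2).
#'
#' @param actual,estimated Equal-length numeric vectors; for `metric_auc`,
#'   `actual` is 0/1 and `scores` are the continuous estimates.
#' @param scores Continuous scores for `metric_auc`.
#' @return A single number.
#' @export
metric_pearson_r <- function(actual, estimated) {
  if (length(actual) != length(estimated)) stopf("length mismatch")
  if (length(actual) < 3L) stopf("need at least 3 pairs for a correlation")
  if (stats::sd(actual) == 0 || stats::sd(estimated) == 0)
    stopf("zero variance: Pearson R undefined")
  stats::cor(actual, estimated)
}

#' @rdname metric_pearson_r
#' @export
metric_rmse <- function(actual, estimated) {
  if (length(actual) != length(estimated)) stopf("length mismatch")
  sqrt(mean((actual - estimated)^2))
}

#' @rdname metric_pearson_r
#' @export
metric_auc <- function(actual, scores) {
  if (length(actual) != length(scores)) stopf("length mismatch")
  if (!all(actual %in% c(0, 1))) stopf("`actual` must be coded {0, 1}")
  n1 <- sum(actual == 1); n0 <- sum(actual == 0)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present for AUC")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[actual == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Precompute per-fold centered training features and centered test features
# (test rows centered with TRAINING means only; no leakage).
prep_fold_features <- function(X, folds) {
  lapply(seq_len(folds$k), function(f) {
    te <- which(folds$assignment == f)
    tr <- which(folds$assignment != f)
    xm <- colMeans(X[tr, , drop = FALSE])
    list(train = tr, test = te,
         Xc = sweep(X[tr, , drop = FALSE], 2L, xm),
         Xt = sweep(X[te, , drop = FALSE], 2L, xm),
         x_mean = xm)
  })
}

# Shared CV engine: given precomputed fold features and a label matrix,
# fit SIMPLS per fold and pool test-set predictions.  Returns pooled
# predictions and the running sum of per-fold B matrices.
cv_engine <- function(pre, Y, d) {
  n <- nrow(Y); M <- ncol(Y)
  pred <- matrix(NA_real_, n, M)
  Bsum <- NULL
  for (fold in pre) {
    Ytr <- Y[fold$train, , drop = FALSE]
    ym <- colMeans(Ytr)
    B <- simpls_B(fold$Xc, sweep(Ytr, 2L, ym), d)
    pred[fold$test, ] <- fold$Xt %*% B + rep(ym, each = length(fold$test))
    Bsum <- if (is.null(Bsum)) B else Bsum + B
  }
  list(pred = pred, Bsum = Bsum)
}

metric_row <- function(actual, est, kind) {
  if (kind == "continuous") {
    c(R = metric_pearson_r(actual, est), RMSE = metric_rmse(actual, est),
      ACC = NA_real_, AUC = NA_real_)
  } else {
    c(R = NA_real_, RMSE = NA_real_,
      ACC = mean(classify_binary(est) == actual),
      AUC = metric_auc(actual, est))
  }
}

#' Cross-validated multi-label PLS estimation
#'
#' Runs the k-fold protocol: within each fold the PLS model (including the
#' feature and label means used for centering) is fitted on training
#' subjects only and applied to the held-out subjects, so every subject is
#' estimated exactly once by a model that never saw it.  Metrics are
#' computed on the predictions pooled across folds: Pearson R and RMSE for
#' continuous labels, thresholded accuracy and AUC for binary labels.
#'
#' @param features A `feature_matrix` (or plain numeric matrix).
#' @param labels A `label_table`.
#' @param label_use Optional character vector selecting the labels entered
#'   into the model (default: all).
#' @param d Number of latent variables (default 50).
#' @param folds A `fold_plan` from [make_folds()].
#' @param keep_models Keep the per-fold `pls_model` objects (default TRUE).
#' @return An object of class `cv_result`: pooled `predictions` (n x M),
#'   `metrics` data frame (label, kind, R, RMSE, ACC, AUC), `B_bar` (the
#'   fold-averaged coefficient matrix), `folds`, `d`, and per-fold models.
#' @export
run_cv <- function(features, labels, label_use = NULL, d = 50, folds,
                   keep_models = TRUE) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (!inherits(labels, "label_table")) stopf("`labels` must be a label_table")
  if (!inherits(folds, "fold_plan")) stopf("`folds` must be a fold_plan")
  if (nrow(X) != nrow(labels$values)) stopf("feature and label row counts differ")
  if (length(folds$assignment) != nrow(X)) stopf("fold plan does not match subject count")
  if (is.null(label_use)) label_use <- labels$names
  miss <- setdiff(label_use, labels$names)
  if (length(miss)) stopf("unknown label name(s): %s", paste(miss, collapse = ", "))
  sel <- match(label_use, labels$names)
  Y <- labels$values[, sel, drop = FALSE]
  kinds <- labels$kinds[sel]
  n_train_min <- nrow(X) - max(tabulate(folds$assignment, folds$k))
  if (d >= n_train_min)
    stopf("d = %d too large for the smallest training fold (n = %d)", d, n_train_min)

  pre <- prep_fold_features(X, folds)
  models <- if (keep_models) vector("list", folds$k) else NULL
  n <- nrow(X); M <- ncol(Y)
  pred <- matrix(NA_real_, n, M, dimnames = list(rownames(X), colnames(Y)))
  Bsum <- NULL
  for (f in seq_len(folds$k)) {
    fold <- pre[[f]]
    fit <- pls_fit(X[fold$train, , drop = FALSE], Y[fold$train, , drop = FALSE], d)
    pred[fold$test, ] <- pls_predict(fit, X[fold$test, , drop = FALSE])
    Bsum <- if (is.null(Bsum)) fit$B else Bsum + fit$B
    if (keep_models) models[[f]] <- fit
  }
  dimnames(Bsum) <- list(colnames(X), colnames(Y))
  met <- t(vapply(seq_len(M), function(m) metric_row(Y[, m], pred[, m], kinds[m]),
                  numeric(4)))
  metrics <- data.frame(label = colnames(Y), kind = kinds, met,
                        row.names = NULL, check.names = FALSE)
  structure(list(predictions = pred, metrics = metrics,
                 B_bar = Bsum / folds$k, folds = folds, d = d,
                 label_names = colnames(Y), kinds = kinds,
                 models = models),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validated PLS estimation: %d folds, d = %d\n", x$folds$k, x$d))
  print(x$metrics, digits = 3)
  invisible(x)
}

#' Run the four canonical estimation sets
#'
#' Reproduces the four-way experimental layout: (set1) all labels of the
#' main group estimated simultaneously, (set2) all labels of the
#' supplementary group, (set3) the union of both groups in one joint model,
#' and (set4) each main-group label estimated alone (single-label
#' learning).  All sets share one fold plan so differences between them
#' reflect only the labels entered into the model.
#'
#' @param features A `feature_matrix`.
#' @param labels A `label_table`.
#' @param main_labels,supp_labels Character vectors naming the two label
#'   groups.
#' @param d Latent variables per model (default 50).
#' @param folds A shared `fold_plan`.
#' @return Named list of `cv_result`: `set1_main`, `set2_supp`,
#'   `set3_all`, and `set4_single_<label>` for each main label.
#' @export
run_estimation_sets <- function(features, labels, main_labels,
                                supp_labels = character(0), d = 50, folds) {
  out <- list()
  out$set1_main <- run_cv(features, labels, main_labels, d, folds, keep_models = FALSE)
  if (length(supp_labels)) {
    out$set2_supp <- run_cv(features, labels, supp_labels, d, folds, keep_models = FALSE)
    out$set3_all <- run_cv(features, labels, c(main_labels, supp_labels), d,
                           folds, keep_models = FALSE)
  }
  for (lab in main_labels)
    out[[paste0("set4_single_", lab)]] <-
      run_cv(features, labels, lab, d, folds, keep_models = FALSE)
  out
}

#' Sweep one experimental factor with everything else fixed
#'
#' Re-runs the cross-validated estimation while varying either the number
#' of latent variables (`axis = "d"`) or the feature variant (`axis =
#' "variant"`, e.g. connectivity method or ROI count), holding the fold
#' plan and all other settings fixed, and returns a tidy long table.
#'
#' @param features For `axis = "d"`: one `feature_matrix`.  For `axis =
#'   "variant"`: a named list of `feature_matrix` objects, one per variant.
#' @param labels A `label_table`.
#' @param axis `"d"` or `"variant"`.
#' @param values For `axis = "d"`: the d values (e.g. `seq(10, 150, 10)`).
#'   For `axis = "variant"`: the variant names to run (default: all).
#' @param label_use Labels entered into each model (default: all).
#' @param d Fixed d for variant sweeps (default 50).
#' @param folds Shared `fold_plan`.
#' @return Data frame with columns `variant`, `label`, `kind`, `R`,
#'   `RMSE`, `ACC`, `AUC`.
#' @export
sweep_cv <- function(features, labels, axis = c("d", "variant"), values = NULL,
                     label_use = NULL, d = 50, folds) {
  axis <- match.arg(axis)
  if (axis == "d") {
    if (is.null(values) || !length(values)) stopf("`values` must list the d values to sweep")
    runs <- lapply(values, function(dv)
      cbind(variant = dv,
            run_cv(features, labels, label_use, dv, folds, keep_models = FALSE)$metrics))
  } else {
    if (!is.list(features) || is.null(names(features)))
      stopf("variant sweeps need a named list of feature matrices")
    if (is.null(values)) values <- names(features)
    miss <- setdiff(values, names(features))
    if (length(miss)) stopf("missing variant feature matrices: %s", paste(miss, collapse = ", "))
    runs <- lapply(values, function(v)
      cbind(variant = v,
            run_cv(features[[v]], labels, label_use, d, folds, keep_models = FALSE)$metrics))
  }
  do.call(rbind, runs)
}
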