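test_that("fold plans are balanced and reproducible", {
  f <- make_folds(990, 10, seed = 4)
  expect_equal(unname(table(f$assignment)), rep(99L, 10), ignore_attr = TRUE)
  expect_true(all(990 - tabulate(f$assignment) == 891))
  expect_identical(f, make_folds(990, 10, seed = 4))
  expect_false(identical(f$assignment, make_folds(990, 10, seed = 5)$assignment))
  # leave-one-out degenerate balance
  loo <- make_folds(7, 7, seed = 1)
  expect_equal(sort(loo$assignment), 1:7)
  expect_error(make_folds(5, 6, seed = 1), "exceeds")
})

test_that("grouped folds never split a family and balance like the enumeration optimum", {
  fam <- rep(c("f1", "f2", "f3"), c(3, 3, 4))
  f <- make_folds(10, 2, seed = 2, family_id = fam)
  tab <- table(fam, f$assignment)
  expect_true(all(rowSums(tab > 0) == 1))  # each family in exactly one fold
  # exhaustive enumeration over the 2^3 family-to-fold assignments: the
  # minimal achievable imbalance puts {4} alone and {3,3} together
  sizes <- c(3, 3, 4)
  loads <- sapply(0:7, function(m) {
    bits <- as.integer(intToBits(m))[1:3]
    c(sum(sizes[bits == 1]), sum(sizes[bits == 0]))
  })
  valid <- loads[, apply(loads, 2, min) > 0, drop = FALSE]
  best <- min(apply(valid, 2, max))
  expect_equal(max(table(f$assignment)), best)  # = 6, i.e. {3,3} vs {4}
  expect_error(make_folds(10, 5, seed = 1, family_id = rep(c("a", "b"), 5)),
               "families")
})

test_that("classification threshold and metrics follow their definitions", {
  expect_equal(classify_binary(c(0.5, 0.49, -0.2, 1.7)), c(1L, 0L, 0L, 1L))
  expect_error(classify_binary(c(0.2, NaN)), "non-finite")
  expect_equal(metric_pearson_r(1:5, 1:5), 1)
  expect_equal(metric_rmse(1:5, 1:5), 0)
  # direct formula-evaluation oracle
  expect_equal(metric_pearson_r(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84),
               tolerance = 1e-12)
  expect_equal(metric_rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3), tolerance = 1e-12)
  expect_error(metric_pearson_r(c(1, 1, 1), 1:3), "zero variance")
  # AUC rank extremes and tie handling
  expect_equal(metric_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(metric_auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0)
  expect_equal(metric_auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_error(metric_auc(c(0, 0), c(0.1, 0.2)), "classes")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(40) + y
  expect_equal(metric_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("cross-validation covers every subject once and does not leak test labels", {
  ds <- tiny_dataset()
  inp <- dataset_to_inputs(ds)
  folds <- make_folds(60, 5, seed = 3)
  cv <- run_cv(inp$features, inp$labels, d = 8, folds = folds)
  expect_false(anyNA(cv$predictions))
  expect_equal(dim(cv$predictions), dim(inp$labels$values))
  # mutating the labels of one test fold must not change its predictions
  mut <- inp$labels
  te <- which(folds$assignment == 2)
  v <- mut$values; v[te, 1] <- v[te, 1] + 1000
  mut <- label_table(v, mut$kinds, mut$subject_ids)
  cv2 <- run_cv(inp$features, mut, d = 8, folds = folds)
  expect_equal(cv2$predictions[te, ], cv$predictions[te, ])
  # metrics are invariant to subject reordering of the pooled predictions
  perm <- sample(60)
  expect_equal(metric_pearson_r(inp$labels$values[perm, 1], cv$predictions[perm, 1]),
               cv$metrics$R[1])
  expect_error(run_cv(inp$features, inp$labels, d = 48, folds = folds), "too large")
  expect_error(run_cv(inp$features, inp$labels, "nope", 5, folds), "unknown label")
})

test_that("permuted labels estimate at chance on a strong-signal dataset", {
  ds <- simulate_dataset(sim_config(n_subjects = 150, n_rois = 10,
                                    n_timepoints = 150, effect_size = 5,
                                    label_spec = c(y = "continuous"), seed = 21))
  inp <- dataset_to_inputs(ds)
  folds <- make_folds(150, 5, seed = 6)
  cv <- run_cv(inp$features, inp$labels, d = 10, folds = folds)
  expect_gt(cv$metrics$R[1], 0.5)
  shuffled <- permute_labels(inp$labels, seed = 7)
  cvp <- run_cv(inp$features, shuffled, d = 10, folds = folds)
  expect_lt(abs(cvp$metrics$R[1]), 0.25)
})

test_that("the four estimation sets share folds and agree between joint and single fits", {
  ds <- simulate_dataset(sim_config(n_subjects = 120, n_rois = 12,
                                    n_timepoints = 200, effect_size = 4,
                                    label_spec = c(a = "continuous", b = "continuous",
                                                   g1 = "continuous", g2 = "binary"),
                                    seed = 22))
  inp <- dataset_to_inputs(ds)
  folds <- make_folds(120, 5, seed = 8)
  sets <- run_estimation_sets(inp$features, inp$labels,
                              main_labels = c("a", "b"),
                              supp_labels = c("g1", "g2"), d = 10, folds = folds)
  expect_named(sets, c("set1_main", "set2_supp", "set3_all",
                       "set4_single_a", "set4_single_b"))
  for (s in sets) expect_identical(s$folds, folds)
  # adding labels to the model barely moves the main-label accuracies
  expect_lt(max(abs(sets$set1_main$metrics$R -
                    sets$set3_all$metrics$R[1:2])), 0.1)
  expect_lt(abs(sets$set1_main$metrics$R[1] - sets$set4_single_a$metrics$R[1]), 0.1)
})

test_that("sweeps return one tidy row per variant and label", {
  ds <- tiny_dataset()
  inp <- dataset_to_inputs(ds)
  folds <- make_folds(60, 5, seed = 9)
  sw <- sweep_cv(inp$features, inp$labels, axis = "d", values = c(5, 10, 15),
                 label_use = c("age", "edu"), folds = folds)
  expect_equal(nrow(sw), 6)
  expect_setequal(unique(sw$variant), c(5, 10, 15))
  both <- list(partial = inp$features,
               full = dataset_to_inputs(ds, "full")$features)
  swv <- sweep_cv(both, inp$labels, axis = "variant", label_use = "age",
                  d = 8, folds = folds)
  expect_equal(swv$variant, c("partial", "full"))
  expect_error(sweep_cv(both, inp$labels, axis = "variant", values = "ica",
                        d = 8, folds = folds), "missing variant")
})
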