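test_that("simulated datasets honor the shape and determinism contracts", {
  cfg <- sim_config(n_subjects = 40, n_rois = 15, n_timepoints = 200, seed = 7)
  ds <- simulate_dataset(cfg)
  expect_length(ds$timeseries, 40)
  expect_true(all(vapply(ds$timeseries, function(x) all(dim(x) == c(200, 15)),
                         logical(1))))
  expect_equal(dim(ds$labels), c(40L, 4L))
  expect_false(anyNA(ds$labels))
  expect_identical(ds, simulate_dataset(cfg))
  # a different seed changes the data
  ds2 <- simulate_dataset(sim_config(n_subjects = 40, n_rois = 15,
                                     n_timepoints = 200, seed = 8))
  expect_false(identical(ds$labels, ds2$labels))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(n_rois = 5, n_effect_edges = 11), "exceeds")
  expect_error(sim_config(n_rois = 4, n_networks = 6, n_effect_edges = 3),
               "n_networks")
  expect_error(sim_config(n_subjects = 10, family_sizes = c(4, 4)), "family_sizes")
  expect_error(sim_config(inter_label_corr = 1.2), "inter_label_corr")
})

test_that("ground-truth masks point exactly at the planted edges", {
  ds <- tiny_dataset()
  for (m in seq_along(ds$true_effect_edges)) {
    mask <- ground_truth_mask(ds, m)
    expect_length(mask, nrow(ds$edge_map))
    expect_equal(which(mask), ds$true_effect_edges[[m]])
    expect_equal(sum(mask), ds$config$n_effect_edges)
  }
  expect_error(ground_truth_mask(ds, 99), "out of range")
  # no planted edges -> all-false mask
  ds0 <- simulate_dataset(sim_config(n_subjects = 10, n_rois = 6,
                                     n_timepoints = 50, n_effect_edges = 0,
                                     seed = 2))
  expect_false(any(ground_truth_mask(ds0, 1)))
})

test_that("binary labels are balanced and family intercepts are shared", {
  cfg <- sim_config(n_subjects = 60, n_rois = 10, n_timepoints = 80,
                    family_sizes = rep(3, 20), family_sd = 10,
                    label_spec = c(y = "continuous", g = "binary"), seed = 9)
  ds <- simulate_dataset(cfg)
  expect_equal(sum(ds$labels[, "g"]), 30)
  expect_equal(ds$family_id, rep(sprintf("fam%04d", 1:20), each = 3))
  # a large family intercept makes siblings' labels cluster: within-family
  # spread of the continuous label far below the between-family spread
  fam_means <- tapply(ds$labels[, "y"], ds$family_id, mean)
  within <- tapply(ds$labels[, "y"], ds$family_id, sd)
  expect_gt(sd(fam_means), 3 * median(within))
})

test_that("inter-label correlation is injected through the shared factor", {
  cfg <- sim_config(n_subjects = 400, n_rois = 8, n_timepoints = 50,
                    effect_size = 0, inter_label_corr = 0.6,
                    label_spec = c(a = "continuous", b = "continuous"),
                    seed = 10)
  ds <- simulate_dataset(cfg)
  expect_lt(abs(cor(ds$labels)[1, 2] - 0.6), 0.12)
  cfg0 <- sim_config(n_subjects = 400, n_rois = 8, n_timepoints = 50,
                     effect_size = 0, inter_label_corr = 0,
                     label_spec = c(a = "continuous", b = "continuous"),
                     seed = 10)
  expect_lt(abs(cor(simulate_dataset(cfg0)$labels)[1, 2]), 0.15)
})

test_that("planted effect edges raise connectivity on exactly those edges", {
  ds <- simulate_dataset(sim_config(n_subjects = 80, n_rois = 12,
                                    n_timepoints = 300, n_effect_edges = 6,
                                    n_networks = 12,  # no network structure
                                    network_loading = 0, network_loading_sd = 0,
                                    label_spec = c(y = "continuous"), seed = 12))
  fm <- build_feature_matrix(ds$timeseries, "full")
  mask <- ground_truth_mask(ds, 1)
  mean_r <- colMeans(fm$values)
  expect_gt(min(mean_r[mask]), max(abs(mean_r[!mask])) )
})

test_that("dataset files round-trip through the plain-text writer", {
  ds <- simulate_dataset(sim_config(n_subjects = 6, n_rois = 5,
                                    n_timepoints = 20, n_effect_edges = 3,
                                    seed = 13))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("manifest.tsv", "labels.tsv",
                                               "ground_truth.json")))))
  back <- read_dataset(dir)
  expect_equal(back$subject_ids, ds$subject_ids)
  expect_equal(back$family_id, ds$family_id)
  expect_equal(back$timeseries[[4]], ds$timeseries[[4]],
               tolerance = 1e-12, ignore_attr = TRUE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$true_effect_edges[[1]], ds$true_effect_edges[[1]])
})
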