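#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the defaults of
#' the full-scale protocol: `d = 50` latent variables, 10-fold
#' cross-validation, 5000 permutations, significance at `alpha = 0.05`
#' (strict), ridge-regularized partial correlation with `rho = 0.01`, and
#' RBF bandwidth `sigma = 150` for the kernel variant.
#'
#' @param d,k_folds,n_perm,alpha,conn_method,rho,kernel_sigma,target_k See
#'   description.
#' @param main_labels,supp_labels Label groups for the four estimation
#'   sets; `NULL` main group means all continuous labels.
#' @param grouped_cv Keep families intact across folds.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(d = 50, k_folds = 10, n_perm = 5000, alpha = 0.05,
                            conn_method = c("partial", "full"), rho = 0.01,
                            kernel_sigma = 150, target_k = 10,
                            main_labels = NULL, supp_labels = character(0),
                            grouped_cv = FALSE, seed = 1L) {
  conn_method <- match.arg(conn_method)
  structure(list(d = check_count(d, "d"), k_folds = check_count(k_folds, "k_folds", 2L),
                 n_perm = check_count(n_perm, "n_perm"), alpha = alpha,
                 conn_method = conn_method, rho = rho,
                 kernel_sigma = kernel_sigma, target_k = target_k,
                 main_labels = main_labels, supp_labels = supp_labels,
                 grouped_cv = grouped_cv, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the whole estimation framework end-to-end
#'
#' Orchestrates connectivity construction, the four cross-validated
#' estimation sets, permutation significance of accuracies and edge
#' weights, and the network-level contribution analysis, writing all
#' results plus a manifest (configuration echo, seed, package version) to
#' a run directory.  A rerun with the identical configuration and inputs
#' reproduces all numeric outputs exactly.
#'
#' @param timeseries List of per-subject timepoints x ROIs matrices (e.g.
#'   `syn_dataset$timeseries` or [read_dataset()]`$timeseries`).
#' @param labels A `label_table`.
#' @param config A `pipeline_config`.
#' @param out_dir Output directory; created if needed.  `NULL` skips file
#'   output.
#' @param family_id Optional per-subject family ids for grouped folds.
#' @return Invisibly, a list with `features`, `folds`, `sets` (named
#'   `cv_result`s), `perm` (multi-label `perm_result`), `perm_single`
#'   (first main label), `partition`, `contribution`, `config`.
#' @export
run_pipeline <- function(timeseries, labels, config = pipeline_config(),
                         out_dir = NULL, family_id = NULL) {
  if (!inherits(config, "pipeline_config")) stopf("`config` must be a pipeline_config")
  if (!inherits(labels, "label_table")) stopf("`labels` must be a label_table")
  t0 <- Sys.time()
  log_stage <- function(stage, event) {
    message(sprintf("[%s] %s elapsed=%.1fs", stage, event,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  log_stage("connectivity", "start")
  features <- build_feature_matrix(timeseries, config$conn_method, config$rho,
                                   labels$subject_ids)
  log_stage("connectivity", sprintf("done n=%d edges=%d", nrow(features$values),
                                    ncol(features$values)))

  main <- config$main_labels %||% labels$names[labels$kinds == "continuous"]
  supp <- config$supp_labels
  folds <- make_folds(nrow(features$values), config$k_folds, config$seed,
                      family_id = if (config$grouped_cv) family_id else NULL)

  log_stage("crossval", "start")
  sets <- run_estimation_sets(features, labels, main, supp, config$d, folds)
  log_stage("crossval", sprintf("done sets=%d", length(sets)))

  log_stage("permute", sprintf("start n_perm=%d", config$n_perm))
  perm <- run_permutation_test(features, labels, main, config$d, folds,
                               config$n_perm, config$alpha, config$seed)
  perm_single <- run_permutation_test(features, labels, main[1L], config$d,
                                      folds, config$n_perm, config$alpha,
                                      config$seed)
  log_stage("permute", "done")

  log_stage("contrib", "start")
  sim <- roi_profile_similarity(features)
  target_k <- min(config$target_k, attr(features$edge_map, "p") - 1L)
  partition <- ap_cluster(sim, target_k)
  contrib <- lapply(seq_along(main), function(m)
    summarize_contribution(perm$sig_mask[, m], features$edge_map, partition))
  names(contrib) <- main
  log_stage("contrib", "done")

  out <- list(features = features, folds = folds, sets = sets, perm = perm,
              perm_single = perm_single, partition = partition,
              contribution = contrib, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(out_dir, "features.tsv"))
    metrics <- do.call(rbind, lapply(names(sets), function(nm)
      cbind(set = nm, sets[[nm]]$metrics)))
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(edge = seq_len(nrow(perm$p_weight)), perm$p_weight,
                 check.names = FALSE),
      file.path(out_dir, "p_weight.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    utils::write.table(
      data.frame(roi = seq_along(partition$assignment),
                 network = partition$assignment,
                 exemplar = partition$exemplars[partition$assignment]),
      file.path(out_dir, "networks.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    manifest <- list(
      package = "plsconn",
      version = as.character(utils::packageVersion("plsconn")),
      seed = config$seed,
      config = unclass(config),
      config_hash = config_hash(config),
      p_accuracy = as.list(perm$p_accuracy),
      n_significant_edges = as.list(colSums(perm$sig_mask)))
    write_results(manifest, file.path(out_dir, "manifest.json"))
  }
  invisible(out)
}

# Stable fingerprint of a configuration (no external digest dependency):
# serialize deterministically and hash with a small FNV-1a loop.
config_hash <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 2, xdr = TRUE)
  h <- 2166136261
  for (byte in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), byte)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
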