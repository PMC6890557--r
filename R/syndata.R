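#' Configuration of the synthetic resting-state study
#'
#' Defines one synthetic "study": network-structured ROI time-series per
#' subject, a sparse set of planted "effect" edges per label whose
#' subject-to-subject connectivity strength carries the signal, continuous
#' labels that are linear in those strengths plus unit-variance Gaussian
#' noise, optional binary labels obtained by median-thresholding a latent
#' continuous variable (balanced classes), a shared subject factor that
#' induces inter-label correlation, and optional family structure acting as
#' a shared additive intercept.
#'
#' The generative law per subject s and ROI i is
#' \deqn{x_i(t) = \lambda_{s,g(i)} z_{g(i)}(t) + \sum_{e \ni i} c_{s,e}
#'   w_e(t) + \sigma_u \epsilon_i(t)}
#' where \eqn{z_g} are network latent signals (one per network g),
#' \eqn{w_e} are effect-edge latent signals shared by the edge's two ROIs,
#' \eqn{c_{s,e} = c_0 + c_1 \eta_{s,e}} is the subject's standardized edge
#' strength mapped onto a loading, and \eqn{\lambda_{s,g}} varies around
#' `network_loading` across subjects so that indirect (network-mediated)
#' correlations fluctuate between subjects as they do in real data.
#' Continuous label m is
#' \deqn{y_m = \mathrm{effect\_size} \cdot \textstyle\sum_e \beta_{m,e}
#'   \eta_{s,e} / \|\beta_m\| + f_{s} + \sqrt{\rho_L} g_s +
#'   \sqrt{1-\rho_L}\,\varepsilon_{s,m}}
#' with \eqn{\rho_L} = `inter_label_corr`, \eqn{g_s} the shared subject
#' factor and \eqn{f_s} the family intercept.  `effect_size = 0` makes
#' every label independent of every edge; large `effect_size` makes labels
#' essentially noise-free functions of the planted strengths.
#'
#' @param n_subjects,n_rois,n_timepoints,n_networks Dimensions of the
#'   study.
#' @param n_effect_edges Planted effect edges per label (must not exceed
#'   `n_rois * (n_rois - 1) / 2`).
#' @param effect_size Signal scale of the label model (noise sd is 1).
#' @param label_spec Named character vector of label kinds, values
#'   `"continuous"` or `"binary"`.
#' @param inter_label_corr Weight in `[0, 1]` of the shared subject factor
#'   in the label noise.
#' @param family_sizes Optional integer vector of family sizes summing to
#'   `n_subjects`; `NULL` means every subject is its own family.
#' @param family_sd Standard deviation of the family intercept (default 0).
#' @param edge_strength_mean,edge_strength_sd Map from standardized
#'   strength to loading: \eqn{c = c_0 + c_1 \eta}.
#' @param network_loading,network_loading_sd Mean and subject-level sd of
#'   the network loading \eqn{\lambda}.
#' @param noise_sd ROI-unique noise sd \eqn{\sigma_u}.
#' @param seed Master seed; all draws derive from it through per-block
#'   counters, so the dataset is a pure function of the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 300, n_rois = 15, n_timepoints = 200,
                       n_networks = 3, n_effect_edges = 10, effect_size = 3,
                       label_spec = c(age = "continuous", edu = "continuous",
                                      cog = "continuous", sex = "binary"),
                       inter_label_corr = 0.3, family_sizes = NULL,
                       family_sd = 0,
                       edge_strength_mean = 0.5, edge_strength_sd = 0.2,
                       network_loading = 0.8, network_loading_sd = 0.15,
                       noise_sd = 0.6, seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects", 2L)
  n_rois <- check_count(n_rois, "n_rois", 2L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", 3L)
  n_networks <- check_count(n_networks, "n_networks")
  n_effect_edges <- check_count(n_effect_edges, "n_effect_edges", 0L)
  E <- n_rois * (n_rois - 1) / 2
  if (n_effect_edges > E)
    stopf("n_effect_edges = %d exceeds the number of edges p(p-1)/2 = %d",
          n_effect_edges, E)
  if (n_networks > n_rois) stopf("n_networks exceeds n_rois")
  if (is.null(names(label_spec)) || !all(label_spec %in% c("continuous", "binary")))
    stopf("label_spec must be a named vector of 'continuous'/'binary'")
  if (inter_label_corr < 0 || inter_label_corr > 1)
    stopf("inter_label_corr must be in [0, 1]")
  if (!is.null(family_sizes)) {
    family_sizes <- vapply(family_sizes, check_count, integer(1), name = "family size")
    if (sum(family_sizes) != n_subjects)
      stopf("family_sizes sum to %d, not n_subjects = %d", sum(family_sizes), n_subjects)
  }
  if (effect_size < 0) stopf("effect_size must be non-negative")
  structure(list(n_subjects = n_subjects, n_rois = n_rois,
                 n_timepoints = n_timepoints, n_networks = n_networks,
                 n_effect_edges = n_effect_edges, effect_size = effect_size,
                 label_spec = label_spec, inter_label_corr = inter_label_corr,
                 family_sizes = family_sizes, family_sd = family_sd,
                 edge_strength_mean = edge_strength_mean,
                 edge_strength_sd = edge_strength_sd,
                 network_loading = network_loading,
                 network_loading_sd = network_loading_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic resting-state dataset
#'
#' Draws one dataset under the generative law documented in
#' [sim_config()].  The result is a pure function of the configuration
#' (including its seed): each logical block of draws (effect-edge
#' placement, subject-level strengths, per-subject time-series, label
#' noise) uses its own counter-derived sub-seed.
#'
#' @param config A `sim_config`.
#' @return An object of class `syn_dataset`: `timeseries` (list of
#'   timepoints x ROIs matrices), `labels` (subjects x labels matrix),
#'   `label_kinds`, `true_effect_edges` (per-label integer edge indices
#'   into the [edge_index_map()]), `true_coefficients`, `family_id`,
#'   `network_of_roi`, `edge_map`, `subject_ids`, `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stopf("`config` must be a sim_config")
  cf <- config
  n <- cf$n_subjects; p <- cf$n_rois; Tn <- cf$n_timepoints
  em <- edge_index_map(p); E <- nrow(em)
  M <- length(cf$label_spec)
  lab_names <- names(cf$label_spec)
  net <- sort(rep_len(seq_len(cf$n_networks), p))

  # block 1: effect-edge placement and coefficients
  eff <- with_seed(sub_seed(cf$seed, 1L), {
    lapply(seq_len(M), function(m) {
      e <- sort(sample.int(E, cf$n_effect_edges))
      b <- stats::runif(cf$n_effect_edges, 0.5, 1.5) *
        sample(c(-1, 1), cf$n_effect_edges, replace = TRUE)
      list(edges = e, beta = b)
    })
  })
  names(eff) <- lab_names
  all_eff <- sort(unique(unlist(lapply(eff, `[[`, "edges"))))
  nE <- length(all_eff)

  # block 2: subject-level latent draws
  draws <- with_seed(sub_seed(cf$seed, 2L), {
    list(eta = matrix(stats::rnorm(n * max(nE, 1L)), n, max(nE, 1L)),
         nu = matrix(stats::rnorm(n * cf$n_networks), n, cf$n_networks),
         g = stats::rnorm(n),
         eps = matrix(stats::rnorm(n * M), n, M))
  })

  # family structure
  if (is.null(cf$family_sizes)) {
    family_id <- sprintf("fam%04d", seq_len(n))
  } else {
    family_id <- sprintf("fam%04d", rep(seq_along(cf$family_sizes), cf$family_sizes))
  }
  fam_int <- with_seed(sub_seed(cf$seed, 3L), {
    u <- stats::rnorm(length(unique(family_id)), sd = cf$family_sd)
    u[match(family_id, unique(family_id))]
  })

  # block 4+: per-subject time-series (one sub-seed per subject, so the
  # series of subject s does not depend on how many subjects follow it)
  lam <- pmax(cf$network_loading + cf$network_loading_sd * draws$nu, 0.1)
  Cload <- matrix(0, p, max(nE, 1L))
  timeseries <- vector("list", n)
  for (s in seq_len(n)) {
    timeseries[[s]] <- with_seed(sub_seed(cf$seed, 1000L + s), {
      Z <- matrix(stats::rnorm(Tn * cf$n_networks), Tn, cf$n_networks)
      X <- Z[, net, drop = FALSE] *
        rep(lam[s, net], each = Tn)
      if (nE > 0L) {
        W <- matrix(stats::rnorm(Tn * nE), Tn, nE)
        cs <- pmax(0, cf$edge_strength_mean + cf$edge_strength_sd * draws$eta[s, seq_len(nE)])
        C <- Cload
        for (k in seq_len(nE)) {
          e <- all_eff[k]
          C[em$i[e], k] <- C[em$i[e], k] + cs[k]
          C[em$j[e], k] <- C[em$j[e], k] + cs[k]
        }
        X <- X + W %*% t(C)
      }
      X + cf$noise_sd * matrix(stats::rnorm(Tn * p), Tn, p)
    })
  }

  # labels
  labels <- matrix(NA_real_, n, M, dimnames = list(NULL, lab_names))
  rho_l <- cf$inter_label_corr
  for (m in seq_len(M)) {
    sig <- if (cf$n_effect_edges > 0L) {
      idx <- match(eff[[m]]$edges, all_eff)
      drop(draws$eta[, idx, drop = FALSE] %*% eff[[m]]$beta) /
        sqrt(sum(eff[[m]]$beta^2))
    } else rep(0, n)
    latent <- cf$effect_size * sig + fam_int +
      sqrt(rho_l) * draws$g + sqrt(1 - rho_l) * draws$eps[, m]
    labels[, m] <- if (cf$label_spec[m] == "binary")
      as.numeric(latent >= stats::median(latent))
    else latent
  }

  subject_ids <- sprintf("sub%04d", seq_len(n))
  rownames(labels) <- subject_ids
  structure(list(timeseries = timeseries, labels = labels,
                 label_kinds = unname(cf$label_spec),
                 true_effect_edges = lapply(eff, `[[`, "edges"),
                 true_coefficients = lapply(eff, `[[`, "beta"),
                 family_id = family_id, network_of_roi = net,
                 edge_map = em, subject_ids = subject_ids,
                 config = cf, seed = cf$seed),
            class = "syn_dataset")
}

#' Ground-truth effect-edge mask for one label
#'
#' @param dataset A `syn_dataset`.
#' @param label_index Label position (1-based) or label name.
#' @return Logical vector over the edge universe, TRUE exactly at the
#'   label's planted effect edges.
#' @export
ground_truth_mask <- function(dataset, label_index) {
  if (!inherits(dataset, "syn_dataset")) stopf("`dataset` must be a syn_dataset")
  M <- length(dataset$true_effect_edges)
  if (is.character(label_index))
    label_index <- match(label_index, colnames(dataset$labels))
  if (is.na(label_index) || label_index < 1 || label_index > M)
    stopf("label index out of range (1..%d)", M)
  mask <- logical(nrow(dataset$edge_map))
  mask[dataset$true_effect_edges[[label_index]]] <- TRUE
  mask
}

#' Convert a synthetic dataset to package containers
#'
#' @param dataset A `syn_dataset`.
#' @param method,rho Connectivity settings passed to
#'   [build_feature_matrix()].
#' @return List with `features` (a `feature_matrix`) and `labels` (a
#'   `label_table`).
#' @export
dataset_to_inputs <- function(dataset, method = c("partial", "full"), rho = 0.01) {
  method <- match.arg(method)
  list(features = build_feature_matrix(dataset$timeseries, method, rho,
                                       dataset$subject_ids),
       labels = label_table(dataset$labels,
                            ifelse(dataset$label_kinds == "binary", "binary",
                                   "continuous"),
                            dataset$subject_ids))
}

#' Write a synthetic dataset to plain-text files
#'
#' One headerless TSV per subject (timepoints x ROIs), a manifest TSV
#' (`subject_id`, `file`, `family_id`), a labels TSV (`subject_id` plus one
#' column per label) and a ground-truth JSON (effect edges, coefficients,
#' configuration echo).
#'
#' @param dataset A `syn_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "syn_dataset")) stopf("`dataset` must be a syn_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  files <- sprintf("timeseries/%s.tsv", dataset$subject_ids)
  for (s in seq_along(dataset$timeseries))
    utils::write.table(dataset$timeseries[[s]], file.path(dir, files[s]),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  manifest <- data.frame(subject_id = dataset$subject_ids, file = files,
                         family_id = dataset$family_id)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  lab <- data.frame(subject_id = dataset$subject_ids, dataset$labels,
                    check.names = FALSE)
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  gt <- list(true_effect_edges = dataset$true_effect_edges,
             true_coefficients = dataset$true_coefficients,
             label_kinds = as.list(stats::setNames(dataset$label_kinds,
                                                   colnames(dataset$labels))),
             edge_order = "lexicographic upper triangle, 1-based (i < j)",
             config = unclass(dataset$config))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read a synthetic dataset written by [write_dataset()]
#'
#' @param dir Directory holding `manifest.tsv`, per-subject time-series and
#'   `labels.tsv`.
#' @return List with `timeseries`, `labels` (data frame), `family_id`,
#'   `subject_ids`.
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stopf("no manifest.tsv under %s", dir)
  manifest <- utils::read.delim(man_path, stringsAsFactors = FALSE)
  ts <- lapply(manifest$file, function(f)
    as.matrix(utils::read.delim(file.path(dir, f), header = FALSE)))
  lab <- utils::read.delim(file.path(dir, "labels.tsv"), check.names = FALSE)
  list(timeseries = ts, labels = lab, family_id = manifest$family_id,
       subject_ids = manifest$subject_id)
}
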