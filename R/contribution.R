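#' Direct edge-label correlations and their ranking
#'
#' Correlates every edge feature directly with one label and ranks edges by
#' descending absolute correlation (ties broken by edge index).  Used to
#' ask whether the edges that carry significant model weight are also the
#' edges most strongly related to the label on their own — i.e. whether the
#' model relies on biologically meaningful connections.
#'
#' @param features A `feature_matrix` (or matrix).
#' @param label Numeric vector, one value per subject.
#' @return Data frame with columns `edge`, `r`, `rank` (rank 1 = largest
#'   `|r|`).
#' @export
direct_edge_correlations <- function(features, label) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (length(label) != nrow(X)) stopf("label length does not match subject count")
  if (nrow(X) < 3L) stopf("need at least 3 subjects")
  if (stats::sd(label) == 0) stopf("zero-variance label")
  r <- drop(stats::cor(X, label))
  ord <- order(-abs(r), seq_along(r))
  rank <- integer(length(r))
  rank[ord] <- seq_along(r)
  data.frame(edge = seq_along(r), r = r, rank = rank)
}

#' Percentage of top-ranked edges that are significant
#'
#' For each cutoff c, the percentage of the c edges most strongly
#' correlated with the label (by `|r|` rank) that also carry significant
#' model weight: `100 * |sig inter top-c| / c`.
#'
#' @param sig_mask Logical vector over edges.
#' @param ranks Integer ranks as returned by [direct_edge_correlations()]
#'   (rank 1 = strongest).
#' @param cutoffs Integer cutoffs, e.g. `c(10, 50, 100, 500)`.
#' @return Named numeric vector of percentages, one per cutoff.
#' @export
significant_among_top <- function(sig_mask, ranks, cutoffs) {
  if (!length(cutoffs)) stopf("`cutoffs` must be non-empty")
  if (length(sig_mask) != length(ranks)) stopf("mask and rank lengths differ")
  if (any(cutoffs > length(ranks))) stopf("cutoff exceeds edge count")
  out <- vapply(cutoffs, function(cc) 100 * sum(sig_mask[ranks <= cc]) / cc,
                numeric(1))
  names(out) <- paste0("top", cutoffs)
  out
}

#' Similarity between ROI connectivity profiles
#'
#' Pearson correlation between ROIs' group-mean connectivity profiles: row
#' i of the subject-averaged connectivity matrix (self-pair excluded
#' pairwise) describes how ROI i connects to all others; ROIs with similar
#' profiles belong to the same functional network.
#'
#' @param features A `feature_matrix`.
#' @return Symmetric p x p similarity matrix (diagonal 1).
#' @export
roi_profile_similarity <- function(features) {
  if (!inherits(features, "feature_matrix")) stopf("`features` must be a feature_matrix")
  p <- attr(features$edge_map, "p")
  mean_cm <- unvectorize(colMeans(features$values), p)
  sim <- matrix(1, p, p)
  for (i in seq_len(p - 1)) for (j in seq.int(i + 1, p)) {
    keep <- setdiff(seq_len(p), c(i, j))  # exclude the pair's own entries
    sim[i, j] <- sim[j, i] <- stats::cor(mean_cm[i, keep], mean_cm[j, keep])
  }
  sim
}

# One affinity-propagation run at a fixed shared preference.
ap_run <- function(S, preference, damping, max_iter, conv_iter) {
  p <- nrow(S)
  Sp <- S
  diag(Sp) <- preference
  R <- matrix(0, p, p); A <- matrix(0, p, p)
  stable <- 0L
  last_ex <- NULL
  for (iter in seq_len(max_iter)) {
    # responsibilities
    AS <- A + Sp
    top <- max.col(AS, ties.method = "first")
    first <- AS[cbind(seq_len(p), top)]
    AS[cbind(seq_len(p), top)] <- -Inf
    second <- do.call(pmax, as.data.frame(AS))
    Rnew <- Sp - first
    Rnew[cbind(seq_len(p), top)] <- Sp[cbind(seq_len(p), top)] - second
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, p, p, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(unname(diag(A) + diag(R)) > 0)
    if (!is.null(last_ex) && length(ex) == length(last_ex) && all(ex == last_ex)) {
      stable <- stable + 1L
      if (stable >= conv_iter && length(ex) > 0L)
        return(list(exemplars = ex, converged = TRUE, iter = iter))
    } else stable <- 0L
    last_ex <- ex
  }
  list(exemplars = last_ex, converged = FALSE, iter = max_iter)
}

ap_assign <- function(S, exemplars) {
  p <- nrow(S)
  Se <- S[, exemplars, drop = FALSE]
  cl <- max.col(Se, ties.method = "first")
  cl[exemplars] <- seq_along(exemplars)
  cl
}

#' Affinity-propagation clustering of ROIs into networks
#'
#' Exemplar-based clustering by responsibility/availability message
#' passing.  Affinity propagation controls the number of clusters only
#' indirectly through the shared preference (the self-similarity placed on
#' the diagonal), so the preference is tuned by bisection until exactly
#' `target_k` exemplars emerge; if `target_k` is unattainable the closest
#' achievable partition is returned with a warning.
#'
#' @param similarity Symmetric p x p similarity matrix.
#' @param target_k Desired number of networks (e.g. 10).
#' @param damping Message damping in `[0.5, 1)`; default 0.9.
#' @param max_iter Maximum message-passing iterations per run.
#' @param conv_iter Iterations of unchanged exemplars declaring
#'   convergence.
#' @param max_bisect Bisection steps over the preference.
#' @return An object of class `network_partition`: integer `assignment`
#'   (per ROI, 1..k), `k`, `exemplars` (per network ROI id),
#'   `preference_used`, `damping`.
#' @references Frey, B.J. and Dueck, D. (2007) Clustering by passing
#'   messages between data points. Science 315, 972-976.
#' @export
ap_cluster <- function(similarity, target_k, damping = 0.9, max_iter = 1000,
                       conv_iter = 50, max_bisect = 40) {
  S <- as.matrix(similarity)
  p <- nrow(S)
  if (ncol(S) != p || max(abs(S - t(S))) > 1e-8) stopf("similarity must be symmetric")
  target_k <- check_count(target_k, "target_k", 2L)
  if (target_k > p) stopf("target_k exceeds the number of ROIs")
  off <- S[row(S) != col(S)]
  lo <- min(off) - 2 * (max(off) - min(off)) - 1  # few clusters
  hi <- max(off) + 1e-6                            # many clusters
  run_at <- function(pref) ap_run(S, pref, damping, max_iter, conv_iter)
  best <- NULL
  any_converged <- FALSE
  for (b in seq_len(max_bisect)) {
    mid <- (lo + hi) / 2
    res <- run_at(mid)
    if (res$converged) {
      any_converged <- TRUE
      k <- length(res$exemplars)
      if (is.null(best) || abs(k - target_k) < abs(length(best$exemplars) - target_k)) {
        best <- res
        best$preference <- mid
      }
      if (k == target_k) break
      if (k < target_k) lo <- mid else hi <- mid
    } else {
      # treat non-convergence as oscillation toward too many clusters
      hi <- mid
    }
  }
  if (!any_converged)
    stopf("affinity propagation failed to converge at every trial preference; try higher damping")
  k <- length(best$exemplars)
  if (k != target_k)
    warning(sprintf("affinity propagation reached k = %d (target %d); returning closest achievable",
                    k, target_k), call. = FALSE)
  assignment <- ap_assign(S, best$exemplars)
  structure(list(assignment = assignment, k = k, exemplars = best$exemplars,
                 preference_used = best$preference, damping = damping),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("Network partition: %d networks over %d ROIs (preference %.4g)\n",
              x$k, length(x$assignment), x$preference_used))
  print(table(network = x$assignment))
  invisible(x)
}

#' Network-level contribution summary
#'
#' Counts, for the set of edges flagged as making significant
#' contributions: per ROI the number of incident significant edges, per
#' network the sum over its member ROIs, and per network pair the number of
#' significant edges with one endpoint in each (diagonal = within-network
#' edges).
#'
#' @param sig_mask Logical vector over the edge universe.
#' @param edge_map The [edge_index_map()] of the feature matrix.
#' @param partition A `network_partition` over the same ROIs.
#' @return An object of class `contribution_summary`: `per_roi_counts`,
#'   `per_network_totals`, `network_pair_counts` (k x k symmetric).
#' @export
summarize_contribution <- function(sig_mask, edge_map, partition) {
  p <- attr(edge_map, "p")
  if (length(sig_mask) != nrow(edge_map)) stopf("mask length does not match edge count")
  if (length(partition$assignment) != p) stopf("partition ROI count differs from edge map")
  sig <- which(as.logical(sig_mask))
  per_roi <- tabulate(c(edge_map$i[sig], edge_map$j[sig]), p)
  k <- partition$k
  per_net <- vapply(seq_len(k), function(g) sum(per_roi[partition$assignment == g]),
                    numeric(1))
  pair <- matrix(0L, k, k)
  for (e in sig) {
    a <- partition$assignment[edge_map$i[e]]
    b <- partition$assignment[edge_map$j[e]]
    pair[a, b] <- pair[a, b] + 1L
    if (a != b) pair[b, a] <- pair[b, a] + 1L
  }
  structure(list(per_roi_counts = per_roi,
                 per_network_totals = as.integer(per_net),
                 network_pair_counts = pair),
            class = "contribution_summary")
}
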