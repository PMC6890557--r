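# Construct a T x p data matrix whose sample covariance (1/(T-1)) equals
# Sigma exactly: whiten a random centered matrix, then color by chol(Sigma).
make_exact_cov_data <- function(Sigma, T, seed = 1) {
  p <- ncol(Sigma)
  set.seed(seed)
  Z <- matrix(rnorm(T * p), T, p)
  Zc <- scale(Z, scale = FALSE)
  W <- Zc %*% solve(chol(crossprod(Zc) / (T - 1)))
  W %*% chol(Sigma)
}

# Small deterministic dataset shared by several test files.
tiny_dataset <- function(n = 60, p = 10, Tn = 120, seed = 5, ...) {
  simulate_dataset(sim_config(n_subjects = n, n_rois = p, n_timepoints = Tn,
                              n_networks = 2, n_effect_edges = 5,
                              seed = seed, ...))
}

# The fixed 12-point, 3-cluster similarity used for the affinity
# propagation reference check (negative squared Euclidean distances).
ap_fixture_similarity <- function() {
  set.seed(99)
  centers <- rbind(c(0, 0), c(3, 0), c(0, 6))
  pts <- do.call(rbind, lapply(1:3, function(g)
    matrix(rnorm(8, sd = 0.3), 4, 2) + matrix(centers[g, ], 4, 2, byrow = TRUE)))
  -as.matrix(dist(pts))^2
}
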