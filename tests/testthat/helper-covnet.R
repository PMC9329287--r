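# Shared fixtures and independent oracles for the test suite.

# 4-region toy table: two homologue pairs on orthogonal sphere axes
toy_region_table <- function() {
  validate_region_table(data.frame(
    name = c("L_a", "R_a", "L_b", "R_b"),
    hemisphere = c("left", "right", "left", "right"),
    class = c("cortical", "cortical", "subcortical", "subcortical"),
    homologue = c("R_a", "L_a", "R_b", "L_b"),
    x = c(-50, 50, -10, 10), y = c(0, 0, 20, 20), z = c(10, 10, -20, -20),
    sx = c(-1, 1, 0, 0), sy = c(0, 0, 1, 1), sz = c(0, 0, 0, 0),
    stringsAsFactors = FALSE))
}

# random symmetric nonnegative weighted adjacency on n nodes
random_weighted_graph <- function(n, p_edge = 0.5) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- runif(length(ut)) < p_edge
  W[ut[on]] <- runif(sum(on), 0.1, 1)
  W + t(W)
}

# brute-force Onnela clustering by triple enumeration
oracle_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(rep(0, n))
  wh <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  C <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h)
        acc <- acc + wh[i, j] * wh[i, h] * wh[j, h]
    }
    C[i] <- acc / (k[i] * (k[i] - 1))
  }
  C
}

# Floyd-Warshall all-pairs shortest paths on 1/w edge lengths
oracle_path_length <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  D[W > 0] <- 1 / W[W > 0]
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  diag(D) <- NA
  D[is.infinite(D)] <- NA
  L <- rowMeans(D, na.rm = TRUE)
  L[!is.finite(L)] <- NA
  L
}

# reference Benjamini-Hochberg step-up adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# small multisite cohort for preprocessing/network tests
small_cohort_df <- function(n_sites = 4, n_per_group = 15, seed = 42, ...) {
  simulate_cohort(sim_config(n_sites = n_sites, n_per_group = n_per_group,
                             ...), seed = seed)
}

# wrap a bare adjacency as the thresholded-network structure
as_thresholded <- function(W, K = NA) {
  structure(list(W = W, K = K), class = "covnet_thresholded")
}

# smooth synthetic brain map: low-order function of the sphere coordinates
# plus GP-free smooth noise via neighbour averaging
smooth_map <- function(sphere_xyz, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- rnorm(3)
  raw <- as.numeric(sphere_xyz %*% b) + rnorm(nrow(sphere_xyz), 0, 0.5)
  as.numeric(scale(raw))
}
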