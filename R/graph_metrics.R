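# Weighted graph metrics: Onnela clustering, inverse-weight shortest
# paths, degree- and weight-preserving rewired nulls, and null-normalized
# topology (clustering, path length, small-world index).

.check_adjacency <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be a square matrix")
  if (any(W < 0)) stop("negative edge weight(s); threshold the network first")
  if (!isSymmetric(unname(W), tol = 1e-12)) stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  invisible(W)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node intensity of closed triangles. With weights rescaled by the
#' network maximum, `w' = W / max(W)`, the coefficient of node i is
#' `C_i = (2 / (k_i (k_i - 1))) * sum_{j<h} (w'_ij w'_ih w'_jh)^(1/3)`,
#' and `C_i = 0` where the degree `k_i < 2`. Values lie in `[0, 1]`.
#'
#' @param W symmetric nonnegative weighted adjacency, zero diagonal.
#' @return numeric vector of per-node coefficients.
#' @export
clustering_coefficient <- function(W) {
  .check_adjacency(W)
  k <- rowSums(W > 0)
  mx <- max(W)
  if (mx == 0) return(rep(0, nrow(W)))
  cw <- (W / mx)^(1 / 3)
  num <- diag(cw %*% cw %*% cw) # 2 * sum over triangles at i
  C <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  unname(C)
}

#' Characteristic path length per node
#'
#' Shortest-path distances with edge length `1/weight` (Dijkstra);
#' `L_i` is the mean distance from node i to every *reachable* node j != i
#' (unreachable pairs are excluded from the mean rather than entering as
#' infinite distances, which keeps L finite at sparse densities). A fully
#' isolated node gets `NA`.
#'
#' @inheritParams clustering_coefficient
#' @return numeric vector of per-node mean shortest-path distances.
#' @export
path_length <- function(W) {
  .check_adjacency(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  len <- 1 / igraph::E(g)$weight
  D <- igraph::distances(g, weights = len, algorithm = "dijkstra")
  diag(D) <- NA
  D[is.infinite(D)] <- NA
  L <- rowMeans(D, na.rm = TRUE)
  L[!is.finite(L)] <- NA
  unname(L)
}

#' Degree- and weight-preserving null network
#'
#' Rewires the binary topology by Maslov-Sneppen double-edge swaps
#' (`10 * |E|` attempted swaps) and re-assigns the original multiset of
#' edge weights to the rewired edges in random order. The degree sequence
#' and the weight multiset are preserved exactly; on graphs with no
#' topological freedom (e.g. complete graphs) the result is a
#' weight-shuffled copy.
#'
#' @inheritParams clustering_coefficient
#' @param seed optional integer seed for reproducibility.
#' @return rewired weighted adjacency matrix.
#' @export
make_null <- function(W, seed = NULL) {
  .check_adjacency(W)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  m <- igraph::ecount(g)
  if (m < 2) stop("need at least 2 edges to rewire")
  g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
  el <- igraph::as_edgelist(g2, names = FALSE)
  wts <- W[upper.tri(W)]
  wts <- sample(wts[wts > 0])
  Wn <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  Wn[el] <- wts
  Wn[el[, c(2, 1), drop = FALSE]] <- wts
  Wn
}

#' Null-normalized network topology
#'
#' Computes raw per-node and global clustering and path length, normalizes
#' each against the mean of an ensemble of degree- and weight-preserving
#' rewired networks, and forms the small-world index
#' `sigma = C_norm / L_norm` from the normalized global means.
#'
#' @inheritParams clustering_coefficient
#' @param n_nulls size of the null ensemble (study default 1000).
#' @param seed integer seed controlling the whole ensemble.
#' @return object of class `covnet_topology`: list with nodal vectors
#'   `C`, `L`, `C_norm`, `L_norm`, globals `C_global`, `L_global`,
#'   `C_norm_global`, `L_norm_global`, `sigma`, plus `n_nulls`.
#' @export
normalized_topology <- function(W, n_nulls = 1000, seed = NULL) {
  .check_adjacency(W)
  if (!is.null(seed)) set.seed(seed)
  C <- clustering_coefficient(W)
  L <- path_length(W)
  n <- nrow(W)
  Cn <- matrix(NA_real_, n_nulls, n)
  Ln <- matrix(NA_real_, n_nulls, n)
  for (b in seq_len(n_nulls)) {
    Wb <- make_null(W)
    Cn[b, ] <- clustering_coefficient(Wb)
    Ln[b, ] <- path_length(Wb)
  }
  C_null <- colMeans(Cn)
  L_null <- colMeans(Ln, na.rm = TRUE)
  norm_by <- function(x, null_mean) {
    out <- x / null_mean
    out[!is.finite(out)] <- NA
    out
  }
  C_global <- mean(C)
  L_global <- mean(L, na.rm = TRUE)
  C_norm_global <- C_global / mean(rowMeans(Cn))
  L_norm_global <- L_global / mean(rowMeans(Ln, na.rm = TRUE))
  structure(list(C = C, L = L,
                 C_norm = norm_by(C, C_null),
                 L_norm = norm_by(L, L_null),
                 C_global = C_global, L_global = L_global,
                 C_norm_global = C_norm_global,
                 L_norm_global = L_norm_global,
                 sigma = C_norm_global / L_norm_global,
                 n_nulls = n_nulls),
            class = "covnet_topology")
}

#' Raw nodal topology without null normalization
#'
#' Convenience wrapper returning nodal clustering and path length only;
#' used by site-wise group contrasts where the null normalization cancels
#' in patient-minus-control differences and can be switched off for speed.
#'
#' @inheritParams clustering_coefficient
#' @return list with vectors `C` and `L`.
#' @export
nodal_topology <- function(W) {
  list(C = clustering_coefficient(W), L = path_length(W))
}
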