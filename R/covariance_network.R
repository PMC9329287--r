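# Structural covariance networks: group/site correlation matrices,
# density thresholding over the K grid, connectedness screening, and
# positive-correlation strength.

#' Density grid used for network thresholding
#'
#' Densities K from 0.05 to 0.50 in steps of 0.01 (46 values).
#' @return numeric vector of densities.
#' @export
density_grid <- function() round(seq(5L, 50L), 10) / 100

# round half away from zero (positive argument)
.round_half_up <- function(x) floor(x + 0.5)

#' Number of edges retained at density K
#'
#' `round(K * n(n-1)/2)` with half rounded away from zero, so every group's
#' network has an identical edge count at a given density.
#'
#' @param K density in (0, 1].
#' @param n number of nodes.
#' @export
edge_count <- function(K, n) as.integer(.round_half_up(K * n * (n - 1) / 2))

#' Build a group- and site-specific covariance network
#'
#' Entry `R[i, j]` is the Pearson product-moment correlation of region `i`
#' and region `j` z-scores across the subjects of one diagnostic group at
#' one site. Site-groups below the minimum sample size are not trusted to
#' give stable correlations and are rejected.
#'
#' @param cohort `covnet_cohort`.
#' @param site,group site label and diagnostic group selecting the subjects.
#' @param min_subjects minimum group size (default 10); smaller groups
#'   raise a condition of class `covnet_skip` that callers may catch to
#'   skip the group.
#' @return object of class `covnet_covariance`: list with `R`, `site`,
#'   `group`, `n_subjects`.
#' @export
build_covariance <- function(cohort, site, group, min_subjects = 10) {
  stopifnot(inherits(cohort, "covnet_cohort"))
  idx <- cohort$meta$site == site & cohort$meta$group == group
  n_sub <- sum(idx)
  if (n_sub < min_subjects) {
    cond <- structure(
      class = c("covnet_skip", "error", "condition"),
      list(message = sprintf(
             "site '%s' group '%s' has %d subjects (< %d); skipped",
             site, group, n_sub, min_subjects),
           call = sys.call()))
    stop(cond)
  }
  X <- cohort$values[idx, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s) in site '", site, "' group '", group,
         "': ", paste(cohort$regions[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  diag(R) <- 0
  structure(list(R = R, site = site, group = group, n_subjects = n_sub),
            class = "covnet_covariance")
}

#' Threshold a covariance matrix at density K
#'
#' Negative correlations are set to zero, then the `edge_count(K, n)`
#' largest remaining off-diagonal correlations are retained with their
#' weights and everything else is zeroed. Ties at equal weight are broken
#' by lexicographic `(i, j)` order of the upper-triangle index, which makes
#' the retained edge set nested across densities. If fewer positive
#' correlations exist than the target edge count, all positives are kept
#' and the result is flagged.
#'
#' @param network `covnet_covariance`, or a bare symmetric correlation
#'   matrix.
#' @param K density.
#' @return object of class `covnet_thresholded`: list with weighted
#'   adjacency `W`, `K`, `edge_target`, `n_edges`, logical `insufficient`.
#' @export
threshold_network <- function(network, K) {
  R <- if (inherits(network, "covnet_covariance")) network$R else network
  if (!isSymmetric(unname(R), tol = 1e-12)) stop("correlation matrix not symmetric")
  n <- nrow(R)
  m <- edge_count(K, n)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  w <- R[ut]
  pos <- w > 0
  ord <- order(-w, ut[, 1], ut[, 2])
  ord <- ord[pos[ord]]
  keep <- utils::head(ord, m)
  W <- matrix(0, n, n, dimnames = dimnames(R))
  W[ut[keep, , drop = FALSE]] <- w[keep]
  W <- W + t(W)
  is_cov <- inherits(network, "covnet_covariance")
  structure(list(W = W, K = K, edge_target = m, n_edges = length(keep),
                 insufficient = length(keep) < m,
                 site = if (is_cov) network$site,
                 group = if (is_cov) network$group),
            class = "covnet_thresholded")
}

.largest_component_fraction <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  max(igraph::components(g)$csize) / nrow(W)
}

#' Does a density pass the connectedness criterion?
#'
#' A density is usable when, in at least `site_frac` of the site networks,
#' at least `node_frac` of the nodes belong to the largest connected
#' component.
#'
#' @param networks list of `covnet_thresholded` networks at one density
#'   (one or more per site).
#' @param node_frac,site_frac criterion fractions (defaults 0.75 and 0.90).
#' @return logical scalar.
#' @export
density_connected <- function(networks, node_frac = 0.75, site_frac = 0.90) {
  if (length(networks) == 0) stop("no networks supplied")
  frac <- vapply(networks, function(tn) .largest_component_fraction(tn$W),
                 numeric(1))
  mean(frac >= node_frac) >= site_frac
}

#' Screen the density grid for connectedness
#'
#' Thresholds every covariance matrix at each density of the grid and
#' applies the connectedness criterion. The valid range is the longest
#' contiguous run of passing densities (the last such run on ties, i.e.
#' the one extending to the densest end of the grid); regional analyses
#' use its smallest density.
#'
#' @param cov_list list of `covnet_covariance` objects (all sites/groups).
#' @param grid density grid, default [density_grid()].
#' @inheritParams density_connected
#' @return data.frame with columns `K` and `pass`; attributes
#'   `valid_range` (numeric length 2 or NULL) and `K_select`.
#' @export
connectedness_range <- function(cov_list, grid = density_grid(),
                                node_frac = 0.75, site_frac = 0.90) {
  if (length(cov_list) == 0) stop("no covariance networks supplied")
  pass <- vapply(grid, function(K) {
    nets <- lapply(cov_list, threshold_network, K = K)
    density_connected(nets, node_frac, site_frac)
  }, logical(1))
  out <- data.frame(K = grid, pass = pass)
  r <- rle(pass)
  if (any(r$values)) {
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs] + seq_along(r$values)[runs] * 1e-9)]
    hi <- cumsum(r$lengths)[best]
    lo <- hi - r$lengths[best] + 1
    attr(out, "valid_range") <- c(grid[lo], grid[hi])
    attr(out, "K_select") <- grid[lo]
  } else {
    attr(out, "valid_range") <- NULL
    attr(out, "K_select") <- NA_real_
  }
  out
}

#' Mean strength of retained positive correlations
#'
#' @param tn `covnet_thresholded`.
#' @return mean retained weight, or `NA` (with attribute `empty = TRUE`)
#'   for an edgeless network.
#' @export
mean_positive_strength <- function(tn) {
  w <- tn$W[upper.tri(tn$W)]
  w <- w[w > 0]
  if (length(w) == 0) return(structure(NA_real_, empty = TRUE))
  mean(w)
}
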