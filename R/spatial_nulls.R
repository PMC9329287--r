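# Spatial null models for parcellated brain maps: spin permutation on the
# merged cortical/subcortical sphere and variogram-matching surrogate maps.

#' Rotation matrix from three axis angles
#'
#' Product of elementary rotations about x (left-right), y
#' (rostral-caudal) and z (dorsal-ventral), applied in x, y, z order:
#' `R = Rz %*% Ry %*% Rx`.
#'
#' @param angles numeric length 3, radians.
#' @return 3 x 3 proper rotation matrix (orthogonal, det +1).
#' @export
rotation_matrix <- function(angles) {
  stopifnot(length(angles) == 3)
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Random sphere rotation
#'
#' Three angles drawn uniformly from `[0, 2*pi)` about the x, y and z
#' axes.
#'
#' @param seed optional integer seed.
#' @return list with `angles` and the 3 x 3 `R`.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  angles <- stats::runif(3, 0, 2 * pi)
  list(angles = angles, R = rotation_matrix(angles))
}

#' Nearest-neighbour assignment after a sphere rotation
#'
#' Rotates the unit-sphere coordinates and matches every rotated region to
#' the nearest original region by Euclidean distance (many-to-one matches
#' allowed). The identity rotation yields the identity mapping for any
#' coordinate set without duplicates.
#'
#' @param sphere_xyz n x 3 matrix of unit vectors.
#' @param R 3 x 3 rotation matrix.
#' @return integer vector `perm` (1-based): region i takes the value of
#'   region `perm[i]` in the spun map.
#' @export
spin_assignment <- function(sphere_xyz, R) {
  rot <- sphere_xyz %*% t(R)
  # for unit vectors, nearest Euclidean neighbour = largest dot product
  sim <- rot %*% t(sphere_xyz)
  max.col(sim, ties.method = "first")
}

#' Spin permutation test for the spatial correlation of two maps
#'
#' The empirical Pearson correlation of `map_x` and `map_y` is compared
#' with null correlations obtained by randomly rotating the merged
#' cortical/subcortical sphere, re-assigning `map_x` by nearest-neighbour
#' matching, and re-correlating with the fixed `map_y`. Both hemispheres
#' rotate jointly. The one-tailed p-value uses the add-one estimator
#' `p = (1 + #{r_null >= r_emp}) / (1 + n_perm)`.
#'
#' @param map_x,map_y numeric vectors, one value per region; `map_x` is
#'   the map that gets rotated.
#' @param sphere_xyz n x 3 unit-sphere coordinates (e.g. columns
#'   `sx, sy, sz` of the region table).
#' @param n_perm number of rotations (study default 10000).
#' @param seed integer seed.
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @param alternative `"greater"` (default, one-tailed positive),
#'   `"less"`, or `"two.sided"`.
#' @return object of class `covnet_spin`: list with `r`, `r_null`,
#'   `p_spin`, `n_perm`, `seed`.
#' @export
p_spin <- function(map_x, map_y, sphere_xyz, n_perm = 10000, seed = NULL,
                   method = c("pearson", "spearman"),
                   alternative = c("greater", "less", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (stats::sd(map_x) == 0 || stats::sd(map_y) == 0)
    stop("constant map: spatial correlation undefined")
  if (length(map_x) != nrow(sphere_xyz) || length(map_y) != nrow(sphere_xyz))
    stop("map length must equal the number of regions")
  if (!is.null(seed)) set.seed(seed)
  r_emp <- stats::cor(map_x, map_y, method = method)
  r_null <- vapply(seq_len(n_perm), function(b) {
    perm <- spin_assignment(sphere_xyz, random_rotation()$R)
    stats::cor(map_x[perm], map_y, method = method)
  }, numeric(1))
  p <- switch(alternative,
    greater = (1 + sum(r_null >= r_emp)) / (1 + n_perm),
    less = (1 + sum(r_null <= r_emp)) / (1 + n_perm),
    two.sided = (1 + sum(abs(r_null) >= abs(r_emp))) / (1 + n_perm))
  structure(list(r = r_emp, r_null = r_null, p_spin = p, n_perm = n_perm,
                 seed = seed, alternative = alternative),
            class = "covnet_spin")
}

#' Inter-regional distance matrix for surrogate-map nulls
#'
#' Geodesic (great-circle) distance on the sphere, scaled to a
#' `sphere_radius` mm sphere, between cortical region pairs;
#' three-dimensional Euclidean distance in anatomical coordinates for any
#' pair involving a subcortical region. Users with real surface meshes may
#' substitute exact geodesics by supplying their own matrix downstream.
#'
#' @param region_table validated region table.
#' @param sphere_radius radius (mm) used for the great-circle distances.
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
region_distance_matrix <- function(region_table, sphere_radius = 100) {
  s <- as.matrix(region_table[, c("sx", "sy", "sz")])
  xyz <- as.matrix(region_table[, c("x", "y", "z")])
  dots <- pmin(pmax(s %*% t(s), -1), 1)
  geo <- sphere_radius * acos(dots)
  euc <- as.matrix(stats::dist(xyz))
  ctx <- region_table$class == "cortical"
  D <- euc
  D[ctx, ctx] <- geo[ctx, ctx]
  diag(D) <- 0
  D
}

# precomputed pair index and bin assignment for the binned variogram
.variogram_bins <- function(D, nbins) {
  ut <- which(upper.tri(D), arr.ind = TRUE)
  h <- D[ut]
  breaks <- seq(0, max(h), length.out = nbins + 1)
  bin <- findInterval(h, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins)
  list(i = ut[, 1], j = ut[, 2], bin = bin, counts = counts, nbins = nbins)
}

# gamma(h) = 0.5 * mean (x_i - x_j)^2 per distance bin
.variogram <- function(x, vb) {
  g <- 0.5 * (x[vb$i] - x[vb$j])^2
  s <- rep(0, vb$nbins)
  tot <- rowsum(g, vb$bin)
  s[as.integer(rownames(tot))] <- tot
  out <- s / vb$counts
  out[vb$counts == 0] <- NA
  out
}

#' Variogram-matching surrogate maps
#'
#' Generates surrogate maps that preserve the distance-dependent variance
#' structure (variogram) of an input map: each surrogate is a random
#' permutation of the map, re-smoothed by an exponential-kernel average
#' over each region's k nearest neighbours -- k chosen from a candidate
#' grid by least-squares agreement between the surrogate's and the
#' empirical binned variograms (25 uniform distance bins) -- and
#' affine-rescaled (with white-noise nugget) to the empirical variogram.
#' With `knn = 0` the surrogates are plain permutations.
#'
#' @param map numeric vector.
#' @param D distance matrix from [region_distance_matrix()] or supplied.
#' @param n_surr number of surrogate maps.
#' @param seed integer seed.
#' @param knn candidate neighbourhood sizes; `0` disables smoothing.
#' @param nbins number of uniform distance bins.
#' @return matrix `n_regions x n_surr` of surrogate maps; attribute
#'   `variogram_sse` holds the per-surrogate fitted variogram discrepancy.
#' @export
variogram_surrogates <- function(map, D, n_surr, seed = NULL,
                                 knn = c(3, 5, 8, 12, 16, 20), nbins = 25) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(map)
  if (nrow(D) != n) stop("distance matrix does not match map length")
  if (any(knn >= n)) stop("k nearest neighbours must be smaller than n")
  vb <- .variogram_bins(D, nbins)
  g_emp <- .variogram(map, vb)
  # neighbour order and exponential-kernel weights per k, precomputed once
  ord <- t(apply(D, 1, order))       # col 1 is self (distance 0)
  kernels <- lapply(knn, function(k) {
    if (k == 0) return(NULL)
    nb <- ord[, 2:(k + 1), drop = FALSE]
    dk <- D[cbind(seq_len(n), nb[, k])]
    w <- exp(-D[cbind(rep(seq_len(n), k), as.vector(nb))] / rep(dk, k))
    w <- matrix(w, n, k)
    list(nb = nb, w = w / rowSums(w))
  })
  smooth_map <- function(x, ki) {
    krn <- kernels[[ki]]
    rowSums(krn$w * matrix(x[krn$nb], n))
  }
  surr <- matrix(NA_real_, n, n_surr)
  sse <- numeric(n_surr)
  for (b in seq_len(n_surr)) {
    perm <- sample(map)
    best <- NULL; best_sse <- Inf
    for (ki in seq_along(knn)) {
      if (knn[ki] == 0) {
        cand <- perm
      } else {
        sm <- smooth_map(perm, ki)
        # affine variogram match: g_emp ~ a + beta * g_cand
        g_sm <- .variogram(sm, vb)
        ok <- is.finite(g_emp) & is.finite(g_sm)
        fit <- stats::lm.fit(cbind(1, g_sm[ok]), g_emp[ok])
        a <- fit$coefficients[1]; bta <- fit$coefficients[2]
        cand <- mean(map) + sqrt(max(bta, 0)) * (sm - mean(sm)) +
          sqrt(max(a, 0)) * stats::rnorm(n)
      }
      g_cand <- .variogram(cand, vb)
      ok <- is.finite(g_emp) & is.finite(g_cand)
      s <- sum((g_emp[ok] - g_cand[ok])^2)
      if (s < best_sse) { best_sse <- s; best <- cand }
    }
    surr[, b] <- best
    sse[b] <- best_sse
  }
  attr(surr, "variogram_sse") <- sse
  surr
}

#' Variogram-matching permutation test
#'
#' One-tailed spatial-correlation test against surrogate maps with matched
#' spatial autocorrelation; same add-one p-value estimator as [p_spin()].
#'
#' @inheritParams p_spin
#' @param D distance matrix.
#' @param n_surr number of surrogates.
#' @param ... passed to [variogram_surrogates()].
#' @return list with `r`, `r_null`, `p_vgm`, `n_surr`.
#' @export
p_variogram <- function(map_x, map_y, D, n_surr = 1000, seed = NULL,
                        alternative = c("greater", "less", "two.sided"),
                        ...) {
  alternative <- match.arg(alternative)
  if (stats::sd(map_x) == 0 || stats::sd(map_y) == 0)
    stop("constant map: spatial correlation undefined")
  r_emp <- stats::cor(map_x, map_y)
  surr <- variogram_surrogates(map_x, D, n_surr, seed = seed, ...)
  r_null <- as.numeric(stats::cor(surr, map_y))
  p <- switch(alternative,
    greater = (1 + sum(r_null >= r_emp)) / (1 + n_surr),
    less = (1 + sum(r_null <= r_emp)) / (1 + n_surr),
    two.sided = (1 + sum(abs(r_null) >= abs(r_emp))) / (1 + n_surr))
  list(r = r_emp, r_null = r_null, p_vgm = p, n_surr = n_surr)
}
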