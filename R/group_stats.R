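# Group-level statistics: density-wise global t-tests with FDR, nodal
# Cohen's d maps, multivariate Hotelling T2 topology-change maps, and
# univariate atrophy effect sizes.

#' Density-wise global metric comparison across sites
#'
#' At every density, the patient and control values of one global metric
#' (one value per site and group) are compared with a paired two-tailed
#' t-test across sites; p-values are Benjamini-Hochberg adjusted across
#' densities. Zero-variance site differences are flagged: an exact zero
#' difference gives `t = 0, p = 1`, a constant nonzero shift gives a
#' degenerate infinite-t result with `p = 0`.
#'
#' @param patient,control numeric matrices, sites x densities, of the
#'   global metric per site network.
#' @param densities density labels (columns).
#' @param metric metric name carried through to the output.
#' @return data.frame with columns `metric`, `K`, `t`, `p`, `p_fdr`,
#'   `degenerate`, `sig_fdr` (p_fdr < 0.1), `sig_uncorr` (p < 0.05).
#' @export
global_density_tests <- function(patient, control, densities,
                                 metric = "metric") {
  if (!all(dim(patient) == dim(control)))
    stop("patient and control matrices must have identical dimensions")
  if (nrow(patient) < 3)
    stop("need at least 3 sites contributing both groups")
  res <- lapply(seq_along(densities), function(j) {
    d <- patient[, j] - control[, j]
    # numerically constant differences (an exact shift) are degenerate
    if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
      if (mean(d) == 0) c(t = 0, p = 1, deg = 0)
      else c(t = sign(mean(d)) * Inf, p = 0, deg = 1)
    } else {
      tt <- stats::t.test(d)
      c(t = unname(tt$statistic), p = tt$p.value, deg = 0)
    }
  })
  res <- do.call(rbind, res)
  out <- data.frame(metric = metric, K = densities,
                    t = res[, "t"], p = res[, "p"],
                    p_fdr = stats::p.adjust(res[, "p"], "BH"),
                    degenerate = res[, "deg"] == 1)
  out$sig_fdr <- out$p_fdr < 0.1
  out$sig_uncorr <- out$p < 0.05
  out
}

#' Per-region Cohen's d across sites
#'
#' Standardized mean difference of a nodal metric between patients and
#' controls, treating sites as observations: per region,
#' `d = (mean_pat - mean_ctrl) / s_pooled` with the (n-1) pooled sample SD.
#' A region with zero pooled SD is flagged `NA`.
#'
#' @param patient,control numeric matrices, sites x regions.
#' @return numeric vector of per-region effect sizes.
#' @export
cohens_d_map <- function(patient, control) {
  if (ncol(patient) != ncol(control))
    stop("patient and control must cover the same regions")
  if (nrow(patient) < 2 || nrow(control) < 2)
    stop("need at least 2 sites per group")
  n1 <- nrow(patient); n2 <- nrow(control)
  m1 <- colMeans(patient); m2 <- colMeans(control)
  v1 <- apply(patient, 2, stats::var)
  v2 <- apply(control, 2, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- (m1 - m2) / sp
  d[sp == 0] <- NA
  unname(d)
}

# Hotelling T2 of paired bivariate differences at one region.
.hotelling_one <- function(X, ridge = 1e-10) {
  n <- nrow(X)
  dbar <- colMeans(X)
  S <- stats::cov(X)
  det_ok <- abs(det(S)) > .Machine$double.eps * max(1, sum(S^2))
  if (!det_ok) S <- S + diag(ridge, ncol(S))
  T2 <- n * drop(t(dbar) %*% solve(S, dbar))
  T2
}

#' Multivariate topology-change map (Hotelling T2)
#'
#' Per region, the site-wise paired differences of nodal clustering and
#' path length (patient minus control) are tested jointly:
#' `T2 = n * dbar' S^-1 dbar` with `S` the sample covariance of the
#' differences, converted to `F = ((n - 2) / (2(n - 1))) T2` on
#' `(2, n - 2)` degrees of freedom, with Benjamini-Hochberg correction
#' across regions. The scalar summary used for spatial correlation is T2
#' signed by the dominant direction of change: positive when the mean
#' difference projects onto `(1, 1)` (joint increase of clustering and
#' path length, i.e. regularization), negative for the joint decrease
#' (randomization). The unsigned variant is returned alongside.
#'
#' @param d_clust,d_path numeric matrices, sites x regions, of paired
#'   patient-minus-control differences in nodal clustering and nodal path
#'   length.
#' @param ridge diagonal ridge added when the difference covariance is
#'   singular (logged via a flag column).
#' @return data.frame per region: `T2`, `F`, `p`, `p_fdr`, `signed_T2`,
#'   `ridged`.
#' @export
hotelling_map <- function(d_clust, d_path, ridge = 1e-10) {
  if (!all(dim(d_clust) == dim(d_path)))
    stop("difference matrices must have identical dimensions")
  n <- nrow(d_clust)
  if (n < 4) stop("need at least 4 sites for a bivariate Hotelling test")
  p_var <- 2
  out <- lapply(seq_len(ncol(d_clust)), function(r) {
    X <- cbind(d_clust[, r], d_path[, r])
    X <- X[stats::complete.cases(X), , drop = FALSE]
    m <- nrow(X)
    if (m < 4) return(c(T2 = NA, F = NA, p = NA, signed = NA, ridged = NA))
    S <- stats::cov(X)
    ridged <- abs(det(S)) <= .Machine$double.eps * max(1, sum(S^2))
    T2 <- .hotelling_one(X, ridge)
    Fst <- (m - p_var) / (p_var * (m - 1)) * T2
    p <- stats::pf(Fst, p_var, m - p_var, lower.tail = FALSE)
    dbar <- colMeans(X)
    sgn <- sign(sum(dbar))
    if (sgn == 0) sgn <- 1
    c(T2 = T2, F = Fst, p = p, signed = sgn * T2, ridged = as.numeric(ridged))
  })
  out <- as.data.frame(do.call(rbind, out))
  names(out) <- c("T2", "F", "p", "signed_T2", "ridged")
  out$ridged <- out$ridged == 1
  out$p_fdr <- stats::p.adjust(out$p, "BH")
  out[, c("T2", "F", "p", "p_fdr", "signed_T2", "ridged")]
}

#' Full regional topology-change map
#'
#' Combines per-region Cohen's d for clustering, path length and their
#' ratio with the multivariate Hotelling map, using site-level nodal
#' metric matrices for each group.
#'
#' @param pat_C,ctl_C,pat_L,ctl_L sites x regions matrices of nodal
#'   clustering / path length for patients and controls (normalized or
#'   raw, as produced upstream).
#' @return data.frame with `d_clustering`, `d_path`, the [hotelling_map()]
#'   columns, and `region` index (1-based).
#' @export
topology_change_map <- function(pat_C, ctl_C, pat_L, ctl_L) {
  h <- hotelling_map(pat_C - ctl_C, pat_L - ctl_L)
  data.frame(region = seq_len(ncol(pat_C)),
             d_clustering = cohens_d_map(pat_C, ctl_C),
             d_path = cohens_d_map(pat_L, ctl_L),
             h)
}

#' Regional atrophy effect-size map
#'
#' Per region, two-sample Cohen's d and Welch t-test of subject-level
#' z-scores, patients versus controls, with Benjamini-Hochberg correction
#' across regions. Lower thickness/volume in patients gives negative d.
#'
#' @param cohort `covnet_cohort`.
#' @param patient_group diagnostic group compared against `"HC"`.
#' @return data.frame per region: `region`, `name`, `d`, `t`, `p`, `p_fdr`.
#' @export
atrophy_map <- function(cohort, patient_group = "TLE") {
  stopifnot(inherits(cohort, "covnet_cohort"))
  pat <- cohort$values[cohort$meta$group == patient_group, , drop = FALSE]
  ctl <- cohort$values[cohort$meta$group == "HC", , drop = FALSE]
  if (nrow(pat) == 0 || nrow(ctl) == 0)
    stop("both the patient group and controls must be present")
  d <- cohens_d_subjects(pat, ctl)
  tp <- vapply(seq_len(ncol(pat)), function(r) {
    tt <- stats::t.test(pat[, r], ctl[, r])
    c(unname(tt$statistic), tt$p.value)
  }, numeric(2))
  data.frame(region = seq_len(ncol(pat)), name = cohort$regions,
             d = d, t = tp[1, ], p = tp[2, ],
             p_fdr = stats::p.adjust(tp[2, ], "BH"))
}

# subject-level two-sample Cohen's d per column
cohens_d_subjects <- function(pat, ctl) {
  n1 <- nrow(pat); n2 <- nrow(ctl)
  sp <- sqrt(((n1 - 1) * apply(pat, 2, stats::var) +
              (n2 - 1) * apply(ctl, 2, stats::var)) / (n1 + n2 - 2))
  d <- (colMeans(pat) - colMeans(ctl)) / sp
  d[sp == 0] <- NA
  unname(d)
}
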