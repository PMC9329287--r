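# Synthetic multisite data: cohorts drawn from block-structured
# covariance with planted group effects, spatially autocorrelated
# expression matrices with a planted gene set, and cell-type specificity
# matrices. These generators define the study conditions under which the
# pipeline is exercised and tested.

#' Simulation configuration
#'
#' Defaults describe a desk-scale multisite study: 14 sites, 40 patients
#' and 40 controls per site, the 82-region default parcellation, region
#' communities of about ten regions, control correlations of 0.4 within
#' and 0.1 between communities, and a regularization effect planted as a
#' +0.2 within-community correlation increment in the first community of
#' the patient group.
#'
#' @param n_sites number of sites.
#' @param n_per_group subjects per diagnostic group per site.
#' @param region_table parcellation (default [default_region_table()]).
#' @param module_sizes community sizes partitioning the regions.
#' @param r_within,r_between control correlation levels.
#' @param delta_plus correlation increment planted in the target community
#'   of patients (regularization); 0 disables the effect.
#' @param planted_module index of the community receiving the effect.
#' @param patient_group diagnostic label of the patient group
#'   (`"TLE"` or `"IGE"`).
#' @param age_slope,sex_effect linear covariate effects in raw units
#'   (mm / mm^3 per year, and the male-minus-female offset).
#' @param missing_rate proportion of values set missing at random.
#' @param site_prefix prefix for generated site labels (lets cohorts for
#'   different comparisons carry distinct site names).
#' @return list of class `covnet_simconfig`.
#' @export
sim_config <- function(n_sites = 14, n_per_group = 40,
                       region_table = default_region_table(),
                       module_sizes = c(10, rep(9, 8)),
                       r_within = 0.4, r_between = 0.1,
                       delta_plus = 0.2, planted_module = 1,
                       patient_group = "TLE",
                       age_slope = -0.02, sex_effect = 0.05,
                       missing_rate = 0.01, site_prefix = "site") {
  n_regions <- nrow(region_table)
  if (sum(module_sizes) != n_regions)
    stop("module sizes must sum to the number of regions (", n_regions, ")")
  structure(list(n_sites = n_sites, n_per_group = n_per_group,
                 region_table = region_table, module_sizes = module_sizes,
                 r_within = r_within, r_between = r_between,
                 delta_plus = delta_plus, planted_module = planted_module,
                 patient_group = patient_group, age_slope = age_slope,
                 sex_effect = sex_effect, missing_rate = missing_rate,
                 site_prefix = site_prefix),
            class = "covnet_simconfig")
}

#' Region indices of the planted community
#'
#' @param config `covnet_simconfig`.
#' @return integer vector (1-based region indices).
#' @export
planted_regions <- function(config) {
  ends <- cumsum(config$module_sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  seq(starts[config$planted_module], ends[config$planted_module])
}

# block correlation matrix; PSD enforced by nearest-PD projection if the
# planted perturbation ever pushes an eigenvalue below zero
.block_correlation <- function(sizes, r_within, r_between, bump = 0,
                               bump_module = 1) {
  n <- sum(sizes)
  module <- rep(seq_along(sizes), sizes)
  S <- matrix(r_between, n, n)
  for (m in seq_along(sizes)) {
    idx <- module == m
    S[idx, idx] <- r_within + if (m == bump_module) bump else 0
  }
  diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    S <- as.matrix(Matrix::nearPD(S, corr = TRUE)$mat)
    attr(S, "projected") <- TRUE
  }
  S
}

#' Simulate a multisite morphometry cohort
#'
#' Per site, control subjects are drawn from a multivariate normal with a
#' block-structured correlation matrix; patients from the same matrix
#' with the planted within-community correlation increment. Raw values are
#' built on realistic scales (cortical thickness around 2.5 mm, subcortical
#' volumes in the thousands of mm^3) with site-specific offsets and scales,
#' linear age and sex effects, and missing-at-random entries. TLE patients
#' are assigned alternating left/right seizure foci; controls (and IGE
#' patients) have none.
#'
#' @param config `covnet_simconfig` from [sim_config()].
#' @param seed integer seed; the output is fully deterministic given the
#'   seed.
#' @return subject data.frame in the format [impute_and_filter()] expects.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rt <- config$region_table
  n_regions <- nrow(rt)
  ctx <- rt$class == "cortical"
  base_mean <- ifelse(ctx, 2.5, 5000)
  base_sd <- ifelse(ctx, 0.15, 400)
  slope <- ifelse(ctx, config$age_slope, config$age_slope * 1500)
  sexeff <- ifelse(ctx, config$sex_effect, config$sex_effect * 2000)

  S_ctl <- .block_correlation(config$module_sizes, config$r_within,
                              config$r_between)
  S_pat <- .block_correlation(config$module_sizes, config$r_within,
                              config$r_between, bump = config$delta_plus,
                              bump_module = config$planted_module)
  out <- list()
  for (s in seq_len(config$n_sites)) {
    site <- sprintf("%s%02d", config$site_prefix, s)
    offset <- stats::rnorm(1, 0, 0.05)
    scale <- exp(stats::rnorm(1, 0, 0.05))
    for (grp in c("HC", config$patient_group)) {
      n <- config$n_per_group
      Sigma <- if (grp == "HC") S_ctl else S_pat
      latent <- MASS::mvrnorm(n, mu = rep(0, n_regions), Sigma = Sigma)
      age <- stats::runif(n, 18, 60)
      sex <- stats::rbinom(n, 1, 0.5)
      vals <- sweep(latent, 2, base_sd * scale, "*")
      vals <- sweep(vals, 2, base_mean * (1 + offset), "+")
      vals <- vals + outer(age - 40, slope) + outer(sex, sexeff)
      if (config$missing_rate > 0) {
        miss <- matrix(stats::runif(n * n_regions) < config$missing_rate,
                       n, n_regions)
        vals[miss] <- NA
      }
      focus <- if (grp == "TLE")
        rep(c("left", "right"), length.out = n) else rep("none", n)
      df <- data.frame(
        subject_id = sprintf("%s_%s_%03d", site, grp, seq_len(n)),
        site = site, group = grp, age = age,
        sex = ifelse(sex == 1, "male", "female"),
        focus_side = focus, stringsAsFactors = FALSE)
      vdf <- as.data.frame(vals)
      names(vdf) <- rt$name
      out[[length(out) + 1L]] <- cbind(df, vdf)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# great-circle distances between unit vectors
.sphere_geodesic <- function(sphere_xyz) {
  dots <- pmin(pmax(sphere_xyz %*% t(sphere_xyz), -1), 1)
  acos(dots)
}

#' Simulate a spatially autocorrelated expression matrix
#'
#' Background genes are Gaussian-process draws with a squared-exponential
#' kernel over great-circle distances on the sphere, emulating the smooth
#' regional expression gradients of bulk transcriptomic atlases. A planted
#' gene set is constructed as `rho * standardized(target_map) +
#' sqrt(1 - rho^2) * GP noise`, so each planted gene correlates `rho` with
#' the target map in expectation. Columns are min-max scaled to `[0, 1]`
#' (a per-gene affine map, so spatial correlations are unchanged).
#'
#' @param sphere_xyz n x 3 unit-sphere region coordinates.
#' @param n_genes size of the gene universe.
#' @param length_scale kernel length scale in radians (default 0.7).
#' @param target_map regional map the planted set tracks (`NULL` for no
#'   planted set).
#' @param rho target correlation of planted genes with `target_map`.
#' @param set_size number of planted genes.
#' @param seed integer seed.
#' @return list with `expr` (regions x genes, gene symbols `g0001`, ...)
#'   and `planted_set` (character vector, empty if nothing planted).
#' @export
simulate_expression <- function(sphere_xyz, n_genes = 500,
                                length_scale = 0.7, target_map = NULL,
                                rho = 0.5, set_size = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(target_map) && (rho <= 0 || rho > 1))
    stop("rho must lie in (0, 1]")
  n <- nrow(sphere_xyz)
  D <- .sphere_geodesic(sphere_xyz)
  K <- exp(-D^2 / (2 * length_scale^2))
  # eigen square root: smooth kernels are numerically rank-deficient
  ei <- eigen(K, symmetric = TRUE)
  Lc <- ei$vectors %*% diag(sqrt(pmax(ei$values, 1e-12)))
  gp_draw <- function() drop(Lc %*% stats::rnorm(n))
  expr <- matrix(NA_real_, n, n_genes)
  planted <- character(0)
  idx_planted <- integer(0)
  if (!is.null(target_map)) {
    idx_planted <- seq_len(set_size)
    tstd <- as.numeric(scale(target_map))
    for (j in idx_planted) {
      noise <- as.numeric(scale(gp_draw()))
      expr[, j] <- rho * tstd + sqrt(1 - rho^2) * noise
    }
  }
  for (j in setdiff(seq_len(n_genes), idx_planted)) expr[, j] <- gp_draw()
  rng <- apply(expr, 2, range)
  expr <- sweep(sweep(expr, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
  colnames(expr) <- sprintf("g%04d", seq_len(n_genes))
  if (length(idx_planted) > 0) planted <- colnames(expr)[idx_planted]
  list(expr = expr, planted_set = planted)
}

celltype_names <- c(
  "Astro1", "Astro2", "Astro3", "Astro4", "Endo", "ExN1", "ExN2a", "ExN2b",
  "ExN3e", "ExN4", "ExN5b", "ExN6a", "ExN6b", "ExN8", "InN1a", "InN1b",
  "InN1c", "InN3", "InN4a", "InN4b", "InN6a", "InN6b", "InN7", "InN8",
  "Microglia", "Oligo", "OPC1", "OPC2", "VSMC")

#' Simulate a gene-by-cell-type specificity matrix
#'
#' Nonnegative baseline specificity scores (gamma noise) for 29 cell-type
#' subtypes; genes of each planted set receive an additive boost on their
#' designated cell type.
#'
#' @param gene_names character vector naming the gene universe.
#' @param n_celltypes number of cell types (default 29).
#' @param planted named list: each element `list(genes = ..., celltype =
#'   <index>, boost = <additive shift>)`.
#' @param seed integer seed.
#' @return genes x cell-types matrix with gene row names.
#' @export
simulate_celltype_matrix <- function(gene_names, n_celltypes = 29,
                                     planted = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ng <- length(gene_names)
  spec <- matrix(stats::rgamma(ng * n_celltypes, shape = 2, rate = 4),
                 ng, n_celltypes)
  rownames(spec) <- gene_names
  colnames(spec) <- if (n_celltypes == length(celltype_names))
    celltype_names else sprintf("celltype%02d", seq_len(n_celltypes))
  for (pl in planted) {
    boost <- if (is.null(pl$boost)) 0.75 else pl$boost
    idx <- rownames(spec) %in% pl$genes
    spec[idx, pl$celltype] <- pmax(0, spec[idx, pl$celltype] + boost)
  }
  spec
}
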