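# Pipeline orchestration: preprocess -> covariance networks -> metrics ->
# group statistics -> transcriptomic association, with logged seeds and
# optional tidy CSV / JSON output.

#' Load a subject morphometry table from CSV
#'
#' @param path CSV with columns `subject_id`, `site`, `group`, `age`,
#'   `sex`, `focus_side`, then one column per region name.
#' @param region_table validated region table used to check the columns.
#' @return data.frame.
#' @export
load_subject_table <- function(path, region_table) {
  subjects <- utils::read.csv(path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  .check_subject_table(subjects, region_table)
  subjects
}

# sites having at least min_subjects in both groups
.eligible_sites <- function(cohort, patient_group, min_subjects) {
  tab <- table(cohort$meta$site, cohort$meta$group)
  ok <- rownames(tab)[tab[, patient_group] >= min_subjects &
                      tab[, "HC"] >= min_subjects]
  sort(ok)
}

# covariance networks for one comparison: list(sites, patient = list of
# covnet_covariance, control = ...)
.comparison_networks <- function(cohort, patient_group, min_subjects) {
  sites <- .eligible_sites(cohort, patient_group, min_subjects)
  if (length(sites) == 0)
    stop("no site has ", min_subjects, " subjects in both '", patient_group,
         "' and 'HC'")
  pat <- lapply(sites, function(s)
    build_covariance(cohort, s, patient_group, min_subjects))
  ctl <- lapply(sites, function(s)
    build_covariance(cohort, s, "HC", min_subjects))
  list(sites = sites, patient = pat, control = ctl)
}

# sites x regions matrices of nodal metrics at density K
.site_nodal_matrices <- function(cov_list, K, normalize = FALSE,
                                 n_nulls = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(cov_list, function(cv) {
    W <- threshold_network(cv, K)$W
    if (normalize) {
      tp <- normalized_topology(W, n_nulls = n_nulls)
      list(C = tp$C_norm, L = tp$L_norm)
    } else nodal_topology(W)
  })
  list(C = do.call(rbind, lapply(res, `[[`, "C")),
       L = do.call(rbind, lapply(res, `[[`, "L")))
}

# sites x densities matrices of null-normalized global metrics
.site_global_matrices <- function(cov_list, densities, n_nulls, seed) {
  set.seed(seed)
  out <- lapply(cov_list, function(cv) {
    vapply(densities, function(K) {
      tp <- normalized_topology(threshold_network(cv, K)$W,
                                n_nulls = n_nulls)
      c(C = tp$C_norm_global, L = tp$L_norm_global, sigma = tp$sigma)
    }, numeric(3))
  })
  list(C = do.call(rbind, lapply(out, function(m) m["C", ])),
       L = do.call(rbind, lapply(out, function(m) m["L", ])),
       sigma = do.call(rbind, lapply(out, function(m) m["sigma", ])))
}

#' Run the full structural covariance network pipeline
#'
#' Executes preprocessing (imputation, residualization, z-scoring,
#' ipsi/contra sorting), builds site- and group-wise covariance networks,
#' screens the density grid for connectedness, compares null-normalized
#' global metrics across densities, derives regional Cohen's d and
#' multivariate Hotelling T2 topology-change maps at the selected density,
#' computes atrophy maps, and -- when an expression matrix and gene sets
#' are supplied -- imaging-transcriptomic associations under spin and
#' random-gene nulls.
#'
#' @param subjects subject data.frame (or CSV path).
#' @param region_table validated region table (or CSV path).
#' @param expr optional regions x genes expression matrix.
#' @param gene_sets optional named list of gene-symbol vectors.
#' @param celltype_spec optional genes x cell-types specificity matrix.
#' @param patient_groups diagnostic groups compared to controls; default
#'   every non-HC group present.
#' @param grid density grid for the connectedness screen.
#' @param global_densities densities at which global metrics are tested;
#'   default every fifth density of the valid range (desk scale).
#' @param n_nulls null networks per metric normalization.
#' @param n_perm permutations for spin and random-gene tests.
#' @param min_subjects minimum site-group size.
#' @param normalize_nodal normalize nodal metrics against rewired nulls
#'   before the regional group comparison (slower; differences of raw
#'   metrics give nearly identical maps).
#' @param seed master seed; all stage seeds derive from it and are logged
#'   in the result.
#' @param out_dir optional directory for tidy CSV outputs and a JSON
#'   summary.
#' @return object of class `covnet_pipeline`: list with `cohort`,
#'   `networks`, `connectedness`, `K_select`, `global`, `regional`,
#'   `atrophy`, `associations`, `celltype`, `summary`, `seeds`.
#' @export
run_pipeline <- function(subjects, region_table, expr = NULL,
                         gene_sets = NULL, celltype_spec = NULL,
                         patient_groups = NULL, grid = density_grid(),
                         global_densities = NULL, n_nulls = 50,
                         n_perm = 1000, min_subjects = 10,
                         normalize_nodal = FALSE, seed = 1,
                         out_dir = NULL) {
  if (is.character(region_table)) region_table <- load_region_table(region_table)
  if (is.character(subjects)) subjects <- load_subject_table(subjects, region_table)
  seeds <- list(master = seed, nodal = seed + 101L, global = seed + 211L,
                spin = seed + 307L)

  filtered <- impute_and_filter(subjects, region_table)
  cohort <- residualize_and_zscore(filtered, region_table)
  cohort <- sort_ipsi_contra(cohort, region_table)

  if (is.null(patient_groups))
    patient_groups <- setdiff(unique(cohort$meta$group), "HC")
  networks <- lapply(patient_groups, function(g)
    .comparison_networks(cohort, g, min_subjects))
  names(networks) <- patient_groups
  all_cov <- unlist(lapply(networks, function(nw) c(nw$patient, nw$control)),
                    recursive = FALSE)
  n_matrices <- length(all_cov)

  conn <- connectedness_range(all_cov, grid)
  K_select <- attr(conn, "K_select")
  if (is.na(K_select))
    stop("no density in the grid satisfies the connectedness criterion")
  valid <- attr(conn, "valid_range")
  if (is.null(global_densities)) {
    gk <- grid[grid >= valid[1] & grid <= valid[2]]
    global_densities <- gk[seq(1, length(gk), by = 5)]
  }

  global <- list(); regional <- list(); atrophy <- list()
  associations <- list(); celltype <- list()
  for (g in patient_groups) {
    nw <- networks[[g]]
    if (length(nw$sites) >= 3) {
      gp <- .site_global_matrices(nw$patient, global_densities, n_nulls,
                                  seeds$global)
      gc <- .site_global_matrices(nw$control, global_densities, n_nulls,
                                  seeds$global + 1L)
      global[[g]] <- do.call(rbind, lapply(
        c("C", "L", "sigma"), function(m)
          global_density_tests(gp[[m]], gc[[m]], global_densities, m)))
    }
    np <- .site_nodal_matrices(nw$patient, K_select, normalize_nodal,
                               n_nulls, seeds$nodal)
    nc <- .site_nodal_matrices(nw$control, K_select, normalize_nodal,
                               n_nulls, seeds$nodal + 1L)
    regional[[g]] <- topology_change_map(np$C, nc$C, np$L, nc$L)
    regional[[g]]$name <- region_table$name
    atrophy[[g]] <- atrophy_map(cohort, g)
    if (!is.null(expr) && !is.null(gene_sets)) {
      sph <- as.matrix(region_table[, c("sx", "sy", "sz")])
      # regions whose metrics were undefined at this density (isolated
      # nodes) enter the spatial correlation as zero change
      tmap <- regional[[g]]$signed_T2
      tmap[is.na(tmap)] <- 0
      associations[[g]] <- lapply(gene_sets, function(gs)
        imaging_transcriptomic_assoc(tmap, expr, gs,
                                     sph, n_perm = n_perm,
                                     seed = seeds$spin))
      if (!is.null(celltype_spec))
        celltype[[g]] <- lapply(gene_sets, function(gs)
          celltype_specificity(gs, celltype_spec, n_perm = n_perm,
                               seed = seeds$spin + 1L))
    }
  }

  summary <- list(
    n_subjects = nrow(cohort$values),
    n_excluded = attr(filtered, "n_excluded"),
    n_regions = nrow(region_table),
    n_covariance_matrices = n_matrices,
    sites_per_comparison = vapply(networks, function(nw)
      length(nw$sites), integer(1)),
    valid_density_range = valid,
    K_select = K_select,
    associations = lapply(associations, function(as_g)
      lapply(as_g, function(a)
        list(r = a$r, p_spin = a$p_spin, p_rand = a$p_rand,
             n_genes_used = a$n_genes_used))))

  res <- structure(list(cohort = cohort, networks = networks,
                        connectedness = conn, K_select = K_select,
                        global = global, regional = regional,
                        atrophy = atrophy, associations = associations,
                        celltype = celltype, summary = summary,
                        seeds = seeds),
                   class = "covnet_pipeline")
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(res$regional)) {
    utils::write.csv(res$regional[[g]],
                     file.path(out_dir, paste0("regional_", g, ".csv")),
                     row.names = FALSE)
    utils::write.csv(res$atrophy[[g]],
                     file.path(out_dir, paste0("atrophy_", g, ".csv")),
                     row.names = FALSE)
    if (!is.null(res$global[[g]]))
      utils::write.csv(res$global[[g]],
                       file.path(out_dir, paste0("global_", g, ".csv")),
                       row.names = FALSE)
  }
  utils::write.csv(res$connectedness,
                   file.path(out_dir, "connectedness.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(res$summary, list(seeds = res$seeds)),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.covnet_pipeline <- function(x, ...) {
  s <- x$summary
  cat("covnet pipeline run\n",
      " subjects: ", s$n_subjects, " (", s$n_excluded, " excluded)\n",
      " covariance matrices: ", s$n_covariance_matrices, "\n",
      " valid density range: [", s$valid_density_range[1], ", ",
      s$valid_density_range[2], "], regional analyses at K = ",
      s$K_select, "\n", sep = "")
  for (g in names(x$associations))
    for (nm in names(x$associations[[g]])) {
      a <- x$associations[[g]][[nm]]
      cat(sprintf("  %s ~ %s: r = %.3f, p_spin = %.4f, p_rand = %.4f\n",
                  g, nm, a$r, a$p_spin, a$p_rand))
    }
  invisible(x)
}

#' Threshold-stability sweep of the multivariate topology map
#'
#' Recomputes the signed Hotelling T2 topology-change map at every density
#' of the grid and returns the pairwise Pearson correlations between the
#' density-specific maps, quantifying how stable the regional pattern is
#' to the thresholding choice.
#'
#' @param networks one comparison's networks, i.e. an element of the
#'   `networks` field of a [run_pipeline()] result, or any list with
#'   `patient` and `control` lists of `covnet_covariance`.
#' @param grid densities to sweep.
#' @return list with `maps` (regions x densities signed-T2 matrix) and
#'   `map_correlations` (densities x densities).
#' @export
stability_sweep <- function(networks, grid = density_grid()) {
  maps <- vapply(grid, function(K) {
    np <- .site_nodal_matrices(networks$patient, K)
    nc <- .site_nodal_matrices(networks$control, K)
    hotelling_map(np$C - nc$C, np$L - nc$L)$signed_T2
  }, numeric(nrow(networks$patient[[1]]$R)))
  colnames(maps) <- grid
  list(maps = maps,
       map_correlations = stats::cor(maps, use = "pairwise.complete.obs"))
}

#' Per-site nodal difference maps
#'
#' Site-wise patient-minus-control differences of nodal clustering and
#' path length at one density, for reproducibility checks across
#' independent sites.
#'
#' @inheritParams stability_sweep
#' @param K density.
#' @return list with matrices `dC` and `dL` (sites x regions) and `sites`.
#' @export
per_site_difference_maps <- function(networks, K) {
  np <- .site_nodal_matrices(networks$patient, K)
  nc <- .site_nodal_matrices(networks$control, K)
  list(dC = np$C - nc$C, dL = np$L - nc$L, sites = networks$sites)
}
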