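# Imaging-transcriptomic association: gene-set expression maps, spin and
# random-gene nulls, and cell-type specificity enrichment.

#' Gene-set expression map
#'
#' Per-region mean expression over the genes of a set that are present in
#' the expression matrix (missing entries excluded pairwise). Genes absent
#' from the matrix are dropped and counted.
#'
#' @param expr regions x genes numeric matrix with gene symbols as column
#'   names.
#' @param genes character vector of gene symbols.
#' @return numeric per-region vector; attributes `n_genes_used` and
#'   `dropped` (symbols not in the matrix).
#' @export
geneset_expression_map <- function(expr, genes) {
  genes <- unique(genes)
  present <- genes[genes %in% colnames(expr)]
  if (length(present) == 0)
    stop("no gene of the set is present in the expression matrix; missing: ",
         paste(genes, collapse = ", "))
  m <- rowMeans(expr[, present, drop = FALSE], na.rm = TRUE)
  structure(unname(m), n_genes_used = length(present),
            dropped = setdiff(genes, present))
}

#' Random-gene permutation null for a spatial correlation
#'
#' Null distribution of the correlation between a topology map and
#' expression maps of randomly drawn gene sets of the same size (drawn
#' without replacement within a draw, from the full gene universe of the
#' matrix). One-tailed add-one p-value
#' `p_rand = (1 + #{r_null >= r_emp}) / (1 + n_perm)`.
#'
#' @param topo_map per-region numeric vector.
#' @param expr regions x genes expression matrix.
#' @param set_size number of genes per random set.
#' @param n_perm number of random sets (study default 10000).
#' @param seed integer seed.
#' @return list with `r_emp` (`NA` unless supplied via `r_emp`), `r_null`,
#'   `p_rand`.
#' @param r_emp empirical correlation the null is compared against; if
#'   `NULL`, only the null distribution is returned with `p_rand = NA`.
#' @export
random_gene_null <- function(topo_map, expr, set_size, n_perm = 10000,
                             seed = NULL, r_emp = NULL) {
  ngene <- ncol(expr)
  if (set_size > ngene)
    stop("set_size (", set_size, ") exceeds the gene universe (", ngene, ")")
  if (!is.null(seed)) set.seed(seed)
  r_null <- vapply(seq_len(n_perm), function(b) {
    gs <- sample.int(ngene, set_size)
    stats::cor(topo_map, rowMeans(expr[, gs, drop = FALSE], na.rm = TRUE))
  }, numeric(1))
  p <- if (is.null(r_emp)) NA_real_ else
    (1 + sum(r_null >= r_emp)) / (1 + n_perm)
  list(r_emp = if (is.null(r_emp)) NA_real_ else r_emp,
       r_null = r_null, p_rand = p, n_perm = n_perm)
}

#' Imaging-transcriptomic spatial association
#'
#' Correlates a regional topology-change map with the expression map of a
#' gene set and assesses significance with two one-tailed non-parametric
#' tests: a spin permutation test (p_spin, preserving spatial
#' autocorrelation) and a random-gene permutation test (p_rand,
#' controlling for gene-set size).
#'
#' @param topo_map per-region numeric vector (e.g. signed T2 map).
#' @param expr regions x genes expression matrix.
#' @param genes gene symbols of the tested set.
#' @param sphere_xyz n x 3 unit-sphere coordinates for the spin test.
#' @param n_perm permutations for both nulls.
#' @param seed integer seed (spin uses `seed`, gene null `seed + 1`).
#' @return object of class `covnet_assoc`: list with `r`, `p_spin`,
#'   `p_rand`, `n_genes_used`, `n_perm`.
#' @export
imaging_transcriptomic_assoc <- function(topo_map, expr, genes, sphere_xyz,
                                         n_perm = 10000, seed = NULL) {
  gmap <- geneset_expression_map(expr, genes)
  r <- stats::cor(topo_map, gmap)
  sp <- p_spin(topo_map, gmap, sphere_xyz, n_perm = n_perm, seed = seed)
  rg <- random_gene_null(topo_map, expr,
                         set_size = attr(gmap, "n_genes_used"),
                         n_perm = n_perm,
                         seed = if (is.null(seed)) NULL else seed + 1,
                         r_emp = r)
  structure(list(r = r, p_spin = sp$p_spin, p_rand = rg$p_rand,
                 n_genes_used = attr(gmap, "n_genes_used"),
                 dropped = attr(gmap, "dropped"), n_perm = n_perm,
                 seed = seed),
            class = "covnet_assoc")
}

#' @export
print.covnet_assoc <- function(x, ...) {
  cat(sprintf("imaging-transcriptomic association: r = %.3f, p_spin = %.4f, p_rand = %.4f (%d genes, %d permutations)\n",
              x$r, x$p_spin, x$p_rand, x$n_genes_used, x$n_perm))
  invisible(x)
}

# mean specificity of a gene set per cell type; all-zero rows discarded
.mean_specificity <- function(spec, genes) {
  sub <- spec[rownames(spec) %in% genes, , drop = FALSE]
  colMeans(sub)
}

#' Cell-type specificity of a gene set
#'
#' Per cell type, the mean specificity score of the set's genes is
#' compared to a null distribution of equally sized random gene sets.
#' Two-tailed add-one p-value
#' `p = 2 * min(P(null >= emp), P(null <= emp))`, capped at 1. Empirical
#' or null gene lists whose mean score equals zero are discarded from the
#' comparison and counted.
#'
#' @param genes gene symbols of the tested set.
#' @param spec genes x cell-types specificity matrix (nonnegative), gene
#'   symbols as row names.
#' @param n_perm number of random sets.
#' @param seed integer seed.
#' @return data.frame per cell type: `celltype`, `mean_specificity`,
#'   `p_rand`, `n_null_discarded`, `empirical_discarded`.
#' @export
celltype_specificity <- function(genes, spec, n_perm = 10000, seed = NULL) {
  genes <- unique(genes)
  present <- genes[genes %in% rownames(spec)]
  if (length(present) == 0) stop("no gene of the set is in the matrix")
  if (!is.null(seed)) set.seed(seed)
  emp <- .mean_specificity(spec, present)
  k <- length(present)
  nulls <- matrix(NA_real_, n_perm, ncol(spec))
  for (b in seq_len(n_perm)) {
    gs <- sample(rownames(spec), k)
    nulls[b, ] <- .mean_specificity(spec, gs)
  }
  res <- lapply(seq_len(ncol(spec)), function(ct) {
    nv <- nulls[, ct]
    discard <- nv == 0
    nv <- nv[!discard]
    if (emp[ct] == 0)
      return(data.frame(celltype = colnames(spec)[ct],
                        mean_specificity = 0, p_rand = NA_real_,
                        n_null_discarded = sum(discard),
                        empirical_discarded = TRUE))
    hi <- (1 + sum(nv >= emp[ct])) / (1 + length(nv))
    lo <- (1 + sum(nv <= emp[ct])) / (1 + length(nv))
    data.frame(celltype = colnames(spec)[ct], mean_specificity = emp[ct],
               p_rand = min(1, 2 * min(hi, lo)),
               n_null_discarded = sum(discard), empirical_discarded = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cell-type specificity difference between two gene sets
#'
#' Per cell type, the difference in mean specificity
#' `delta = mean(A) - mean(B)` is compared against two null difference
#' distributions: `A - random(|B|)` and `random(|A|) - B`. A two-tailed
#' p-value is reported against each, plus their maximum as a conservative
#' combination.
#'
#' @param genes_a,genes_b the two gene sets.
#' @inheritParams celltype_specificity
#' @return data.frame per cell type: `celltype`, `delta`, `p_vs_randB`,
#'   `p_vs_randA`, `p_combined`.
#' @export
celltype_difference <- function(genes_a, genes_b, spec, n_perm = 10000,
                                seed = NULL) {
  pa <- unique(genes_a)[unique(genes_a) %in% rownames(spec)]
  pb <- unique(genes_b)[unique(genes_b) %in% rownames(spec)]
  if (length(pa) == 0 || length(pb) == 0)
    stop("both gene sets must overlap the specificity matrix")
  if (!is.null(seed)) set.seed(seed)
  ma <- .mean_specificity(spec, pa)
  mb <- .mean_specificity(spec, pb)
  delta <- ma - mb
  null1 <- matrix(NA_real_, n_perm, ncol(spec)) # A - random(|B|)
  null2 <- matrix(NA_real_, n_perm, ncol(spec)) # random(|A|) - B
  for (b in seq_len(n_perm)) {
    null1[b, ] <- ma - .mean_specificity(spec, sample(rownames(spec), length(pb)))
    null2[b, ] <- .mean_specificity(spec, sample(rownames(spec), length(pa))) - mb
  }
  two_tailed <- function(nv, d) {
    hi <- (1 + sum(nv >= d)) / (1 + length(nv))
    lo <- (1 + sum(nv <= d)) / (1 + length(nv))
    min(1, 2 * min(hi, lo))
  }
  p1 <- vapply(seq_len(ncol(spec)),
               function(ct) two_tailed(null1[, ct], delta[ct]), numeric(1))
  p2 <- vapply(seq_len(ncol(spec)),
               function(ct) two_tailed(null2[, ct], delta[ct]), numeric(1))
  data.frame(celltype = colnames(spec), delta = unname(delta),
             p_vs_randB = p1, p_vs_randA = p2,
             p_combined = pmax(p1, p2))
}

#' Read a newline-delimited gene-set file
#'
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with `#` ignored.
#' @return character vector of unique symbols.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0) stop("empty gene set: ", path)
  unique(x)
}
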