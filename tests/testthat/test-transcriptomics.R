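make_expr <- function(n_regions = 20, n_genes = 30, seed = 50) {
  set.seed(seed)
  expr <- matrix(runif(n_regions * n_genes), n_regions, n_genes)
  colnames(expr) <- sprintf("g%03d", seq_len(n_genes))
  expr
}

test_that("gene-set expression maps are per-region means over available genes", {
  expr <- make_expr()
  one <- geneset_expression_map(expr, "g005")
  expect_equal(one, unname(expr[, "g005"]), ignore_attr = TRUE)
  two <- geneset_expression_map(expr, c("g001", "g002"))
  expect_equal(as.numeric(two), unname((expr[, "g001"] + expr[, "g002"]) / 2))
  full <- geneset_expression_map(expr, colnames(expr))
  expect_equal(as.numeric(full), unname(rowMeans(expr)))
  expect_error(geneset_expression_map(expr, c("nope1", "nope2")), "nope1")
})

test_that("absent genes are dropped without changing the remaining map", {
  expr <- make_expr()
  with_absent <- geneset_expression_map(expr, c("g001", "g002", "missing"))
  present_only <- geneset_expression_map(expr, c("g001", "g002"))
  expect_equal(as.numeric(with_absent), as.numeric(present_only))
  expect_equal(attr(with_absent, "dropped"), "missing")
  expect_equal(attr(with_absent, "n_genes_used"), 2)
})

test_that("gene-set maps are permutation-equivariant in the region rows", {
  expr <- make_expr()
  perm <- sample(nrow(expr))
  m1 <- geneset_expression_map(expr, c("g003", "g007", "g010"))
  m2 <- geneset_expression_map(expr[perm, ], c("g003", "g007", "g010"))
  expect_equal(as.numeric(m2), as.numeric(m1)[perm])
})

test_that("random-gene null: degenerate cases and determinism", {
  expr <- make_expr()
  topo <- rnorm(nrow(expr))
  r_full <- cor(topo, rowMeans(expr))
  out <- random_gene_null(topo, expr, set_size = ncol(expr), n_perm = 50,
                          seed = 51, r_emp = r_full)
  expect_equal(out$p_rand, 1) # every null set is the whole universe
  expect_error(random_gene_null(topo, expr, set_size = ncol(expr) + 1,
                                n_perm = 5), "exceeds")
  a <- random_gene_null(topo, expr, 5, n_perm = 40, seed = 52, r_emp = 0.2)
  b <- random_gene_null(topo, expr, 5, n_perm = 40, seed = 52, r_emp = 0.2)
  expect_identical(a$r_null, b$r_null)
  # size-1 sets draw single-gene maps
  single <- random_gene_null(topo, expr, 1, n_perm = 200, seed = 53)
  per_gene <- as.numeric(cor(topo, expr))
  expect_true(all(vapply(single$r_null, function(r)
    min(abs(r - per_gene)) < 1e-12, logical(1))))
})

test_that("imaging-transcriptomic association flags a planted signal", {
  rt <- default_region_table()
  sph <- as.matrix(rt[, c("sx", "sy", "sz")])
  set.seed(54)
  target <- smooth_map(sph)
  sim <- simulate_expression(sph, n_genes = 150, target_map = target,
                             rho = 0.6, set_size = 15, seed = 55)
  a <- imaging_transcriptomic_assoc(target, sim$expr, sim$planted_set, sph,
                                    n_perm = 300, seed = 56)
  expect_gt(a$r, 0.3)
  expect_lt(a$p_spin, 0.05)
  expect_lt(a$p_rand, 0.05)
  expect_equal(a$n_genes_used, 15)
})

test_that("cell-type specificity: full universe, discards, planted enrichment", {
  set.seed(57)
  genes <- sprintf("g%03d", 1:120)
  spec <- simulate_celltype_matrix(genes, n_celltypes = 29,
                                   planted = list(list(genes = genes[1:12],
                                                       celltype = 4)),
                                   seed = 58)
  expect_equal(colnames(spec)[25], "Microglia")
  full <- celltype_specificity(genes, spec, n_perm = 30, seed = 59)
  expect_true(all(full$p_rand == 1))

  planted <- celltype_specificity(genes[1:12], spec, n_perm = 400, seed = 60)
  expect_equal(which.min(planted$p_rand), 4)
  expect_gt(planted$mean_specificity[4], mean(spec[, 4]))

  # an all-zero cell-type column is discarded and counted
  spec0 <- spec; spec0[, 2] <- 0
  z <- celltype_specificity(genes[1:12], spec0, n_perm = 30, seed = 61)
  expect_true(z$empirical_discarded[2])
  expect_true(is.na(z$p_rand[2]))
  expect_equal(z$n_null_discarded[2], 30)
})

test_that("cell-type differences: identical sets give zero, planted sets diverge", {
  genes <- sprintf("g%03d", 1:150)
  # set A over-, set B under-expresses cell type 1; the reverse at type 2,
  # so both sets deviate from random genes at both planted types
  spec <- simulate_celltype_matrix(
    genes, planted = list(list(genes = genes[1:15], celltype = 1),
                          list(genes = genes[16:30], celltype = 1,
                               boost = -0.45),
                          list(genes = genes[16:30], celltype = 2),
                          list(genes = genes[1:15], celltype = 2,
                               boost = -0.45)),
    seed = 62)
  same <- celltype_difference(genes[1:15], genes[1:15], spec, n_perm = 20,
                              seed = 63)
  expect_equal(same$delta, rep(0, 29))

  div <- celltype_difference(genes[1:15], genes[16:30], spec, n_perm = 400,
                             seed = 64)
  top2 <- order(div$p_combined)[1:2]
  expect_setequal(top2, c(1, 2))
  expect_gt(div$delta[1], 0)
  expect_lt(div$delta[2], 0)
})

test_that("gene-set files are read as unique trimmed symbols", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "GRIK1 ", "", "SCN1A", "GRIK1"), f)
  expect_equal(read_gene_set(f), c("GRIK1", "SCN1A"))
})
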