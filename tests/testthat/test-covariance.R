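test_that("covariance entries are Pearson correlations of regional z-scores", {
  rt <- toy_region_table()
  set.seed(5)
  subj <- data.frame(subject_id = sprintf("s%02d", 1:24), site = "s1",
                     group = rep(c("HC", "TLE"), each = 12),
                     age = runif(24, 20, 60),
                     sex = rep(c("male", "female"), 12),
                     focus_side = rep(c("none", "left"), each = 12),
                     L_a = rnorm(24), R_a = rnorm(24), L_b = rnorm(24),
                     R_b = rnorm(24))
  co <- residualize_and_zscore(subj, rt)
  cv <- build_covariance(co, "s1", "TLE")
  idx <- co$meta$group == "TLE"
  expect_equal(cv$R[1, 2], cor(co$values[idx, 1], co$values[idx, 2]))
  expect_true(isSymmetric(cv$R))
  expect_equal(diag(cv$R), rep(0, 4), ignore_attr = TRUE)
  expect_equal(cv$n_subjects, 12)
})

test_that("site-groups under the minimum sample size raise a skip condition", {
  rt <- toy_region_table()
  set.seed(6)
  subj <- data.frame(subject_id = sprintf("s%02d", 1:19), site = "s1",
                     group = c(rep("HC", 10), rep("TLE", 9)),
                     age = runif(19, 20, 60),
                     sex = sample(c("male", "female"), 19, TRUE),
                     focus_side = c(rep("none", 10), rep("left", 9)),
                     L_a = rnorm(19), R_a = rnorm(19), L_b = rnorm(19),
                     R_b = rnorm(19))
  co <- residualize_and_zscore(subj, rt)
  expect_error(build_covariance(co, "s1", "TLE"), class = "covnet_skip")
  expect_s3_class(build_covariance(co, "s1", "HC"), "covnet_covariance")
})

test_that("perfectly dependent value vectors give correlations of +/- 1", {
  # identical regions correlate 1; exact anti-correlation gives -1
  co <- structure(list(
    values = cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1)),
    meta = data.frame(site = "s1", group = "HC",
                      subject_id = c("x", "y", "z"), age = 1, sex = "male",
                      focus_side = "none"),
    regions = c("a", "b", "c")), class = "covnet_cohort")
  cv <- build_covariance(co, "s1", "HC", min_subjects = 3)
  expect_equal(cv$R["a", "b"], 1)
  expect_equal(cv$R["a", "c"], -1)
})

test_that("thresholding keeps exactly round(K n(n-1)/2) strongest positive edges", {
  set.seed(8)
  R <- matrix(0, 4, 4)
  R[upper.tri(R)] <- c(0.9, 0.8, 0.7, 0.3, 0.2, -0.5)
  R <- R + t(R)
  tn <- threshold_network(R, 0.5)
  expect_equal(tn$edge_target, 3)
  expect_equal(tn$n_edges, 3)
  expect_equal(sort(tn$W[upper.tri(tn$W)][tn$W[upper.tri(tn$W)] > 0]),
               c(0.7, 0.8, 0.9))
  expect_false(tn$insufficient)

  all_neg <- -abs(R); diag(all_neg) <- 0
  tn2 <- threshold_network(all_neg, 0.2)
  expect_equal(tn2$n_edges, 0)
  expect_true(tn2$insufficient)

  all_pos <- abs(R); diag(all_pos) <- 0
  tn3 <- threshold_network(all_pos, 0.5)
  expect_equal(tn3$n_edges, 3) # half of the 6 possible edges
})

test_that("retained edge sets are nested across increasing densities", {
  set.seed(9)
  for (rep in 1:20) {
    R <- random_weighted_graph(12, p_edge = 1)
    R[upper.tri(R)][sample(66, 20)] <- -runif(20)
    R <- matrix(0, 12, 12) + R * upper.tri(R)
    R <- R + t(R)
    prev <- NULL
    for (K in c(0.1, 0.2, 0.35, 0.5)) {
      edges <- which(threshold_network(R, K)$W > 0)
      if (!is.null(prev)) expect_true(all(prev %in% edges))
      prev <- edges
    }
  }
})

test_that("connectedness criterion counts largest-component membership per site", {
  # star on 82 nodes: all nodes in one component -> passes with one site
  n <- 82
  star <- matrix(0, n, n)
  star[1, 2:n] <- star[2:n, 1] <- 0.5
  expect_true(density_connected(list(as_thresholded(star))))

  # 10 sites, 2 with half the nodes isolated: 8/10 = 80% < 90% -> fails
  half_isolated <- matrix(0, n, n)
  half_isolated[1:41, 1:41][upper.tri(matrix(0, 41, 41))] <- 0.5
  half_isolated <- half_isolated + t(half_isolated)
  nets <- c(replicate(8, as_thresholded(star), simplify = FALSE),
            replicate(2, as_thresholded(half_isolated), simplify = FALSE))
  expect_false(density_connected(nets))
  # with both criteria relaxed just below the failing fractions it passes
  expect_true(density_connected(nets, site_frac = 0.80))
})

test_that("the valid density range is the longest contiguous passing run", {
  set.seed(10)
  subj <- small_cohort_df(n_sites = 3, n_per_group = 20, seed = 21)
  rt <- default_region_table()
  co <- residualize_and_zscore(impute_and_filter(subj, rt), rt)
  cvs <- c(lapply(unique(co$meta$site), build_covariance, cohort = co,
                  group = "HC"),
           lapply(unique(co$meta$site), build_covariance, cohort = co,
                  group = "TLE"))
  grid <- density_grid()[c(1, 10, 20, 30, 46)]
  out <- connectedness_range(cvs, grid)
  expect_equal(out$K, grid)
  vr <- attr(out, "valid_range")
  expect_true(is.null(vr) || attr(out, "K_select") == vr[1])
  if (!is.null(vr)) expect_true(all(out$pass[out$K >= vr[1] & out$K <= vr[2]]))
})

test_that("mean positive strength matches a brute-force recomputation", {
  w <- c(0.5, 0.3)
  W <- matrix(0, 3, 3); W[1, 2] <- w[1]; W[1, 3] <- w[2]
  W <- W + t(W)
  expect_equal(mean_positive_strength(as_thresholded(W)), 0.4)

  set.seed(12)
  R <- random_weighted_graph(10, p_edge = 1)
  tn <- threshold_network(R, 0.2)
  manual <- mean(tn$W[upper.tri(tn$W)][tn$W[upper.tri(tn$W)] > 0])
  expect_equal(mean_positive_strength(tn), manual)

  empty <- as_thresholded(matrix(0, 3, 3))
  expect_true(is.na(mean_positive_strength(empty)))
  expect_true(attr(mean_positive_strength(empty), "empty"))
})
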