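test_that("rotation matrices are proper rotations, deterministic under seed", {
  expect_equal(rotation_matrix(c(0, 0, 0)), diag(3))
  r1 <- random_rotation(seed = 4)
  r2 <- random_rotation(seed = 4)
  expect_identical(r1$angles, r2$angles)
  expect_lt(max(abs(r1$R %*% t(r1$R) - diag(3))), 1e-9)
  expect_lt(abs(det(r1$R) - 1), 1e-9)
  expect_true(all(r1$angles >= 0 & r1$angles < 2 * pi))
})

test_that("spin assignment is nearest-neighbour matching on the sphere", {
  rt <- default_region_table()
  sph <- as.matrix(rt[, c("sx", "sy", "sz")])
  expect_equal(spin_assignment(sph, diag(3)), seq_len(82))

  # two antipodal regions on the x axis: rotating pi about z swaps them
  two <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(spin_assignment(two, rotation_matrix(c(0, 0, pi))), c(2L, 1L))

  # random rotations move the parcellation almost surely
  set.seed(40)
  moved <- replicate(200, {
    p <- spin_assignment(sph, random_rotation()$R)
    !identical(p, seq_len(82))
  })
  expect_gt(mean(moved), 0.99)
})

test_that("p_spin is extreme for identical maps and near 1 for sign-flipped maps", {
  rt <- default_region_table()
  sph <- as.matrix(rt[, c("sx", "sy", "sz")])
  x <- smooth_map(sph, seed = 41)
  same <- p_spin(x, x, sph, n_perm = 99, seed = 42)
  expect_equal(same$r, 1)
  expect_lte(same$p_spin, (1 + sum(same$r_null >= 1 - 1e-12)) / 100)
  flip <- p_spin(x, -x, sph, n_perm = 99, seed = 43)
  expect_gt(flip$p_spin, 0.9)
  expect_error(p_spin(rep(1, 82), x, sph, n_perm = 9), "constant")
})

test_that("distance matrix mixes geodesic and Euclidean rules by region class", {
  rt <- default_region_table()
  D <- region_distance_matrix(rt, sphere_radius = 100)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 82))
  ctx <- which(rt$class == "cortical")
  sub <- which(rt$class == "subcortical")
  i <- ctx[1]; j <- ctx[5]
  s <- as.matrix(rt[, c("sx", "sy", "sz")])
  expect_equal(D[i, j], 100 * acos(sum(s[i, ] * s[j, ])))
  k <- sub[1]
  expect_equal(D[i, k],
               sqrt(sum((rt[i, c("x", "y", "z")] - rt[k, c("x", "y", "z")])^2)))
})

test_that("variogram surrogates with k = 0 reduce to plain shuffles", {
  rt <- default_region_table()
  D <- region_distance_matrix(rt)
  x <- smooth_map(as.matrix(rt[, c("sx", "sy", "sz")]), seed = 44)
  s1 <- variogram_surrogates(x, D, n_surr = 3, seed = 45, knn = 0)
  set.seed(45)
  manual <- replicate(3, sample(x))
  expect_equal(unname(s1), manual, ignore_attr = TRUE)
})

test_that("surrogates approximate the empirical variogram of a smooth map", {
  rt <- default_region_table()
  sph <- as.matrix(rt[, c("sx", "sy", "sz")])
  D <- region_distance_matrix(rt)
  x <- smooth_map(sph, seed = 46)
  surr <- variogram_surrogates(x, D, n_surr = 30, seed = 47)
  # smoothing+rescaling must beat plain permutation at variogram matching
  plain <- variogram_surrogates(x, D, n_surr = 30, seed = 47, knn = 0)
  expect_lt(mean(attr(surr, "variogram_sse")),
            mean(attr(plain, "variogram_sse")))
  expect_equal(dim(surr), c(82, 30))
})

test_that("spin and variogram nulls give concordant p-values on map pairs", {
  rt <- default_region_table()
  sph <- as.matrix(rt[, c("sx", "sy", "sz")])
  D <- region_distance_matrix(rt)
  set.seed(48)
  ps <- pv <- numeric(15)
  for (i in seq_len(15)) {
    x <- smooth_map(sph)
    y <- 0.4 * runif(1) * x + smooth_map(sph) # varying overlap
    ps[i] <- p_spin(x, y, sph, n_perm = 200)$p_spin
    pv[i] <- p_variogram(x, y, D, n_surr = 200)$p_vgm
  }
  expect_gt(cor(ps, pv, method = "spearman"), 0.7)
})
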