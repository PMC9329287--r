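test_that("subjects missing half a compartment are excluded, the rest imputed", {
  rt <- default_region_table()
  subj <- small_cohort_df(n_sites = 1, n_per_group = 12, seed = 7,
                          missing_rate = 0)
  ctx <- rt$name[rt$class == "cortical"]
  # subject 1: 34 of 68 cortical values missing -> excluded
  subj[1, ctx[1:34]] <- NA
  # subject 2: one missing value, imputed with the site-group region mean
  rg <- ctx[40]
  subj[2, rg] <- NA
  # the mean is taken over the retained, observed subjects of the site-group
  donor <- subj$group == subj$group[2] & subj$site == subj$site[2] &
    !(seq_len(nrow(subj)) %in% c(1, 2))
  expected <- mean(subj[[rg]][donor])
  out <- impute_and_filter(subj, rt)
  expect_equal(nrow(out), nrow(subj) - 1)
  expect_equal(attr(out, "n_excluded"), 1)
  expect_equal(out[[rg]][out$subject_id == subj$subject_id[2]], expected)
  # untouched subjects pass through unchanged
  expect_equal(unlist(out[out$subject_id == subj$subject_id[3], rt$name]),
               unlist(subj[3, rt$name]))
})

test_that("imputation mean is the arithmetic mean of the observed values", {
  rt <- default_region_table()
  subj <- small_cohort_df(n_sites = 1, n_per_group = 3, seed = 8,
                          missing_rate = 0)
  rg <- rt$name[1]
  hc <- which(subj$group == "HC")
  subj[hc, rg] <- c(NA, 2, 4)
  out <- impute_and_filter(subj, rt)
  expect_equal(out[[rg]][out$subject_id == subj$subject_id[hc[1]]], 3)
  # a region missing in every subject of a site-group is an error
  subj[hc, rg] <- NA_real_
  expect_error(impute_and_filter(subj, rt), "missing in every subject")
})

test_that("control z-scores have mean 0 and SD 1 per site and region", {
  rt <- default_region_table()
  subj <- small_cohort_df(n_sites = 3, n_per_group = 15, seed = 11)
  co <- residualize_and_zscore(impute_and_filter(subj, rt), rt)
  for (s in unique(co$meta$site)) {
    hc <- co$values[co$meta$site == s & co$meta$group == "HC", ]
    expect_lt(max(abs(colMeans(hc))), 1e-8)
    expect_lt(max(abs(apply(hc, 2, sd) - 1)), 1e-8)
  }
})

test_that("a planted linear age slope is recovered by the residualization fit", {
  rt <- default_region_table()
  slope <- 0.02
  subj <- small_cohort_df(n_sites = 1, n_per_group = 60, seed = 13,
                          age_slope = slope, missing_rate = 0)
  co <- residualize_and_zscore(subj, rt)
  beta <- co$coefficients[[1]]
  ctx <- rt$class == "cortical"
  est <- beta[2, ctx]
  se <- sd(est) / sqrt(sum(ctx))
  expect_lt(abs(mean(est) - slope), 3 * max(se, 1e-3))
})

test_that("degenerate designs and too-few controls are rejected", {
  rt <- toy_region_table()
  subj <- data.frame(subject_id = letters[1:6], site = "s1",
                     group = rep(c("HC", "TLE"), each = 3),
                     age = 40, sex = rep(c("male", "female"), 3),
                     focus_side = rep(c("none", "left"), each = 3),
                     L_a = rnorm(6), R_a = rnorm(6), L_b = rnorm(6),
                     R_b = rnorm(6))
  expect_error(residualize_and_zscore(subj, rt), "singular")
  one_hc <- subj[subj$group == "TLE" | subj$subject_id == "a", ]
  expect_error(residualize_and_zscore(one_hc, rt), "fewer than 2 controls")
})

test_that("ipsi/contra sorting permutes right-focus patients only, as an involution", {
  rt <- toy_region_table()
  set.seed(3)
  subj <- data.frame(subject_id = letters[1:8], site = "s1",
                     group = rep(c("HC", "TLE"), each = 4),
                     age = runif(8, 20, 60), sex = rep(c("male", "female"), 4),
                     focus_side = c(rep("none", 4), "left", "right", "left",
                                    "right"),
                     L_a = rnorm(8), R_a = rnorm(8), L_b = rnorm(8),
                     R_b = rnorm(8))
  co <- residualize_and_zscore(subj, rt)
  sorted <- sort_ipsi_contra(co, rt)
  right <- co$meta$focus_side == "right"
  expect_equal(unname(sorted$values[right, ]),
               unname(co$values[right, c(2, 1, 4, 3)]))
  expect_equal(sorted$values[!right, ], co$values[!right, ])
  # involution and multiset preservation
  twice <- sort_ipsi_contra(sorted, rt)
  expect_equal(twice$values, co$values)
  for (i in seq_len(nrow(co$values)))
    expect_equal(unname(sort(sorted$values[i, ])),
                 unname(sort(co$values[i, ])))
})
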