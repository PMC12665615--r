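# Voxelwise GLM, TFCE, permutation FWE, LOO consistency, scalar comparisons.

test_that("analysis_mask applies the FA threshold and region intersection", {
  d <- c(4, 4, 4)
  full <- analysis_mask(scalar_map(array(0.5, d)), 0.2, array(TRUE, d))
  expect_true(all(full))
  expect_error(analysis_mask(scalar_map(array(0.1, d)), 0.2), "empty")
  set.seed(1)
  fa <- scalar_map(array(runif(prod(d)), d))
  region <- array(rep(c(TRUE, FALSE), length.out = prod(d)), d)
  m <- analysis_mask(fa, 0.3, region)
  expect_equal(sum(m), sum(fa$values > 0.3 & region))
})

test_that("glm_tstat equals the classical two-sample t and partials covariates", {
  set.seed(2)
  n <- 24
  grp <- factor(rep(c("a", "b"), each = n / 2))
  Y <- matrix(rnorm(n * 30), n)
  msk <- array(TRUE, c(5, 3, 2))
  attr(Y, "mask") <- msk
  des <- make_design(grp)
  tmap <- glm_tstat(Y, des)
  tref <- apply(Y, 2, function(col)
    -unname(t.test(col ~ grp, var.equal = TRUE)$statistic))
  expect_lt(max(abs(tmap$values[msk] - tref)), 1e-10)

  # a covariate collinear with the group effect direction absorbs it
  cov <- as.numeric(grp == "b") + rnorm(n, 0, 1e-3)
  Y2 <- Y + outer(as.numeric(grp == "b"), rep(2, 30))
  attr(Y2, "mask") <- msk
  t_with <- glm_tstat(Y2, make_design(grp, data.frame(x = cov)))
  t_without <- glm_tstat(Y2, des)
  expect_lt(median(abs(t_with$values[msk])), median(abs(t_without$values[msk])) / 2)

  # constant data flagged with t = 0
  Yc <- matrix(1, n, 30)
  attr(Yc, "mask") <- msk
  tc <- glm_tstat(Yc, des)
  expect_true(all(tc$values == 0))
  expect_true(all(attr(tc, "zero_variance")))

  # demeaning invariant: covariate means are removed
  expect_lt(abs(mean(make_design(grp, data.frame(age = rnorm(n, 50)))$X[, "age"])),
            1e-10)
})

test_that("TFCE matches the single-voxel hand sum and the brute-force oracle", {
  d <- c(5, 5, 5)
  z <- array(0, d)
  expect_true(all(tfce_enhance(scalar_map(z), dh = 0.1)$values == 0))

  z[3, 3, 3] <- 2.0
  v <- tfce_enhance(scalar_map(z), E = 0.5, H = 2, dh = 0.1)$values[3, 3, 3]
  expect_equal(v, sum(1^0.5 * (0.1 * (1:20))^2 * 0.1), tolerance = 1e-12)
  expect_equal(v, 2.87, tolerance = 1e-12)

  skip_if_not_installed("igraph")
  for (s in 1:4) {
    set.seed(s)
    stat <- array(pmax(rnorm(512, 0.2, 1), 0), c(8, 8, 8))
    got <- tfce_enhance(scalar_map(stat))$values
    want <- brute_tfce(stat)
    expect_lt(max(abs(got - want)) / max(want), 1e-6)
  }

  # corner-touching voxels are one component under 26-connectivity
  z2 <- array(0, c(4, 4, 4))
  z2[1, 1, 1] <- 1; z2[2, 2, 2] <- 1
  v26 <- tfce_enhance(scalar_map(z2), E = 1, H = 0, dh = 1)$values[1, 1, 1]
  expect_equal(v26, 2)
  v6 <- tfce_enhance(scalar_map(z2), E = 1, H = 0, dh = 1, connectivity = 6)$values[1, 1, 1]
  expect_equal(v6, 1)

  # monotonicity: a pointwise-larger map never yields smaller TFCE
  set.seed(9)
  base <- array(pmax(rnorm(216, 0, 1), 0), c(6, 6, 6))
  bigger <- base + 0.3 * (base > 0)
  expect_true(all(tfce_enhance(scalar_map(bigger), dh = 0.05)$values + 1e-12 >=
                    tfce_enhance(scalar_map(base), dh = 0.05)$values))

  expect_error(tfce_enhance(scalar_map(z), dh = -1), "positive")
})

test_that("permutation_fwe is deterministic and detects a strong planted effect", {
  eff <- data.frame(group = "MSA", roi = "ROI_B", metric = "twist", size = -10)
  co <- make_cohort(quick_cohort_spec(effects = eff, seed = 21))
  Y <- cohort_metric_matrix(co, "twist")
  des <- make_design(co$subjects$group,
                     data.frame(age = co$subjects$age,
                                sex = as.numeric(co$subjects$sex)))
  r1 <- permutation_fwe(Y, des, n_perm = 150, seed = 7)
  r2 <- permutation_fwe(Y, des, n_perm = 150, seed = 7)
  expect_identical(r1$p_fwe_pos, r2$p_fwe_pos)
  expect_identical(r1$p_fwe_neg, r2$p_fwe_neg)

  roi_b <- co$roi_labels == 2
  expect_gt(sum(r1$sig_mask & roi_b) / sum(roi_b), 0.8)
  expect_equal(sum(r1$sig_mask & !roi_b), 0)
  # the effect is a decrease: only the negative direction fires
  expect_true(any(r1$p_fwe_neg[roi_b] <= 0.05))
  expect_false(any(r1$p_fwe_pos <= 0.05))
  expect_true(all(r1$p_fwe_pos > 0 & r1$p_fwe_pos <= 1))

  # exhaustive enumeration announces itself for tiny designs
  g <- factor(rep(c("a", "b"), c(4, 4)))
  Ys <- matrix(rnorm(8 * 27), 8)
  attr(Ys, "mask") <- array(TRUE, c(3, 3, 3))
  expect_warning(permutation_fwe(Ys, make_design(g), n_perm = 100, seed = 1),
                 "exhaustively")
})

test_that("loo_consistency runs once per small-group member and intersects", {
  eff <- data.frame(group = "MSA", roi = "ROI_B", metric = "twist", size = -10)
  co <- make_cohort(cohort_spec(n_per_group = c(HC = 10, MSA = 4),
                                metrics = "twist", effects = eff,
                                roi_labels = default_roi_labels(c(6, 6, 8)),
                                output = "volumes", seed = 3))
  Y <- cohort_metric_matrix(co, "twist")
  res <- loo_consistency(Y, co$subjects$group, n_perm = 100, seed = 5)
  expect_equal(nrow(res$reports), 4)
  expect_identical(res$intersection, Reduce(`&`, res$masks))

  # intersection is a subset of the all-subjects significance mask
  full <- permutation_fwe(Y, make_design(co$subjects$group), n_perm = 100, seed = 5)
  expect_true(all(!res$intersection | full$sig_mask))

  # a repeat with no significant voxels forces an empty intersection
  masks <- res$masks
  masks[[2]] <- array(FALSE, dim(masks[[2]]))
  expect_false(any(Reduce(`&`, masks)))

  expect_error(loo_consistency(Y, co$subjects$group, small_level = "MSA",
                               n_perm = 100, seed = 1,
                               mask = NULL)[0], NA)
})

test_that("group_compare_scalars gates between t-test and Mann-Whitney", {
  set.seed(4)
  g <- factor(rep(c("hc", "pt"), each = 30))
  shifted <- c(rnorm(30), rnorm(30) + 5)
  r <- group_compare_scalars(shifted, g)
  expect_equal(r$test, "t-test")
  expect_lt(r$p_raw, 1e-6)

  heavy <- c(rnorm(30)^3, rnorm(30)^3 + 1)
  r2 <- group_compare_scalars(heavy, g)
  expect_equal(r2$test, "mann-whitney")

  # family-level FDR column respects the step-up rule
  df <- data.frame(a = shifted, b = rnorm(60), c = rnorm(60))
  fam <- group_compare_scalars(df, g)
  expect_equal(fam$p_fdr, brute_bh(fam$p_raw), tolerance = 1e-12)

  expect_error(group_compare_scalars(rep(1, 60), g), "constant")

  # null calibration: ~5% rejections for identical groups
  rej <- sapply(1:200, function(s) {
    set.seed(s)
    group_compare_scalars(rnorm(20), factor(rep(1:2, each = 10)))$p_raw < 0.05
  })
  expect_gte(sum(rej), 2)
  expect_lte(sum(rej), 21)
})
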