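# Analytic phantoms and the DWI signal simulator.

test_that("phantom directors match their closed forms", {
  u <- make_phantom(phantom_spec("uniform", shape = c(5, 5, 5)))
  expect_true(all(abs(u$directors[, , , 3] - 1) < 1e-12))
  expect_true(all(abs(u$directors[, , , 1:2]) < 1e-12))

  # helix n = (cos kz, sin kz, 0) with z = (slice - 1) * dz
  tw <- make_phantom(phantom_spec("twist", shape = c(4, 4, 40), rate = 0.1))
  expect_equal(tw$directors[2, 2, 1, ], c(1, 0, 0), tolerance = 1e-12)
  zq <- pi / (2 * 0.1)          # quarter turn at z = pi/(2k)
  tw2 <- make_phantom(phantom_spec("twist", shape = c(4, 4, 40), rate = 0.1,
                                   spacing = c(1, 1, zq / 10)))
  expect_lt(max(abs(tw2$directors[2, 2, 11, ] - c(0, 1, 0))), 1e-9)

  # radial phantom: director at (3, 4, 0) mm offset is (0.6, 0.8, 0)
  sp <- make_phantom(phantom_spec("splay", shape = c(21, 21, 5)))
  expect_equal(sp$directors[14, 15, 3, ], c(0.6, 0.8, 0), tolerance = 1e-12)
  # singularity core is masked out
  expect_false(sp$mask[11, 11, 3])
  expect_false(sp$mask[12, 11, 3])

  # unit norm everywhere in-mask
  for (ph in list(u, tw, sp)) {
    nrm <- sqrt(ph$directors[, , , 1]^2 + ph$directors[, , , 2]^2 +
                  ph$directors[, , , 3]^2)
    expect_lt(max(abs(nrm[ph$mask] - 1)), 1e-12)
  }
})

test_that("phantom spec validation rejects bad geometry", {
  expect_error(phantom_spec("splay", spacing = c(0, 1, 1)), "spacing")
  expect_error(phantom_spec("splay", shape = c(0, 4, 4)), "shape")
  expect_error(phantom_spec("twist", rate = Inf), "finite")
  expect_error(phantom_spec("uniform", eigenvalues = c(1e-3, 2e-3, 1e-4)),
               "descending")
})

test_that("directors_to_tensors builds constant-shape tensors", {
  ev <- c(1.7e-3, 2e-4, 2e-4)
  # axis-aligned director gives the diagonal tensor
  d <- array(0, c(2, 2, 2, 3)); d[, , , 1] <- 1
  ti <- directors_to_tensors(director_field(d), ev)
  expect_equal(ti$tensors[1, 1, 1, ], c(ev[1], 0, 0, ev[2], 0, ev[3]),
               tolerance = 1e-15)

  # eigendecomposition round trip for an oblique director
  d2 <- array(0, c(1, 1, 1, 3)); d2[1, 1, 1, ] <- c(0.6, 0.8, 0)
  t2 <- directors_to_tensors(director_field(d2), ev)
  eg <- eigen(matrix(t2$tensors[1, 1, 1, c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3),
              symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  expect_lt(min(sum((v1 - c(0.6, 0.8, 0))^2), sum((v1 + c(0.6, 0.8, 0))^2)), 1e-16)

  # FA and MD constant across any phantom
  ph <- make_phantom(phantom_spec("bend", shape = c(15, 15, 5)))
  sc <- tensor_scalars(directors_to_tensors(ph, ev))
  expect_lt(sd(sc$fa$values[ph$mask]), 1e-14)
  expect_lt(sd(sc$md$values[ph$mask]), 1e-18)

  # non-unit directors rejected
  d3 <- array(0.5, c(1, 1, 1, 3))
  expect_error(director_field(d3), "unit norm")
})

test_that("simulate_dwi obeys the forward model and Rician statistics", {
  grad <- gradient_scheme(n_dirs = 12, bval = 1000)
  iso <- array(0, c(2, 2, 2, 6))
  dcoef <- 7e-4
  iso[, , , 1] <- dcoef; iso[, , , 4] <- dcoef; iso[, , , 6] <- dcoef
  ti <- tensor_image(iso)
  dwi <- simulate_dwi(ti, grad$bvals, grad$bvecs, s0 = 100, snr = Inf)
  # b = 0 measurement returns s0 exactly
  expect_equal(dwi$signals[1, 1, 1, 1], 100, tolerance = 1e-12)
  # isotropic tensor: S = s0 exp(-b d) at every gradient
  expect_equal(as.numeric(dwi$signals[1, 1, 1, -1]),
               rep(100 * exp(-1000 * dcoef), 12), tolerance = 1e-10)

  # Rician second moment: E[S^2] = nu^2 + 2 sigma^2
  n <- 1e5
  one <- tensor_image(array(rep(c(dcoef, 0, 0, dcoef, 0, dcoef), each = n),
                            c(n, 1, 1, 6)))
  snr <- 5
  grad7 <- gradient_scheme(n_dirs = 6, bval = 1000)
  noisy <- simulate_dwi(one, grad7$bvals, grad7$bvecs,
                        s0 = 100, snr = snr, seed = 7)
  nu <- 100 * exp(-1000 * dcoef)
  sigma <- 100 / snr
  m2 <- mean(noisy$signals[, 1, 1, 2]^2)
  expect_lt(abs(m2 - (nu^2 + 2 * sigma^2)) / (nu^2 + 2 * sigma^2), 0.01)

  # determinism and gradient validation
  noisy2 <- simulate_dwi(one, grad7$bvals, grad7$bvecs,
                         s0 = 100, snr = snr, seed = 7)
  expect_identical(noisy$signals, noisy2$signals)
  expect_error(simulate_dwi(ti, c(0, -10, grad$bvals[-(1:2)]), grad$bvecs),
               "negative")
  bad <- grad$bvecs; bad[, 2] <- c(2, 0, 0)
  expect_error(simulate_dwi(ti, grad$bvals, bad), "unit")
})

test_that("cohort generation is deterministic and recovers planted effects", {
  eff <- data.frame(group = "MSA", roi = "ROI_B", metric = "twist", size = -1.5)
  spec <- cohort_spec(n_per_group = c(HC = 16, MSA = 16), metrics = "twist",
                      effects = eff, seed = 11)
  c1 <- make_cohort(spec)
  c2 <- make_cohort(spec)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$volumes, c2$volumes)

  # mean difference over seeds recovers -1.5 * noise_sd
  diffs <- sapply(1:100, function(s) {
    co <- make_cohort(cohort_spec(n_per_group = c(HC = 16, MSA = 16),
                                  metrics = "twist", effects = eff, seed = s))
    f <- co$features$ROI_B_twist
    mean(f[co$subjects$group == "MSA"]) - mean(f[co$subjects$group == "HC"])
  })
  expect_lt(abs(mean(diffs) - (-1.5 * 0.1)), 0.4 * 0.1)

  # null cohorts reject at ~5% with a plain t-test
  pvals <- sapply(1:200, function(s) {
    co <- make_cohort(cohort_spec(n_per_group = c(HC = 16, MSA = 16),
                                  metrics = "twist", seed = s))
    t.test(ROI_A_twist ~ group, data = cbind(co$features, group = co$subjects$group),
           var.equal = TRUE)$p.value
  })
  expect_gte(sum(pvals < 0.05), 2)   # binomial 95% band around 10/200
  expect_lte(sum(pvals < 0.05), 19)

  expect_error(cohort_spec(effects = data.frame(group = "MSA", roi = "ROI_Z",
                                                metric = "twist", size = 1)),
               "absent")
})

test_that("generated clinical scores approach their target correlation", {
  spec <- cohort_spec(n_per_group = c(HC = 500, MSA = 500), metrics = "bend",
                      clinical = data.frame(score = "sara", feature = "ROI_B_bend",
                                            r = 0.5),
                      fixel = data.frame(column = "FD_ROI_B", feature = "ROI_B_bend",
                                         r = -0.6),
                      seed = 3)
  co <- make_cohort(spec)
  expect_lt(abs(cor(co$clinical$sara, co$features$ROI_B_bend) - 0.5), 0.1)
  expect_lt(abs(cor(co$features$FD_ROI_B, co$features$ROI_B_bend) + 0.6), 0.1)
})

test_that("cohort volume output carries the same subject-level values", {
  eff <- data.frame(group = "MSA", roi = "ROI_B", metric = "twist", size = -2)
  co <- make_cohort(quick_cohort_spec(effects = eff, seed = 5))
  Y <- cohort_metric_matrix(co, "twist")
  roi <- co$roi_labels[co$mask]
  roi_means <- rowMeans(Y[, roi == 2])
  # region mean of the volume reproduces the table value up to voxel noise
  expect_lt(max(abs(roi_means - co$features$ROI_B_twist)),
            4 * 0.05 / sqrt(sum(roi == 2)) * 5)
  grp <- co$subjects$group
  expect_lt(mean(roi_means[grp == "MSA"]) - mean(roi_means[grp == "HC"]), -0.05)
})
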