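# Geometric distortion maps: closed-form recovery, invariances, convergence.

test_that("uniform fields have a zero Jacobian and zero indices", {
  u <- make_phantom(phantom_spec("uniform", shape = c(6, 6, 6),
                                 direction = c(1, 2, 2)))
  jac <- director_jacobian(u)
  expect_lt(max(abs(jac$J)), 1e-14)
  m <- dfa_maps(u)
  for (nm in c("splay", "bend", "twist", "distortion"))
    expect_lt(max(m[[nm]]$values), 1e-14)
})

test_that("the Jacobian is invariant under per-voxel sign flips", {
  ph <- make_phantom(phantom_spec("twist", shape = c(8, 8, 10), rate = 0.1))
  flipped <- flip_directors(ph, seed = 9)
  J1 <- director_jacobian(ph)$J
  J2 <- director_jacobian(flipped)$J
  expect_lt(max(abs(J1 - J2)), 1e-12)

  # derivative magnitude along z equals the twist rate in the interior
  nz <- sqrt(J1[, , , 1, 3]^2 + J1[, , , 2, 3]^2 + J1[, , , 3, 3]^2)
  expect_lt(max(abs(nz[3:6, 3:6, 3:8] - 0.1)), 0.1^3 / 6 + 1e-9)
})

test_that("phantom index maps match their analytic values", {
  # helix: twist = k, others 0
  tw <- make_phantom(phantom_spec("twist", shape = c(12, 12, 12), rate = 0.1))
  m <- dfa_maps(tw)
  inner <- interior_mask(c(12, 12, 12), 2)
  expect_lt(max(abs(m$twist$values[inner] / 0.1 - 1)), 0.02)
  expect_lt(max(m$splay$values[inner]), 1e-3)
  expect_lt(max(m$bend$values[inner]), 1e-3)

  # radial: splay = 1/r, circular: bend = 1/r (5% for r >= 5 voxels)
  shape <- c(24, 24, 8)
  r <- radius_array(shape)
  inner <- interior_mask(shape, 1)
  for (kind in c("splay", "bend")) {
    ph <- make_phantom(phantom_spec(kind, shape = shape))
    mm <- dfa_maps(ph)
    sel <- ph$mask & inner & r >= 5
    expect_lt(max(abs(mm[[kind]]$values[sel] * r[sel] - 1)), 0.05)
    other <- setdiff(c("splay", "bend"), kind)
    expect_lt(max(mm[[other]]$values[sel]), 0.05 / 5)
    expect_lt(max(mm$twist$values[sel]), 1e-10)
  }
})

test_that("all four maps are antipodal-invariant and satisfy the quadrature identity", {
  for (kind in c("splay", "bend", "twist")) {
    ph <- make_phantom(phantom_spec(kind, shape = c(10, 10, 8), rate = 0.12))
    m1 <- dfa_maps(ph)
    m2 <- dfa_maps(flip_directors(ph, seed = 4))
    for (nm in names(m1))
      expect_lt(max(abs(m1[[nm]]$values - m2[[nm]]$values)), 1e-12)
    d2 <- m1$splay$values^2 + m1$bend$values^2 + m1$twist$values^2
    expect_lt(max(abs(m1$distortion$values^2 - d2)), 1e-12)
    expect_true(all(m1$distortion$values + 1e-15 >=
                      pmax(m1$splay$values, m1$bend$values, m1$twist$values)))
  }
})

test_that("total_distortion validates grids and matches the Pythagorean identity", {
  z <- array(0, c(2, 2, 2))
  s <- scalar_map(z + 3); b <- scalar_map(z + 4); tw <- scalar_map(z)
  expect_equal(total_distortion(s, b, tw)$values[1], 5, tolerance = 1e-14)
  expect_equal(total_distortion(scalar_map(z), scalar_map(z), scalar_map(z))$values[1], 0)
  bad <- scalar_map(array(0, c(3, 2, 2)))
  expect_error(total_distortion(s, b, bad), "grid")
})

test_that("maps are equivariant under a 90-degree rotation of field and grid", {
  ph <- make_phantom(phantom_spec("twist", shape = c(9, 9, 7), rate = 0.2))
  # rotate 90 degrees about z: voxel (i,j,k) <- original (j, n+1-i, k),
  # directors rotated by Rz
  d <- dim(ph$directors)[1:3]
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  rot <- array(0, c(d[2], d[1], d[3], 3))
  for (k in 1:3) rot[, , , k] <- aperm(ph$directors[, rev(seq_len(d[2])), , , drop = FALSE],
                                       c(2, 1, 3, 4))[, , , k]
  tmp <- rot
  rot[, , , 1] <- Rz[1, 1] * tmp[, , , 1] + Rz[1, 2] * tmp[, , , 2]
  rot[, , , 2] <- Rz[2, 1] * tmp[, , , 1] + Rz[2, 2] * tmp[, , , 2]
  phr <- director_field(rot, aperm(ph$mask[, rev(seq_len(d[2])), , drop = FALSE],
                                   c(2, 1, 3)))
  m0 <- dfa_maps(ph)
  mr <- dfa_maps(phr)
  for (nm in names(m0)) {
    expected <- aperm(m0[[nm]]$values[, rev(seq_len(d[2])), , drop = FALSE], c(2, 1, 3))
    expect_lt(max(abs(mr[[nm]]$values - expected)), 1e-10)
  }
})

test_that("interior error decreases when the voxel size halves", {
  err_at <- function(h) {
    shape <- c(round(20 / h), round(20 / h), 4)
    ph <- make_phantom(phantom_spec("bend", shape = shape, spacing = c(h, h, h)))
    m <- dfa_maps(ph)
    ctr <- (shape[1:2] - 1) * h / 2
    x <- ((seq_len(shape[1]) - 1) * h) - ctr[1]
    y <- ((seq_len(shape[2]) - 1) * h) - ctr[2]
    r <- array(rep(sqrt(outer(x^2, y^2, `+`)), shape[3]), shape)
    inner <- interior_mask(shape, 1)
    sel <- ph$mask & inner & r >= 4 & r <= 8
    max(abs(m$bend$values[sel] * r[sel] - 1))
  }
  e1 <- err_at(1)
  e2 <- err_at(0.5)
  expect_lt(e2, e1)
})

test_that("FA/MD stay constant while geometric maps vary (dissociation)", {
  for (kind in c("splay", "bend", "twist")) {
    ph <- make_phantom(phantom_spec(kind, shape = c(16, 16, 8), rate = 0.1))
    sc <- tensor_scalars(directors_to_tensors(ph, c(1.7e-3, 2e-4, 2e-4)))
    expect_lt(sd(sc$fa$values[ph$mask]), 1e-8)
    expect_lt(sd(sc$md$values[ph$mask]), 1e-8)
    m <- dfa_maps(ph)
    ranges <- sapply(m, function(s) diff(range(s$values[ph$mask])))
    expect_gt(max(ranges), 1e-11 * 10)
  }
})

test_that("empty masks and boundary erosion are handled", {
  d <- array(0, c(3, 3, 3, 3)); d[, , , 3] <- 1
  f <- director_field(d, array(FALSE, c(3, 3, 3)))
  expect_error(director_jacobian(f), "empty mask")

  ph <- make_phantom(phantom_spec("twist", shape = c(6, 6, 6), rate = 0.1))
  je <- director_jacobian(ph, erode_boundary = TRUE)
  expect_equal(sum(je$mask), 4^3)
})
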