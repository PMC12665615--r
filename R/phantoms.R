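# Analytic director-field phantoms: constant-shape tensor fields whose
# orientation varies in space, so FA/MD are flat while the geometric indices
# have known closed-form values.

#' Phantom specification
#'
#' Describes a synthetic director field of constant tensor shape. `splay` is an
#' in-plane radial field (x - c)/r (divergence 1/r, zero curl); `bend` an
#' in-plane circular field (-(y - cy), x - cx, 0)/r (bend 1/r); `twist` a helix
#' n = (cos kz, sin kz, 0) with twist rate `rate` = k in rad/mm; `uniform` a
#' constant direction.
#'
#' @param kind one of `"uniform"`, `"splay"`, `"bend"`, `"twist"`.
#' @param shape grid extents in voxels (3 positive integers).
#' @param spacing voxel dimensions in mm.
#' @param rate twist rate k in rad/mm (twist phantom only).
#' @param center in-plane singularity center in mm; default grid center.
#' @param eigenvalues tensor shape, descending, mm^2/s.
#' @param direction direction of the uniform phantom.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(kind = c("uniform", "splay", "bend", "twist"),
                         shape = c(32, 32, 32), spacing = c(1, 1, 1),
                         rate = 0.1, center = NULL,
                         eigenvalues = c(1.7e-3, 2e-4, 2e-4),
                         direction = c(0, 0, 1)) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) stop("shape must be 3 positive integers")
  if (length(spacing) != 3 || any(spacing <= 0) || any(!is.finite(spacing)))
    stop("spacing must be 3 positive reals")
  if (kind == "twist" && !is.finite(rate)) stop("twist rate must be finite")
  eigenvalues <- as.numeric(eigenvalues)
  if (length(eigenvalues) != 3 || any(eigenvalues <= 0) ||
      is.unsorted(rev(eigenvalues)))
    stop("eigenvalues must be 3 positive reals sorted descending")
  if (is.null(center)) center <- (shape - 1) * spacing / 2
  structure(list(kind = kind, shape = shape, spacing = as.numeric(spacing),
                 rate = rate, center = as.numeric(center),
                 eigenvalues = eigenvalues,
                 direction = as.numeric(direction)),
            class = "phantom_spec")
}

#' Build a director-field phantom
#'
#' Voxel centers sit at `(i - 1) * spacing`. For the radial and circular kinds,
#' voxels within one voxel of the central singularity axis are masked out
#' because the 1/r indices diverge there.
#'
#' @param spec a [phantom_spec()].
#' @return A [director_field()].
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  d <- spec$shape
  sp <- spec$spacing
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  dirs <- array(0, c(d, 3))
  mask <- array(TRUE, d)
  switch(spec$kind,
    uniform = {
      u <- spec$direction / sqrt(sum(spec$direction^2))
      for (k in 1:3) dirs[, , , k] <- u[k]
    },
    splay = {
      dx <- X - spec$center[1]
      dy <- Y - spec$center[2]
      r <- sqrt(dx^2 + dy^2)
      mask <- r > max(sp[1:2]) * (1 + 1e-9)
      r[!mask] <- 1
      dirs[, , , 1] <- dx / r
      dirs[, , , 2] <- dy / r
    },
    bend = {
      dx <- X - spec$center[1]
      dy <- Y - spec$center[2]
      r <- sqrt(dx^2 + dy^2)
      mask <- r > max(sp[1:2]) * (1 + 1e-9)
      r[!mask] <- 1
      dirs[, , , 1] <- -dy / r
      dirs[, , , 2] <- dx / r
    },
    twist = {
      dirs[, , , 1] <- cos(spec$rate * Z)
      dirs[, , , 2] <- sin(spec$rate * Z)
    })
  for (k in 1:3) dirs[, , , k][!mask] <- 0
  # re-store a unit placeholder outside the mask so the constructor only
  # validates in-mask voxels
  dirs[, , , 3][!mask] <- 1
  director_field(dirs, mask, sp)
}

#' Dress a director field with constant-shape tensors
#'
#' Each in-mask voxel receives the tensor `R diag(l1, l2, l3) R^T` whose first
#' eigenvector is the local director; the secondary axes are a deterministic
#' orthonormal completion. Because the eigenvalues are shared by every voxel,
#' FA and MD are constant across the field.
#'
#' @param field a [director_field()].
#' @param eigenvalues 3 positive reals, descending (mm^2/s).
#' @return A [tensor_image()].
#' @export
directors_to_tensors <- function(field, eigenvalues = c(1.7e-3, 2e-4, 2e-4)) {
  stopifnot(inherits(field, "director_field"))
  ev <- as.numeric(eigenvalues)
  if (length(ev) != 3 || any(ev <= 0) || is.unsorted(rev(ev)))
    stop("eigenvalues must be 3 positive reals sorted descending")
  d <- dim(field$directors)[1:3]
  m <- field$mask
  n <- cbind(field$directors[, , , 1][m],
             field$directors[, , , 2][m],
             field$directors[, , , 3][m])
  if (nrow(n) && any(abs(sqrt(rowSums(n^2)) - 1) > 1e-6))
    stop("non-unit directors")
  # orthonormal completion: cross with the axis least aligned with n
  ax <- max.col(-abs(n), ties.method = "first")
  e <- matrix(0, nrow(n), 3)
  e[cbind(seq_len(nrow(n)), ax)] <- 1
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  u <- cross(n, e)
  u <- u / sqrt(rowSums(u^2))
  w <- cross(n, u)
  comp <- function(i, j) ev[1] * n[, i] * n[, j] + ev[2] * u[, i] * u[, j] +
    ev[3] * w[, i] * w[, j]
  tens <- array(0, c(d, 6))
  ij <- list(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3)) # FSL order
  for (k in 1:6) tens <- set_component(tens, k, m, comp(ij[[k]][1], ij[[k]][2]))
  tensor_image(tens, m, field$spacing)
}

#' Deterministic well-spread gradient scheme
#'
#' Single-shell gradient table built from a Fibonacci hemisphere (plus `n_b0`
#' b = 0 measurements), emulating an m-direction clinical acquisition.
#'
#' @param n_dirs number of diffusion-weighted directions.
#' @param bval shell b-value in s/mm^2.
#' @param n_b0 number of b = 0 measurements.
#' @return list with `bvals` (vector) and `bvecs` (3 x m matrix).
#' @export
gradient_scheme <- function(n_dirs = 30, bval = 1000, n_b0 = 1) {
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  cz <- i / n_dirs             # hemisphere: z in (0, 1)
  sz <- sqrt(1 - cz^2)
  g <- rbind(sz * cos(phi), sz * sin(phi), cz)
  bvals <- c(rep(0, n_b0), rep(bval, n_dirs))
  bvecs <- unname(cbind(matrix(0, 3, n_b0), g))
  dimnames(bvecs) <- NULL
  list(bvals = bvals, bvecs = bvecs)
}

#' Simulate diffusion-weighted signals from a tensor image
#'
#' Noise-free signal `S = s0 * exp(-b g' D g)`; a finite `snr` adds Rician noise
#' (magnitude of two independent Gaussian channels with sigma = s0/snr).
#'
#' @param tensors a [tensor_image()].
#' @param bvals,bvecs gradient table as in [dwi_dataset()].
#' @param s0 non-diffusion-weighted signal.
#' @param snr signal-to-noise ratio; `Inf` for noise-free.
#' @param seed integer seed for the noise draw.
#' @return A [dwi_dataset()].
#' @export
simulate_dwi <- function(tensors, bvals, bvecs, s0 = 1, snr = Inf, seed = NULL) {
  stopifnot(inherits(tensors, "tensor_image"))
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  m <- length(bvals)
  if (m < 7 || !any(bvals == 0))
    stop("need at least 7 measurements including one b = 0 for tensor fitting")
  if (any(bvals < 0)) stop("negative b-values are not allowed")
  nrm <- sqrt(colSums(bvecs^2))
  if (any(bvals > 0 & abs(nrm - 1) > 1e-6)) stop("non-unit gradient direction(s)")
  d <- dim(tensors$tensors)[1:3]
  msk <- tensors$mask
  tc <- lapply(1:6, function(k) tensors$tensors[, , , k][msk]) # xx xy xz yy yz zz
  # g' D g per measurement for all in-mask voxels
  gx <- bvecs[1, ]; gy <- bvecs[2, ]; gz <- bvecs[3, ]
  quad <- outer(tc[[1]], gx^2) + outer(tc[[4]], gy^2) + outer(tc[[6]], gz^2) +
    2 * (outer(tc[[2]], gx * gy) + outer(tc[[3]], gx * gz) + outer(tc[[5]], gy * gz))
  sig <- s0 * exp(-sweep(quad, 2, bvals, `*`))
  if (is.finite(snr)) {
    sigma <- s0 / snr
    sig <- with_seed(seed, {
      e1 <- matrix(rnorm(length(sig), 0, sigma), nrow(sig))
      e2 <- matrix(rnorm(length(sig), 0, sigma), nrow(sig))
      sqrt((sig + e1)^2 + e2^2)
    })
  }
  signals <- array(0, c(d, m))
  for (k in seq_len(m)) signals <- set_component(signals, k, msk, sig[, k])
  dwi_dataset(signals, bvals, bvecs, msk, tensors$spacing)
}
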