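# Diffusion tensor estimation and derived maps.

# Design matrix of the log-linear model log S = log S0 - b g' D g.
# Parameter order: (log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
.dti_design <- function(bvals, bvecs) {
  gx <- bvecs[1, ]; gy <- bvecs[2, ]; gz <- bvecs[3, ]
  cbind(1, -bvals * gx^2, -bvals * gy^2, -bvals * gz^2,
        -2 * bvals * gx * gy, -2 * bvals * gx * gz, -2 * bvals * gy * gz)
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Ordinary least squares on the log signals (the default for well-conditioned
#' single-shell acquisitions); `method = "wls"` re-weights each measurement by
#' its squared signal. Negative eigenvalues are clamped to zero rather than the
#' voxel being rejected, so spatial derivatives keep their support.
#'
#' @param dwi a [dwi_dataset()].
#' @param method `"lls"` (default) or `"wls"`.
#' @param signal_floor signals are clamped to this value before the log.
#' @return A [tensor_image()]; out-of-mask voxels are zero.
#' @export
fit_tensor_lls <- function(dwi, method = c("lls", "wls"), signal_floor = 1e-10) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  method <- match.arg(method)
  X <- .dti_design(dwi$bvals, dwi$bvecs)
  m <- nrow(X)
  if (m < 7 || qr(X)$rank < 7)
    stop(sprintf("design matrix rank-deficient: %d usable measurements (need >= 7 spanning directions)", m))
  d <- dim(dwi$signals)[1:3]
  msk <- dwi$mask
  tens <- array(0, c(d, 6))
  if (!any(msk)) return(tensor_image(tens, msk, dwi$spacing))
  S <- sapply(seq_len(m), function(k) dwi$signals[, , , k][msk])
  if (sum(msk) == 1) S <- matrix(S, 1)
  L <- t(log(pmax(S, signal_floor)))                 # m x v
  if (method == "lls") {
    theta <- qr.coef(qr(X), L)                       # 7 x v
  } else {
    theta <- apply(rbind(L, t(S)), 2, function(col) {
      l <- col[1:m]; w <- col[-(1:m)]^2
      qr.coef(qr(X * sqrt(w)), l * sqrt(w))
    })
  }
  # (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) -> FSL (xx, xy, xz, yy, yz, zz)
  Dm <- theta[c(2, 5, 6, 3, 7, 4), , drop = FALSE]
  Dm <- .clamp_psd(Dm)
  for (k in 1:6) tens <- set_component(tens, k, msk, Dm[k, ])
  tensor_image(tens, msk, dwi$spacing)
}

# Clamp negative eigenvalues to zero. Columns are FSL-ordered 6-vectors; only
# voxels failing a cheap principal-minor PSD test go through eigen().
.clamp_psd <- function(Dm) {
  xx <- Dm[1, ]; xy <- Dm[2, ]; xz <- Dm[3, ]
  yy <- Dm[4, ]; yz <- Dm[5, ]; zz <- Dm[6, ]
  m1 <- xx
  m2 <- xx * yy - xy^2
  m3 <- xx * (yy * zz - yz^2) - xy * (xy * zz - yz * xz) + xz * (xy * yz - yy * xz)
  scale2 <- (abs(xx) + abs(yy) + abs(zz))^2 + .Machine$double.xmin
  bad <- which(m1 < 0 | m2 < -1e-14 * scale2 | m3 < -1e-14 * scale2^1.5)
  for (v in bad) {
    eg <- eigen(.tensor_matrix(Dm[, v]), symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    M <- eg$vectors %*% diag(lam) %*% t(eg$vectors)
    Dm[, v] <- M[c(1, 4, 7, 5, 8, 9)]
  }
  Dm
}

#' FA and MD maps from a tensor image
#'
#' MD is the eigenvalue mean; FA is `sqrt(3/2) * ||lambda - MD|| / ||lambda||`,
#' computed from rotation invariants (Frobenius norms), with FA defined as 0
#' for an all-zero tensor.
#'
#' @param tensors a [tensor_image()].
#' @return list with elements `fa` and `md`, both [scalar_map()]s.
#' @export
tensor_scalars <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_image"))
  tc <- tensors$tensors
  d3 <- dim(tc)[1:3]
  cmp <- function(k) array(tc[, , , k], d3)
  xx <- cmp(1); xy <- cmp(2); xz <- cmp(3)
  yy <- cmp(4); yz <- cmp(5); zz <- cmp(6)
  md <- (xx + yy + zz) / 3
  fr2 <- xx^2 + yy^2 + zz^2 + 2 * (xy^2 + xz^2 + yz^2)   # ||D||_F^2
  dev2 <- pmax(fr2 - 3 * md^2, 0)                        # ||D - MD*I||_F^2
  fa <- sqrt(1.5 * dev2 / pmax(fr2, .Machine$double.xmin))
  fa[fr2 == 0] <- 0
  fa <- pmin(pmax(fa, 0), 1)
  fa[!tensors$mask] <- 0
  md[!tensors$mask] <- 0
  list(fa = scalar_map(fa, tensors$mask, tensors$spacing, "FA"),
       md = scalar_map(md, tensors$mask, tensors$spacing, "MD"))
}

#' Principal-eigenvector director field
#'
#' The director at each voxel is the eigenvector of the largest tensor
#' eigenvalue; its sign is arbitrary by contract. Voxels that are nearly
#' isotropic (FA below `fa_floor`) or orientationally degenerate (relative
#' gap between the two leading eigenvalues below `gap_tol`) are removed from
#' the mask; their count is reported in `attr(, "n_masked")`.
#'
#' @param tensors a [tensor_image()].
#' @param fa_floor minimum FA for a meaningful director (default 0.1; this is
#'   deliberately below the 0.2 analysis-mask threshold).
#' @param gap_tol minimum relative gap (l1 - l2) / l1.
#' @return A [director_field()].
#' @export
principal_director <- function(tensors, fa_floor = 0.1, gap_tol = 1e-6) {
  stopifnot(inherits(tensors, "tensor_image"))
  d <- dim(tensors$tensors)[1:3]
  fa <- tensor_scalars(tensors)$fa$values
  idx <- which(tensors$mask)
  dirs <- array(0, c(d, 3))
  dirs[, , , 3] <- 1   # unit placeholder outside the mask
  keep <- logical(length(idx))
  comp <- sapply(1:6, function(k) tensors$tensors[, , , k][idx])
  if (length(idx) == 1) comp <- matrix(comp, 1)
  n1 <- n2 <- n3 <- array(0, d)
  for (i in seq_along(idx)) {
    eg <- eigen(.tensor_matrix(comp[i, ]), symmetric = TRUE)
    lam <- eg$values
    if (fa[idx[i]] < fa_floor) next
    if (lam[1] <= 0 || (lam[1] - lam[2]) / lam[1] < gap_tol) next
    keep[i] <- TRUE
    n1[idx[i]] <- eg$vectors[1, 1]
    n2[idx[i]] <- eg$vectors[2, 1]
    n3[idx[i]] <- eg$vectors[3, 1]
  }
  mask <- array(FALSE, d)
  mask[idx[keep]] <- TRUE
  dirs[, , , 1] <- n1
  dirs[, , , 2] <- n2
  tmp <- dirs[, , , 3]; tmp[mask] <- n3[mask]; dirs[, , , 3] <- tmp
  out <- director_field(dirs, mask, tensors$spacing)
  attr(out, "n_masked") <- sum(!keep)
  out
}
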