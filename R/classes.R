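# Lightweight S3 containers for volumetric data sharing a common grid.

.check_grid <- function(values_dim, mask, spacing) {
  if (length(values_dim) != 3 || any(values_dim < 1))
    stop("expected a 3-D grid with positive extents")
  if (!is.logical(mask) || !identical(as.integer(dim(mask)), as.integer(values_dim)))
    stop("mask must be a logical array on the same grid as the data")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel dimensions (mm)")
  invisible(TRUE)
}

.same_grid <- function(a, b) {
  identical(dim(a$mask), dim(b$mask)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

#' Scalar map on a voxel grid
#'
#' A per-voxel scalar metric (FA, MD, splay, bend, twist, distortion, ...) with
#' its analysis mask and voxel spacing.
#'
#' @param values 3-D numeric array.
#' @param mask logical array on the same grid; default all voxels.
#' @param spacing voxel dimensions in mm.
#' @param metric metric name; `"FA"` additionally enforces values in \[0, 1\].
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, mask = NULL, spacing = c(1, 1, 1), metric = "other") {
  values <- as.array(values)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  .check_grid(dim(values), mask, spacing)
  if (any(!is.finite(values[mask]))) stop("non-finite values inside the mask")
  if (identical(metric, "FA") && any(values[mask] < -1e-9 | values[mask] > 1 + 1e-9))
    stop("FA values must lie in [0, 1]")
  structure(list(values = values, mask = mask, spacing = as.numeric(spacing),
                 metric = metric),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<scalar_map '%s'> %s grid, %d in-mask voxels, range [%.4g, %.4g]\n",
              x$metric, paste(dim(x$values), collapse = "x"), sum(x$mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Director field
#'
#' Per-voxel unit orientation with antipodal semantics: `n` and `-n` describe
#' the same director, and every downstream geometric index is invariant under
#' per-voxel sign flips.
#'
#' @param directors 4-D array (x, y, z, 3) of unit vectors.
#' @param mask logical array; default all voxels.
#' @param spacing voxel dimensions in mm.
#' @return An object of class `director_field`.
#' @export
director_field <- function(directors, mask = NULL, spacing = c(1, 1, 1)) {
  directors <- as.array(directors)
  d <- dim(directors)
  if (length(d) != 4 || d[4] != 3) stop("directors must be an x*y*z*3 array")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  .check_grid(d[1:3], mask, spacing)
  nrm <- sqrt(directors[, , , 1]^2 + directors[, , , 2]^2 + directors[, , , 3]^2)
  if (any(!is.finite(nrm[mask])) || any(abs(nrm[mask] - 1) > 1e-6))
    stop("directors must be unit norm inside the mask")
  structure(list(directors = directors, mask = mask, spacing = as.numeric(spacing)),
            class = "director_field")
}

#' @export
print.director_field <- function(x, ...) {
  cat(sprintf("<director_field> %s grid, %d in-mask voxels, spacing %s mm\n",
              paste(dim(x$directors)[1:3], collapse = "x"), sum(x$mask),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Diffusion tensor image
#'
#' Per-voxel symmetric 3x3 diffusion tensor stored as 6 components in FSL
#' lower-triangular order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz), units mm^2/s.
#'
#' @param tensors 4-D array (x, y, z, 6).
#' @param mask logical array; default all voxels.
#' @param spacing voxel dimensions in mm.
#' @return An object of class `tensor_image`.
#' @export
tensor_image <- function(tensors, mask = NULL, spacing = c(1, 1, 1)) {
  tensors <- as.array(tensors)
  d <- dim(tensors)
  if (length(d) != 4 || d[4] != 6)
    stop("tensors must be an x*y*z*6 array (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  .check_grid(d[1:3], mask, spacing)
  for (k in 1:6) if (any(!is.finite(tensors[, , , k][mask])))
    stop("non-finite tensor components inside the mask")
  structure(list(tensors = tensors, mask = mask, spacing = as.numeric(spacing)),
            class = "tensor_image")
}

#' @export
print.tensor_image <- function(x, ...) {
  cat(sprintf("<tensor_image> %s grid, %d in-mask voxels\n",
              paste(dim(x$tensors)[1:3], collapse = "x"), sum(x$mask)))
  invisible(x)
}

# 3x3 symmetric matrix from the 6 FSL-ordered components of one voxel.
.tensor_matrix <- function(comp6) {
  matrix(comp6[c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3)
}

#' Diffusion-weighted dataset
#'
#' 4-D signal volume with its FSL-dialect gradient table (b-values in s/mm^2,
#' unit gradient directions as a 3 x m matrix).
#'
#' @param signals 4-D array (x, y, z, measurement) of non-negative signals.
#' @param bvals numeric vector of b-values, one per measurement.
#' @param bvecs 3 x m matrix of gradient directions; unit norm where b > 0.
#' @param mask logical array; default all voxels.
#' @param spacing voxel dimensions in mm.
#' @return An object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(signals, bvals, bvecs, mask = NULL, spacing = c(1, 1, 1)) {
  signals <- as.array(signals)
  d <- dim(signals)
  if (length(d) != 4) stop("signals must be a 4-D array (x, y, z, measurement)")
  m <- d[4]
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != m || !identical(dim(bvecs), c(3L, as.integer(m))))
    stop("gradient table does not match the number of measurements")
  if (any(bvals < 0)) stop("negative b-values are not allowed")
  if (!any(bvals == 0)) stop("at least one b = 0 measurement is required")
  nrm <- sqrt(colSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-6
  if (any(bad)) stop(sprintf("%d gradient direction(s) are not unit norm", sum(bad)))
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  .check_grid(d[1:3], mask, spacing)
  structure(list(signals = signals, bvals = bvals, bvecs = bvecs, mask = mask,
                 spacing = as.numeric(spacing)),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  cat(sprintf("<dwi_dataset> %s grid, %d measurements (%d b=0), %d in-mask voxels\n",
              paste(dim(x$signals)[1:3], collapse = "x"), length(x$bvals),
              sum(x$bvals == 0), sum(x$mask)))
  invisible(x)
}
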