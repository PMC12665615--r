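# NIfTI and FSL gradient-table input/output (thin wrappers around RNifti).

.nifti_spacing <- function(img) {
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  as.numeric(pd[1:3])
}

#' Read a scalar NIfTI volume
#' @param path NIfTI file (.nii or .nii.gz).
#' @param mask optional logical array; default: finite nonzero voxels.
#' @param metric metric name for the resulting map.
#' @return A [scalar_map()].
#' @export
read_scalar_nifti <- function(path, mask = NULL, metric = "other") {
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim(img)[1:3])
  if (is.null(mask)) mask <- is.finite(v) & v != 0
  v[!is.finite(v)] <- 0
  scalar_map(v, mask, .nifti_spacing(img), metric)
}

#' Write a scalar map to NIfTI
#' @param map a [scalar_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scalar_nifti <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a director field as a 4-D 3-vector NIfTI
#' @param field a [director_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_director_nifti <- function(field, path) {
  stopifnot(inherits(field, "director_field"))
  d <- field$directors
  for (k in 1:3) d[, , , k][!field$mask] <- 0
  img <- RNifti::asNifti(d)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a director field from a 4-D 3-vector NIfTI
#' @param path NIfTI file.
#' @param mask optional logical array; default: voxels with nonzero norm.
#' @return A [director_field()].
#' @export
read_director_nifti <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) != 4 || dim(a)[4] != 3) stop("expected an x*y*z*3 volume")
  nrm <- sqrt(a[, , , 1]^2 + a[, , , 2]^2 + a[, , , 3]^2)
  if (is.null(mask)) mask <- nrm > 0.5
  # renormalize in-mask voxels against quantization error
  nrm[!mask] <- 1
  for (k in 1:3) a[, , , k] <- a[, , , k] / nrm
  a[, , , 3][!mask] <- 1
  a[, , , 1][!mask] <- 0
  a[, , , 2][!mask] <- 0
  director_field(a, mask, .nifti_spacing(img))
}

#' Write a tensor image as a 4-D 6-component NIfTI (FSL lower-triangular order)
#' @param tensors a [tensor_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tensor_nifti <- function(tensors, path) {
  stopifnot(inherits(tensors, "tensor_image"))
  img <- RNifti::asNifti(tensors$tensors)
  RNifti::pixdim(img) <- c(tensors$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read FSL-dialect b-values
#' @param path whitespace-separated text file.
#' @return numeric vector.
#' @export
read_bvals <- function(path) scan(path, quiet = TRUE)

#' Read FSL-dialect b-vectors
#'
#' FSL stores gradients as 3 rows x N columns; `orientation = "auto"` also
#' accepts the transposed (N x 3) layout.
#'
#' @param path whitespace-separated text file.
#' @param orientation `"auto"`, `"rows"` (3 x N) or `"columns"` (N x 3).
#' @return 3 x N matrix.
#' @export
read_bvecs <- function(path, orientation = c("auto", "rows", "columns")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (orientation == "auto") orientation <- if (nrow(m) == 3) "rows" else "columns"
  if (orientation == "columns") m <- t(m)
  if (nrow(m) != 3) stop("b-vector table is not 3 x N")
  m
}

#' Write an FSL-dialect gradient table
#' @param bvals numeric vector.
#' @param bvecs 3 x N matrix.
#' @param bval_path,bvec_path output paths.
#' @return invisibly, the two paths.
#' @export
write_gradient_table <- function(bvals, bvecs, bval_path, bvec_path) {
  writeLines(paste(format(bvals, trim = TRUE, scientific = FALSE), collapse = " "),
             bval_path)
  writeLines(apply(bvecs, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                               collapse = " ")),
             bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read a DWI dataset (NIfTI + bval/bvec)
#' @param dwi_path 4-D NIfTI of signals.
#' @param bval_path,bvec_path FSL gradient table.
#' @param mask_path optional NIfTI mask (nonzero = in mask).
#' @return A [dwi_dataset()].
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path, mask_path = NULL) {
  img <- RNifti::readNifti(dwi_path)
  a <- array(as.numeric(img), dim(img))
  mask <- NULL
  if (!is.null(mask_path)) {
    mi <- RNifti::readNifti(mask_path)
    mask <- array(as.numeric(mi), dim(mi)[1:3]) != 0
  }
  dwi_dataset(a, read_bvals(bval_path), read_bvecs(bvec_path), mask,
              .nifti_spacing(img))
}
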