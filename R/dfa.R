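# Geometric distortion indices of a director field.
#
# Operative definitions (continuous-field form, evaluated on the sign-aligned
# discrete field):
#   splay = |div n|            fanning perpendicular to the fiber axis
#   twist = |n . curl n|       rotation of neighbors about the axis
#   bend  = ||n x curl n||     curvature along the axis
# All three are magnitudes in 1/mm (equivalently rad/mm); the total distortion
# is their root-sum-of-squares.

#' Spatial Jacobian of a director field
#'
#' Central differences of the director components after local sign alignment:
#' each neighbor used in a difference is flipped when its dot product with the
#' center director is negative (a zero dot product is left unflipped), which
#' makes the Jacobian invariant under any per-voxel sign reassignment of the
#' input. One-sided differences are used where a neighbor leaves the mask;
#' voxels with no in-mask neighbor along an axis get a zero derivative along
#' that axis and are flagged in `attr(, "flagged")`.
#'
#' @param field a [director_field()].
#' @param erode_boundary drop in-mask voxels that lack a full central-difference
#'   stencil instead of falling back to one-sided differences.
#' @return list of class `director_jacobian` with `J` (x, y, z, 3, 3 array,
#'   `J[..., i, a]` = dn_i/dx_a in 1/mm), `mask`, `spacing`.
#' @export
director_jacobian <- function(field, erode_boundary = FALSE) {
  stopifnot(inherits(field, "director_field"))
  if (!any(field$mask)) stop("empty mask")
  d <- dim(field$directors)[1:3]
  n <- field$directors
  mask <- field$mask
  # canonicalize the per-voxel sign (largest-magnitude component positive) so
  # the Jacobian itself, not only the derived indices, is flip-invariant
  a1 <- abs(array(n[, , , 1], d)); a2 <- abs(array(n[, , , 2], d))
  a3 <- abs(array(n[, , , 3], d))
  lead <- array(n[, , , 1], d)
  lead[a2 > a1 & a2 >= a3] <- array(n[, , , 2], d)[a2 > a1 & a2 >= a3]
  lead[a3 > a1 & a3 > a2] <- array(n[, , , 3], d)[a3 > a1 & a3 > a2]
  s <- ifelse(lead < 0, -1, 1)
  for (k in 1:3) n[, , , k] <- array(n[, , , k], d) * s
  J <- array(0, c(d, 3, 3))
  flagged <- array(FALSE, d)
  eroded <- mask
  for (a in 1:3) {
    h <- field$spacing[a]
    mp <- shift_array(mask, a, 1L); mp[is.na(mp)] <- FALSE
    mm <- shift_array(mask, a, -1L); mm[is.na(mm)] <- FALSE
    np <- lapply(1:3, function(k) shift_array(n[, , , k], a, 1L))
    nm <- lapply(1:3, function(k) shift_array(n[, , , k], a, -1L))
    dot_p <- n[, , , 1] * np[[1]] + n[, , , 2] * np[[2]] + n[, , , 3] * np[[3]]
    dot_m <- n[, , , 1] * nm[[1]] + n[, , , 2] * nm[[2]] + n[, , , 3] * nm[[3]]
    sp <- ifelse(!is.na(dot_p) & dot_p < 0, -1, 1)
    sm <- ifelse(!is.na(dot_m) & dot_m < 0, -1, 1)
    both <- mask & mp & mm
    ponly <- mask & mp & !mm
    monly <- mask & !mp & mm
    none <- mask & !mp & !mm
    flagged[none] <- TRUE
    eroded <- eroded & both
    for (k in 1:3) {
      der <- array(0, d)
      der[both] <- (sp[both] * np[[k]][both] - sm[both] * nm[[k]][both]) / (2 * h)
      der[ponly] <- (sp[ponly] * np[[k]][ponly] - n[, , , k][ponly]) / h
      der[monly] <- (n[, , , k][monly] - sm[monly] * nm[[k]][monly]) / h
      J[, , , k, a] <- der
    }
  }
  out_mask <- if (erode_boundary) eroded else mask
  if (erode_boundary) for (k in 1:3) for (a in 1:3) J[, , , k, a][!out_mask] <- 0
  structure(list(J = J, mask = out_mask, spacing = field$spacing),
            class = "director_jacobian", flagged = flagged)
}

#' Splay, bend and twist index maps
#'
#' Assembles the three geometric distortion indices from the director Jacobian:
#' splay as the magnitude of the divergence, twist as the magnitude of the
#' curl component along the director, bend as the norm of the curl component
#' perpendicular to it. All maps are non-negative with units 1/mm and zero
#' outside the mask.
#'
#' @param field a [director_field()].
#' @param jacobian optionally a precomputed [director_jacobian()].
#' @param erode_boundary passed to [director_jacobian()].
#' @return list with `splay`, `bend`, `twist` [scalar_map()]s.
#' @export
dfa_indices <- function(field, jacobian = NULL, erode_boundary = FALSE) {
  stopifnot(inherits(field, "director_field"))
  jac <- jacobian %||% director_jacobian(field, erode_boundary)
  J <- jac$J
  mask <- jac$mask
  n1 <- field$directors[, , , 1]
  n2 <- field$directors[, , , 2]
  n3 <- field$directors[, , , 3]
  splay <- abs(J[, , , 1, 1] + J[, , , 2, 2] + J[, , , 3, 3])
  c1 <- J[, , , 3, 2] - J[, , , 2, 3]
  c2 <- J[, , , 1, 3] - J[, , , 3, 1]
  c3 <- J[, , , 2, 1] - J[, , , 1, 2]
  twist <- abs(n1 * c1 + n2 * c2 + n3 * c3)
  b1 <- n2 * c3 - n3 * c2
  b2 <- n3 * c1 - n1 * c3
  b3 <- n1 * c2 - n2 * c1
  bend <- sqrt(b1^2 + b2^2 + b3^2)
  for (nm in c("splay", "twist", "bend")) {
    v <- get(nm)
    v[!mask] <- 0
    assign(nm, v)
  }
  list(splay = scalar_map(splay, mask, field$spacing, "splay"),
       bend = scalar_map(bend, mask, field$spacing, "bend"),
       twist = scalar_map(twist, mask, field$spacing, "twist"))
}

#' Total distortion index
#'
#' Root-sum-of-squares of the splay, bend and twist maps, voxelwise; a single
#' non-negative severity index that dominates each of its components.
#'
#' @param splay,bend,twist [scalar_map()]s on identical grids and masks.
#' @return A [scalar_map()] named `"distortion"`.
#' @export
total_distortion <- function(splay, bend, twist) {
  for (m in list(bend, twist)) {
    if (!.same_grid(splay, m) || !identical(splay$mask, m$mask))
      stop("splay/bend/twist maps must share one grid and mask")
  }
  d <- sqrt(splay$values^2 + bend$values^2 + twist$values^2)
  d[!splay$mask] <- 0
  scalar_map(d, splay$mask, splay$spacing, "distortion")
}

#' All four distortion maps of a director field
#'
#' Convenience wrapper returning splay, bend, twist and total distortion.
#'
#' @inheritParams dfa_indices
#' @return list with `splay`, `bend`, `twist`, `distortion`.
#' @export
dfa_maps <- function(field, erode_boundary = FALSE) {
  idx <- dfa_indices(field, erode_boundary = erode_boundary)
  idx$distortion <- total_distortion(idx$splay, idx$bend, idx$twist)
  idx
}
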