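# Mask-restricted voxelwise group inference: GLM t-statistics, TFCE,
# Freedman-Lane permutation with max-statistic FWE correction, a leave-one-out
# consistency procedure, and normality-gated scalar group comparisons.

#' Analysis mask from a mean FA map and a region mask
#'
#' Voxels whose mean FA exceeds `threshold` (strictly) intersected with the
#' supplied anatomical region mask. This replaces full skeleton projection:
#' subjects are assumed to share a common grid.
#'
#' @param mean_fa [scalar_map()] of the cohort mean FA.
#' @param threshold FA cutoff (default 0.2).
#' @param region_mask logical array of the anatomically constrained region.
#' @return logical array.
#' @export
analysis_mask <- function(mean_fa, threshold = 0.2, region_mask = NULL) {
  stopifnot(inherits(mean_fa, "scalar_map"))
  if (is.null(region_mask)) region_mask <- array(TRUE, dim(mean_fa$values))
  if (!identical(dim(region_mask), dim(mean_fa$values))) stop("grid mismatch")
  out <- (mean_fa$values > threshold) & mean_fa$mask & region_mask
  if (!any(out))
    stop(sprintf("empty analysis mask: %d voxels pass FA > %g, %d in region, 0 in intersection",
                 sum(mean_fa$values > threshold & mean_fa$mask), threshold,
                 sum(region_mask)))
  out
}

#' Voxelwise mean of a list of scalar maps
#' @param maps list of [scalar_map()]s on one grid.
#' @return A [scalar_map()] (mask = intersection of input masks).
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  v <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  m <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  v[!m] <- 0
  scalar_map(v, m, maps[[1]]$spacing, maps[[1]]$metric)
}

#' Group design with demeaned nuisance covariates
#'
#' Builds the design matrix for a two-group comparison with optional nuisance
#' covariates (demeaned, as required for an interpretable group contrast).
#' The tested contrast is the group-indicator column (second level minus
#' first); both directions are examined downstream.
#'
#' @param group factor with exactly two levels, >= 2 subjects each.
#' @param covariates data frame or matrix of per-subject nuisance covariates
#'   (factors are expanded to 0/1), or NULL.
#' @return list of class `dfa_design` with `X`, `contrast_idx`, `reduced_idx`,
#'   `group`.
#' @export
make_design <- function(group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) < 2)) stop("need >= 2 subjects per group")
  X <- cbind(intercept = 1, group = as.numeric(group == levels(group)[2]))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cm <- sapply(cv, function(col) as.numeric(if (is.factor(col)) col else col))
    cm <- as.matrix(cm)
    if (nrow(cm) != length(group)) stop("covariate rows must match subjects")
    cm <- sweep(cm, 2, colMeans(cm))
    colnames(cm) <- names(cv)
    X <- cbind(X, cm)
  }
  if (qr(X)$rank < ncol(X)) stop("singular design")
  structure(list(X = X, contrast_idx = 2L,
                 reduced_idx = setdiff(seq_len(ncol(X)), 2L), group = group),
            class = "dfa_design")
}

# Normalize voxelwise data to an n x v matrix plus grid info.
.as_subject_matrix <- function(data, mask = NULL) {
  if (is.matrix(data)) {
    msk <- mask %||% attr(data, "mask")
    dims <- attr(data, "dims") %||% dim(msk)
    if (is.null(msk)) stop("a mask is required with matrix input")
    if (sum(msk) != ncol(data)) stop("mask size does not match matrix columns")
    return(list(Y = data, dims = dim(msk), mask = msk,
                spacing = attr(data, "spacing") %||% c(1, 1, 1)))
  }
  if (is.array(data) && length(dim(data)) == 4) {
    msk <- mask %||% array(TRUE, dim(data)[1:3])
    n <- dim(data)[4]
    Y <- t(sapply(seq_len(n), function(s) data[, , , s][msk]))
    if (sum(msk) == 1) Y <- matrix(Y, n, 1)
    return(list(Y = Y, dims = dim(msk), mask = msk, spacing = c(1, 1, 1)))
  }
  if (is.list(data) && all(sapply(data, inherits, "scalar_map"))) {
    msk <- mask %||% Reduce(`&`, lapply(data, `[[`, "mask"))
    Y <- t(sapply(data, function(m) m$values[msk]))
    if (sum(msk) == 1) Y <- matrix(Y, length(data), 1)
    return(list(Y = Y, dims = dim(msk), mask = msk, spacing = data[[1]]$spacing))
  }
  stop("data must be an n x v matrix, a 4-D array, or a list of scalar_map")
}

.vol_from_vec <- function(v, dims, mask) {
  out <- array(0, dims)
  out[mask] <- v
  out
}

# Precomputed pieces of the voxelwise OLS fit for one design.
.glm_prep <- function(X, contrast_idx) {
  if (qr(X)$rank < ncol(X)) stop("singular design")
  XtXinv <- chol2inv(chol(crossprod(X)))
  list(X = X, px = XtXinv %*% t(X), cvar = XtXinv[contrast_idx, contrast_idx],
       df = nrow(X) - ncol(X), ci = contrast_idx)
}

.glm_tvec <- function(prep, Y) {
  beta <- prep$px %*% Y
  res <- Y - prep$X %*% beta
  s2 <- colSums(res^2) / prep$df
  tt <- beta[prep$ci, ] / sqrt(pmax(s2 * prep$cvar, .Machine$double.xmin))
  zero <- s2 < 1e-28 * pmax(colMeans(Y^2), .Machine$double.xmin)
  tt[zero] <- 0
  attr(tt, "zero_variance") <- zero
  tt
}

#' Voxelwise GLM t-statistic map
#'
#' Ordinary least squares per voxel; t-statistic for the group contrast with
#' the nuisance covariates partialled out. With no covariates this reduces
#' exactly to the pooled-variance two-sample t-test. Zero-variance voxels get
#' t = 0 and are flagged in `attr(, "zero_variance")`.
#'
#' @param data n x v matrix (with `mask` attribute or `mask` argument), 4-D
#'   array (x, y, z, subject), or list of per-subject [scalar_map()]s.
#' @param design a [make_design()].
#' @param mask optional logical array restricting the analysis.
#' @return A [scalar_map()] of t-statistics.
#' @export
glm_tstat <- function(data, design, mask = NULL) {
  stopifnot(inherits(design, "dfa_design"))
  dd <- .as_subject_matrix(data, mask)
  if (nrow(dd$Y) != nrow(design$X)) stop("data rows must match design rows")
  if (nrow(design$X) < ncol(design$X) + 2) stop("too few subjects for the design")
  prep <- .glm_prep(design$X, design$contrast_idx)
  tt <- .glm_tvec(prep, dd$Y)
  out <- scalar_map(.vol_from_vec(tt, dd$dims, dd$mask), dd$mask, dd$spacing, "tstat")
  attr(out, "zero_variance") <- attr(tt, "zero_variance")
  out
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum_h e_h(v)^E * h^H * dh` over thresholds `h = dh, 2dh, ...`,
#' where `e_h(v)` is the extent (in voxels) of the connected component
#' containing `v` among voxels with statistic >= h. Only positive values are
#' enhanced; run the negated map for the opposite contrast direction. The
#' output is monotone in the input.
#'
#' @param stat [scalar_map()] or 3-D array of statistics.
#' @param E,H extent and height exponents (neuroimaging defaults 0.5 and 2).
#' @param dh threshold step; default `max(stat) / 100`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param mask optional logical array when `stat` is a plain array.
#' @return Same type as `stat`, holding the enhanced map.
#' @export
tfce_enhance <- function(stat, E = 0.5, H = 2, dh = NULL, connectivity = 26,
                         mask = NULL) {
  is_map <- inherits(stat, "scalar_map")
  v <- if (is_map) stat$values else as.array(stat)
  msk <- if (is_map) stat$mask else (mask %||% array(TRUE, dim(v)))
  v[!msk] <- 0
  mx <- max(v)
  if (is.null(dh)) dh <- if (mx > 0) mx / 100 else 1
  if (!is.finite(dh) || dh <= 0) stop("dh must be positive")
  out <- array(tfce_cpp(as.numeric(v), as.integer(dim(v)), E, H, dh,
                        as.integer(connectivity)), dim(v))
  if (is_map) scalar_map(out, msk, stat$spacing, "tfce") else out
}

#' Permutation-based FWE-corrected voxelwise inference
#'
#' Freedman-Lane permutation of the residuals from the reduced (nuisance-only)
#' model, TFCE enhancement of the resulting t-maps, and a max-statistic null:
#' each permutation contributes the maximum TFCE value over the mask across
#' *both* contrast directions, so the union of the two one-sided significance
#' maps controls family-wise error at `alpha` exactly. Corrected p-values use
#' the `(1 + count) / (1 + n_perm)` convention. When the group labelling
#' admits fewer distinct reassignments than `n_perm` (and there are no
#' covariates), the test enumerates them exhaustively with a warning.
#'
#' @inheritParams glm_tstat
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; results are deterministic given the seed.
#' @param E,H,connectivity TFCE parameters.
#' @param dh TFCE step; default per-map `max/100`.
#' @param alpha significance level for `sig_mask`.
#' @return list of class `stat_result`: `tstat`, `tfce_pos`, `tfce_neg`,
#'   `p_fwe_pos`, `p_fwe_neg` (3-D arrays), `sig_mask`, `mask`, `null_max`,
#'   `n_perm`, `seed`, `params`.
#' @export
permutation_fwe <- function(data, design, mask = NULL, n_perm = 5000,
                            seed = NULL, E = 0.5, H = 2, connectivity = 26,
                            dh = NULL, alpha = 0.05) {
  stopifnot(inherits(design, "dfa_design"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  dd <- .as_subject_matrix(data, mask)
  X <- design$X
  n <- nrow(X)
  if (nrow(dd$Y) != n) stop("data rows must match design rows")
  prep <- .glm_prep(X, design$contrast_idx)
  dims <- dd$dims
  msk <- dd$mask

  tfce_of <- function(tvec) {
    vol <- .vol_from_vec(tvec, dims, msk)
    array(tfce_cpp(as.numeric(vol), as.integer(dims), E, H,
                   dh %||% (if (max(vol) > 0) max(vol) / 100 else 1),
                   as.integer(connectivity)), dims)
  }

  t_obs <- .glm_tvec(prep, dd$Y)
  tf_pos <- tfce_of(t_obs)
  tf_neg <- tfce_of(-t_obs)

  no_covars <- length(design$reduced_idx) == 1
  n2 <- sum(design$group == levels(design$group)[2])
  exhaustive <- no_covars && choose(n, n2) <= n_perm
  Z <- X[, design$reduced_idx, drop = FALSE]
  fitZ <- Z %*% (chol2inv(chol(crossprod(Z))) %*% (t(Z) %*% dd$Y))
  resZ <- dd$Y - fitZ

  null_max <- with_seed(seed, {
    if (exhaustive) {
      warning(sprintf("only %d distinct group reassignments; enumerating exhaustively",
                      choose(n, n2)))
      combos <- combn(n, n2)
      apply(combos, 2, function(sel) {
        gperm <- rep(0, n); gperm[sel] <- 1
        Xp <- X; Xp[, design$contrast_idx] <- gperm
        tp <- .glm_tvec(.glm_prep(Xp, design$contrast_idx), dd$Y)
        max(max(tfce_of(tp)), max(tfce_of(-tp)))
      })
    } else {
      vapply(seq_len(n_perm), function(j) {
        Yp <- fitZ + resZ[sample.int(n), , drop = FALSE]
        tp <- .glm_tvec(prep, Yp)
        max(max(tfce_of(tp)), max(tfce_of(-tp)))
      }, numeric(1))
    }
  })
  n_eff <- length(null_max)
  pmap <- function(tf) {
    p <- array(1, dims)
    idx <- which(msk)
    obs <- tf[idx]
    p[idx] <- (1 + vapply(obs, function(o) sum(null_max >= o), numeric(1))) / (1 + n_eff)
    p
  }
  p_pos <- pmap(tf_pos)
  p_neg <- pmap(tf_neg)
  sig <- msk & ((p_pos <= alpha) | (p_neg <= alpha))
  structure(list(tstat = .vol_from_vec(t_obs, dims, msk),
                 tfce_pos = tf_pos, tfce_neg = tf_neg,
                 p_fwe_pos = p_pos, p_fwe_neg = p_neg,
                 sig_mask = sig, mask = msk, null_max = null_max,
                 n_perm = n_eff, seed = seed,
                 params = list(E = E, H = H, dh = dh,
                               connectivity = connectivity, alpha = alpha)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %d permutations, %d/%d voxels FWE-significant at alpha = %g\n",
              x$n_perm, sum(x$sig_mask), sum(x$mask), x$params$alpha))
  invisible(x)
}

# Voxel intersection of a list of logical arrays.
.mask_intersection <- function(masks) Reduce(`&`, masks)

#' Leave-one-out consistency of a small-group comparison
#'
#' Repeats the full permutation comparison once per member of the small group,
#' each time excluding that member, and retains only voxels significant in
#' every repeat. Guards small-sample voxelwise findings against being driven
#' by a single subject.
#'
#' @inheritParams permutation_fwe
#' @param group factor over all subjects (two levels).
#' @param covariates optional per-subject nuisance covariates (re-demeaned
#'   within each leave-one-out subset).
#' @param small_level level of `group` whose members are left out in turn;
#'   default the less frequent level (must have >= 3 members).
#' @return list with `intersection` (logical array), `reports` (one row per
#'   repeat: left-out index, number of significant voxels), `masks`.
#' @export
loo_consistency <- function(data, group, covariates = NULL, small_level = NULL,
                            mask = NULL, n_perm = 1000, seed = NULL,
                            alpha = 0.05, ...) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("group must have two levels")
  tab <- table(group)
  small_level <- small_level %||% names(tab)[which.min(tab)]
  members <- which(group == small_level)
  if (length(members) < 3) stop("small group must have >= 3 members")
  if (min(tab) - 1 < 2) stop("a repeat would leave an empty design")
  dd <- .as_subject_matrix(data, mask)
  masks <- list()
  reports <- data.frame(left_out = members, n_sig = NA_integer_)
  for (i in seq_along(members)) {
    keep <- setdiff(seq_along(group), members[i])
    des <- make_design(group[keep],
                       if (!is.null(covariates))
                         as.data.frame(covariates)[keep, , drop = FALSE])
    sub <- dd$Y[keep, , drop = FALSE]
    attr(sub, "mask") <- dd$mask
    res <- permutation_fwe(sub, des, n_perm = n_perm,
                           seed = if (is.null(seed)) NULL else seed + i,
                           alpha = alpha, ...)
    masks[[i]] <- res$sig_mask
    reports$n_sig[i] <- sum(res$sig_mask)
  }
  list(intersection = .mask_intersection(masks), reports = reports, masks = masks)
}

#' Normality-gated group comparison of scalar measures
#'
#' For each measure, Shapiro-Wilk normality within each group and Levene's
#' homogeneity test gate the choice between the pooled-variance independent
#' t-test and the Mann-Whitney U test; Benjamini-Hochberg correction is
#' applied across the family of measures.
#'
#' @param data data frame holding the measures, or a numeric vector for a
#'   single measure.
#' @param group factor with two levels.
#' @param measures column names to compare (all numeric columns by default).
#' @param alpha gate level for the normality and homogeneity tests.
#' @return data frame with columns `measure`, `test`, `statistic`, `p_raw`,
#'   `p_fdr`.
#' @export
group_compare_scalars <- function(data, group, measures = NULL, alpha = 0.05) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("group must have two levels")
  if (any(table(group) < 3)) stop("need >= 3 subjects per group")
  if (is.numeric(data)) data <- data.frame(value = data)
  measures <- measures %||% names(data)[sapply(data, is.numeric)]
  rows <- lapply(measures, function(m) {
    x <- data[[m]]
    g1 <- x[group == levels(group)[1]]
    g2 <- x[group == levels(group)[2]]
    if (sd(g1) == 0 && sd(g2) == 0) stop(sprintf("'%s' is constant within both groups", m))
    normal <- sd(g1) > 0 && sd(g2) > 0 &&
      shapiro.test(g1)$p.value >= alpha && shapiro.test(g2)$p.value >= alpha
    homosced <- tryCatch(
      car::leveneTest(x ~ group, center = "mean")[1, "Pr(>F)"] > alpha,
      error = function(e) FALSE)
    if (normal && homosced) {
      tt <- t.test(g1, g2, var.equal = TRUE)
      data.frame(measure = m, test = "t-test", statistic = unname(tt$statistic),
                 p_raw = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(g1, g2, exact = FALSE))
      data.frame(measure = m, test = "mann-whitney",
                 statistic = unname(wt$statistic), p_raw = wt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p_raw, method = "BH")
  out
}
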