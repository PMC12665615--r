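# Synthetic two-group cohorts with known region-specific geometric effects,
# age/sex covariates, clinical scores with chosen correlations, brainstem
# volume tables, and optional fixel-metric stand-in columns.

#' Default region label volume
#'
#' A 10 x 10 x 8 grid holding three 200-voxel slab regions separated by
#' background planes (so significance clusters cannot bridge regions under
#' 26-connectivity). The label lookup is stored in `attr(, "lookup")`.
#'
#' @param shape grid extents; the default is small enough for permutation
#'   simulations to run in seconds.
#' @return integer 3-D array of labels, 0 = background.
#' @export
default_roi_labels <- function(shape = c(10, 10, 8)) {
  lab <- array(0L, shape)
  lab[, , 1:2] <- 1L
  lab[, , 4:5] <- 2L
  lab[, , 7:8] <- 3L
  attr(lab, "lookup") <- c(ROI_A = 1L, ROI_B = 2L, ROI_C = 3L)
  lab
}

#' Cohort specification
#'
#' Describes a synthetic multi-group study: per-group sizes, the region label
#' volume, planted (group, region, metric) effects in units of the control
#' between-subject SD, covariate and clinical-score models, and noise levels.
#' Baselines are dimensionless (1.0 +- 0.1 by default) because absolute index
#' scales are study-specific.
#'
#' @param n_per_group named integer vector, e.g. `c(HC = 33, MSA = 31)`; the
#'   first name is the reference (control) group.
#' @param metrics metric names to simulate.
#' @param roi_labels integer label volume with a `lookup` attribute
#'   (name -> id); see [default_roi_labels()].
#' @param effects data frame with columns `group`, `roi`, `metric`, `size`
#'   (shift in units of `noise_sd`), or NULL for a null cohort.
#' @param baseline control-group mean of every metric.
#' @param noise_sd between-subject SD of the region-level metric values; effect
#'   sizes are expressed in these units.
#' @param voxel_noise_sd additional independent voxelwise measurement noise
#'   (volume output only).
#' @param age named list of `c(mean, sd)` per group.
#' @param sex_prop_female named numeric vector of female proportions per group.
#' @param clinical data frame with columns `score`, `feature` (e.g.
#'   `"ROI_B_bend"`), `r` (target correlation), or NULL.
#' @param fixel data frame with columns `column`, `feature`, `r` adding
#'   fixel-metric stand-in columns correlated with named features, or NULL.
#' @param volume_effects data frame with columns `group`, `region`, `size` for
#'   the brainstem subregion volume table.
#' @param output `"volumes"` to emit per-subject metric volumes as well as the
#'   subject-level feature table, `"table"` for the table only.
#' @param spacing voxel dimensions in mm.
#' @param seed integer seed; the bundle is a pure function of the spec.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(HC = 33, MSA = 31),
                        metrics = c("splay", "bend", "twist", "distortion"),
                        roi_labels = default_roi_labels(),
                        effects = NULL,
                        baseline = 1.0, noise_sd = 0.1, voxel_noise_sd = 0.05,
                        age = list(HC = c(mean = 57.5, sd = 8.9),
                                   MSA = c(mean = 57.6, sd = 7.3)),
                        sex_prop_female = c(HC = 16 / 33, MSA = 14 / 31),
                        clinical = NULL, fixel = NULL,
                        volume_effects = data.frame(
                          group = "MSA",
                          region = c("medulla", "midbrain", "pons"),
                          size = c(-0.8, -1.2, -2.6)),
                        output = c("table", "volumes"),
                        spacing = c(1, 1, 1), seed = 1L) {
  output <- match.arg(output)
  if (is.null(names(n_per_group)) || any(n_per_group < 2))
    stop("n_per_group must be a named vector with counts >= 2")
  lookup <- attr(roi_labels, "lookup")
  if (is.null(lookup)) {
    ids <- sort(setdiff(unique(as.integer(roi_labels)), 0L))
    lookup <- setNames(ids, paste0("ROI_", ids))
  }
  groups <- names(n_per_group)
  if (!is.null(effects)) {
    stopifnot(all(c("group", "roi", "metric", "size") %in% names(effects)))
    if (!all(effects$group %in% groups)) stop("unknown group in effects")
    if (!all(effects$roi %in% names(lookup))) stop("roi absent from label volume")
    if (!all(effects$metric %in% metrics)) stop("unknown metric in effects")
    if (any(!is.finite(effects$size))) stop("effect sizes must be finite")
  }
  if (!is.null(clinical)) {
    stopifnot(all(c("score", "feature", "r") %in% names(clinical)))
    if (any(abs(clinical$r) >= 1)) stop("|target correlation| must be < 1")
  }
  if (!is.null(fixel)) {
    stopifnot(all(c("column", "feature", "r") %in% names(fixel)))
    if (any(abs(fixel$r) >= 1)) stop("|target correlation| must be < 1")
  }
  if (!all(groups %in% names(age))) stop("age model missing for some group")
  if (!all(groups %in% names(sex_prop_female))) stop("sex model missing for some group")
  if (noise_sd <= 0 || voxel_noise_sd < 0) stop("invalid noise SDs")
  structure(list(n_per_group = n_per_group, metrics = metrics,
                 roi_labels = roi_labels, lookup = lookup, effects = effects,
                 baseline = baseline, noise_sd = noise_sd,
                 voxel_noise_sd = voxel_noise_sd, age = age,
                 sex_prop_female = sex_prop_female, clinical = clinical,
                 fixel = fixel, volume_effects = volume_effects,
                 output = output, spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# score constructed as r * z(feature) + sqrt(1 - r^2) * independent noise so the
# population correlation with the feature equals r.
.correlated_column <- function(feature, r, location, scale) {
  z <- as.numeric(scale(feature))
  location + scale * (r * z + sqrt(1 - r^2) * rnorm(length(feature)))
}

#' Generate a synthetic cohort bundle
#'
#' Control-group region-level metric values are Normal(baseline, noise_sd);
#' each (group, roi, metric) effect shifts the affected cells by
#' `size * noise_sd`. Volume output adds independent voxelwise noise on top of
#' the subject-level region value, so region means recover the planted effects.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `dfa_cohort` with elements `subjects` (id, group, age,
#'   sex), `features` (subject x region_metric table), `clinical`, `volumes`
#'   (brainstem subregions + eTIV), `maps` (named list metric -> 4-D array, or
#'   NULL), `mask`, `roi_labels`, and the spec.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    groups <- names(spec$n_per_group)
    n <- sum(spec$n_per_group)
    group <- factor(rep(groups, spec$n_per_group), levels = groups)
    age <- numeric(n)
    sex <- integer(n)
    for (g in groups) {
      i <- group == g
      age[i] <- rnorm(sum(i), spec$age[[g]]["mean"], spec$age[[g]]["sd"])
      sex[i] <- rbinom(sum(i), 1, spec$sex_prop_female[[g]])
    }
    subjects <- data.frame(id = sprintf("S%03d", seq_len(n)), group = group,
                           age = age, sex = factor(sex, 0:1, c("M", "F")))

    rois <- names(spec$lookup)
    feat_names <- as.vector(outer(rois, spec$metrics, paste, sep = "_"))
    shift <- matrix(0, n, length(feat_names), dimnames = list(NULL, feat_names))
    if (!is.null(spec$effects)) {
      for (k in seq_len(nrow(spec$effects))) {
        e <- spec$effects[k, ]
        shift[group == e$group, paste(e$roi, e$metric, sep = "_")] <-
          e$size * spec$noise_sd
      }
    }
    dev <- matrix(rnorm(n * length(feat_names), 0, spec$noise_sd), n,
                  dimnames = list(NULL, feat_names))
    features <- as.data.frame(spec$baseline + shift + dev)
    rownames(features) <- subjects$id

    clinical <- NULL
    if (!is.null(spec$clinical)) {
      clinical <- data.frame(id = subjects$id, group = group)
      for (k in seq_len(nrow(spec$clinical))) {
        cl <- spec$clinical[k, ]
        if (!cl$feature %in% names(features)) stop("clinical target feature not found")
        clinical[[cl$score]] <- .correlated_column(features[[cl$feature]], cl$r,
                                                   location = 12, scale = 6)
      }
    }

    vol_regions <- c(medulla = 4600, midbrain = 6500, pons = 14500)
    vol_sd <- vol_regions * 0.08
    volumes <- data.frame(id = subjects$id, group = group)
    for (rg in names(vol_regions)) {
      sft <- numeric(n)
      ve <- spec$volume_effects
      if (!is.null(ve)) {
        for (k in seq_len(nrow(ve))) if (ve$region[k] == rg)
          sft[group == ve$group[k]] <- ve$size[k] * vol_sd[[rg]]
      }
      volumes[[rg]] <- rnorm(n, vol_regions[[rg]], vol_sd[[rg]]) + sft
    }
    volumes$etiv <- rnorm(n, 1.45e6, 1.2e5)

    if (!is.null(spec$fixel)) {
      for (k in seq_len(nrow(spec$fixel))) {
        fx <- spec$fixel[k, ]
        if (!fx$feature %in% names(features)) stop("fixel target feature not found")
        features[[fx$column]] <- .correlated_column(features[[fx$feature]], fx$r,
                                                    location = 0.5, scale = 0.1)
      }
    }

    maps <- NULL
    mask <- spec$roi_labels > 0
    if (spec$output == "volumes") {
      d <- dim(spec$roi_labels)
      nmv <- sum(mask)
      roi_of_voxel <- spec$roi_labels[mask]
      maps <- list()
      for (mt in spec$metrics) {
        arr <- array(0, c(d, n))
        for (s in seq_len(n)) {
          base_vals <- numeric(nmv)
          for (rg in rois) {
            rid <- spec$lookup[[rg]]
            base_vals[roi_of_voxel == rid] <- features[s, paste(rg, mt, sep = "_")]
          }
          v <- base_vals + rnorm(nmv, 0, spec$voxel_noise_sd)
          tmp <- arr[, , , s]
          tmp[mask] <- v
          arr[, , , s] <- tmp
        }
        maps[[mt]] <- arr
      }
    }

    structure(list(subjects = subjects, features = features, clinical = clinical,
                   volumes = volumes, maps = maps, mask = mask,
                   roi_labels = spec$roi_labels, spec = spec),
              class = "dfa_cohort")
  })
}

#' @export
print.dfa_cohort <- function(x, ...) {
  cat(sprintf("<dfa_cohort> %s; %d features%s\n",
              paste(sprintf("%s=%d", names(x$spec$n_per_group), x$spec$n_per_group),
                    collapse = ", "),
              ncol(x$features),
              if (is.null(x$maps)) "" else sprintf("; volumes for %d metrics",
                                                   length(x$maps))))
  invisible(x)
}

#' Subject-by-voxel matrix for one cohort metric
#'
#' Flattens the per-subject volumes of one metric into the n x v matrix used by
#' the voxelwise statistics functions.
#'
#' @param cohort a `dfa_cohort` generated with `output = "volumes"`.
#' @param metric metric name.
#' @return matrix with attributes `dims` and `mask`.
#' @export
cohort_metric_matrix <- function(cohort, metric) {
  stopifnot(inherits(cohort, "dfa_cohort"))
  if (is.null(cohort$maps)) stop("cohort was generated without metric volumes")
  arr <- cohort$maps[[metric]]
  if (is.null(arr)) stop(sprintf("metric '%s' not simulated", metric))
  n <- dim(arr)[4]
  Y <- t(apply(arr, 4, function(v) v[cohort$mask]))
  if (sum(cohort$mask) == 1) Y <- matrix(as.vector(arr), n, 1)
  attr(Y, "dims") <- dim(cohort$mask)
  attr(Y, "mask") <- cohort$mask
  Y
}
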