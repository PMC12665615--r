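# Atlas-based feature extraction from significant voxel clusters.

#' Label connected clusters of a significance mask
#'
#' @param sig_mask logical array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return integer array, components labeled 1..K, background 0.
#' @export
label_clusters <- function(sig_mask, connectivity = 26) {
  sig_mask <- as.array(sig_mask)
  if (!is.logical(sig_mask)) sig_mask <- sig_mask > 0
  if (!any(sig_mask)) warning("empty significance mask")
  array(label_components_cpp(sig_mask, as.integer(dim(sig_mask)),
                             as.integer(connectivity)), dim(sig_mask))
}

# Family-specific minimum overlap (strict) for retaining a parcel.
.family_threshold <- function(metric_family) {
  switch(metric_family, DFA = 50L, FA_MD = 100L, FBA = 100L,
         stop("metric_family must be one of 'DFA', 'FA_MD', 'FBA'"))
}

#' Extract per-subject mean-metric features from atlas parcels
#'
#' For each atlas parcel, the overlap with the significant clusters is
#' computed; the parcel-metric is retained only if the overlap strictly
#' exceeds the family voxel-count threshold (100 voxels for FA/MD and
#' fixel-based metrics, 50 for the geometric DFA metrics). Retained features
#' are the per-subject means of the metric over the overlap voxels.
#'
#' @param clusters integer cluster map from [label_clusters()] (any nonzero
#'   voxel counts as significant).
#' @param atlas integer label volume (0 = background), optionally carrying a
#'   `lookup` attribute (name -> id).
#' @param metric_maps named list: metric name -> 4-D array (x, y, z, subject)
#'   or list of per-subject [scalar_map()]s.
#' @param metric_family `"DFA"`, `"FA_MD"` or `"FBA"`; sets the threshold.
#' @param subject_ids optional row names.
#' @return data frame (subjects x retained region_metric columns) with a
#'   `provenance` attribute recording the overlap voxel count per column.
#' @export
parcel_features <- function(clusters, atlas, metric_maps,
                            metric_family = c("DFA", "FA_MD", "FBA"),
                            subject_ids = NULL) {
  metric_family <- match.arg(metric_family)
  thr <- .family_threshold(metric_family)
  clusters <- as.array(clusters)
  atlas <- as.array(atlas)
  if (!identical(dim(clusters), dim(atlas))) stop("atlas/cluster grid mismatch")
  lookup <- attr(atlas, "lookup")
  ids <- sort(setdiff(unique(as.integer(atlas)), 0L))
  if (is.null(lookup)) lookup <- setNames(ids, paste0("region", ids))
  sig <- clusters > 0
  feats <- list()
  prov <- list()
  for (rid in ids) {
    overlap <- which(atlas == rid & sig)
    if (length(overlap) <= thr) next
    rname <- names(lookup)[match(rid, lookup)]
    for (mt in names(metric_maps)) {
      mm <- metric_maps[[mt]]
      vals <- if (is.list(mm)) {
        sapply(mm, function(m) mean(m$values[overlap]))
      } else {
        n <- dim(mm)[4]
        sapply(seq_len(n), function(s) mean(mm[, , , s][overlap]))
      }
      col <- paste(rname, mt, sep = "_")
      feats[[col]] <- vals
      prov[[col]] <- data.frame(column = col, region = rname, metric = mt,
                                family = metric_family, n_voxels = length(overlap))
    }
  }
  out <- if (length(feats)) as.data.frame(feats) else
    data.frame(row.names = seq_along(subject_ids %||% integer(0)))
  if (!is.null(subject_ids) && nrow(out)) rownames(out) <- subject_ids
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(column = character(), region = character(), metric = character(),
               family = character(), n_voxels = integer())
  rownames(provenance) <- NULL
  stopifnot(all(provenance$n_voxels > thr))
  if (anyNA(out)) stop("missing cells in extracted features")
  attr(out, "provenance") <- provenance
  out
}

#' Co-altered parcels from two significance maps
#'
#' Intersects two significance maps (e.g. a geometric-index map and a
#' fixel-metric map) and returns the atlas parcels containing at least
#' `min_voxels` intersecting voxels, with their intersection masks, for
#' cross-modal co-variation analysis.
#'
#' @param sig_a,sig_b logical arrays on one grid.
#' @param atlas integer label volume.
#' @param min_voxels inclusive minimum intersection size (default 30).
#' @return list with `regions` (data frame: region, n_voxels) and `masks`
#'   (named list of logical arrays).
#' @export
intersect_coaltered <- function(sig_a, sig_b, atlas, min_voxels = 30) {
  sig_a <- as.array(sig_a) > 0
  sig_b <- as.array(sig_b) > 0
  atlas <- as.array(atlas)
  if (!identical(dim(sig_a), dim(sig_b)) || !identical(dim(sig_a), dim(atlas)))
    stop("grid mismatch")
  lookup <- attr(atlas, "lookup")
  ids <- sort(setdiff(unique(as.integer(atlas)), 0L))
  if (is.null(lookup)) lookup <- setNames(ids, paste0("region", ids))
  both <- sig_a & sig_b
  regions <- list()
  masks <- list()
  for (rid in ids) {
    m <- both & (atlas == rid)
    nv <- sum(m)
    if (nv >= min_voxels) {
      rname <- names(lookup)[match(rid, lookup)]
      regions[[rname]] <- data.frame(region = rname, n_voxels = nv)
      masks[[rname]] <- m
    }
  }
  list(regions = if (length(regions)) do.call(rbind, c(regions, make.row.names = FALSE))
       else data.frame(region = character(), n_voxels = integer()),
       masks = masks)
}
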