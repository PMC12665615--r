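# Normality-gated correlations and multiplicity control for feature-clinical,
# feature-volume and cross-modal associations.

#' Normality-gated bivariate correlation
#'
#' Pearson's correlation when both variables pass the Shapiro-Wilk test at
#' `alpha` (and, for group-structured pairs, Levene's homogeneity test on both
#' variables); Spearman's rank correlation otherwise. The method actually used
#' is recorded.
#'
#' @param x,y numeric vectors (n >= 5, finite, non-constant).
#' @param alpha gate level (default 0.05).
#' @param group optional grouping factor; if supplied, Levene's test on each
#'   variable joins the gate.
#' @return list with `method` ("pearson" or "spearman"), `r`, `p`, `n`.
#' @export
gated_correlation <- function(x, y, alpha = 0.05, group = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  gate <- shapiro.test(x)$p.value >= alpha && shapiro.test(y)$p.value >= alpha
  if (gate && !is.null(group)) {
    group <- droplevels(as.factor(group[ok]))
    if (nlevels(group) >= 2) {
      lev <- function(v) tryCatch(
        car::leveneTest(v ~ group, center = "mean")[1, "Pr(>F)"] > alpha,
        error = function(e) FALSE)
      gate <- lev(x) && lev(y)
    }
  }
  method <- if (gate) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(method = method, r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjusted p-values, capped at 1 and returned in the input order.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values.
#' @export
bh_fdr <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Correlate a feature table against a family of target columns
#'
#' Applies [gated_correlation()] to every (feature, target) pair and corrects
#' the resulting p-values with Benjamini-Hochberg within the declared family
#' (clinical scores, subregion volumes, and cross-modal fixel columns are
#' corrected separately, as distinct analyses).
#'
#' @param features data frame of per-subject features (rows = subjects).
#' @param targets data frame of target columns on the same subjects; non-numeric
#'   columns are ignored.
#' @param family family identifier recorded in the report.
#' @param alpha normality-gate level.
#' @param group optional grouping factor passed to the gate.
#' @return data frame of class `correlation_report`, sorted by `p_fdr`:
#'   `x_name`, `y_name`, `method`, `r`, `p_raw`, `p_fdr`, `n`.
#' @export
family_correlations <- function(features, targets, family = "clinical",
                                alpha = 0.05, group = NULL) {
  features <- as.data.frame(features)
  targets <- as.data.frame(targets)
  if (nrow(features) != nrow(targets))
    stop("features and targets must cover the same subjects")
  if (nrow(features) < 5) stop("need >= 5 shared subjects")
  tcols <- names(targets)[sapply(targets, is.numeric)]
  fcols <- names(features)[sapply(features, is.numeric)]
  if (!length(tcols) || !length(fcols)) stop("no numeric columns to correlate")
  rows <- list()
  for (fx in fcols) for (ty in tcols) {
    g <- gated_correlation(features[[fx]], targets[[ty]], alpha, group)
    rows[[paste(fx, ty)]] <- data.frame(x_name = fx, y_name = ty,
                                        method = g$method, r = g$r,
                                        p_raw = g$p, n = g$n)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$p_fdr <- bh_fdr(out$p_raw)
  out$family <- family
  out <- out[order(out$p_fdr, out$p_raw), ]
  rownames(out) <- NULL
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Normalize regional volumes to estimated total intracranial volume
#'
#' @param volumes numeric vector or data frame of region volumes (mm^3).
#' @param etiv per-subject estimated total intracranial volume (mm^3, > 0).
#' @return volumes divided by eTIV, same shape as the input.
#' @export
volume_normalize <- function(volumes, etiv) {
  etiv <- as.numeric(etiv)
  if (any(!is.finite(etiv)) || any(etiv <= 0)) stop("eTIV must be positive")
  if (is.data.frame(volumes)) {
    num <- sapply(volumes, is.numeric)
    volumes[num] <- lapply(volumes[num], function(v) v / etiv)
    volumes
  } else {
    volumes / etiv
  }
}
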