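# Nested cross-validated stacked-ensemble classification with averaged-ROC
# evaluation and permutation feature importance.
#
# The protocol, not the model zoo, is the contract: an outer stratified k-fold
# reserves each fold in turn as an untouched test set; within each training
# set, heterogeneous base learners are trained with inner stratified folds and
# a meta-learner is fit only on their out-of-fold predictions, so no test-fold
# information leaks into the stack.

#' Stratified fold assignment
#'
#' Disjoint, exhaustive folds preserving class ratios: within each class the
#' per-fold counts differ by at most one, and the classes' extra members are
#' rotated across folds so total fold sizes stay balanced. Deterministic under
#' `seed`.
#'
#' @param labels class labels (factor or coercible).
#' @param k number of folds; reduced with a warning if a class has fewer
#'   members than `k`.
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..k.
#' @export
stratified_folds <- function(labels, k = 10, seed = NULL) {
  labels <- droplevels(as.factor(labels))
  counts <- table(labels)
  if (any(counts < 2)) stop("every class needs at least 2 members")
  kk <- min(k, min(counts))
  if (kk < k) warning(sprintf("k reduced from %d to %d (smallest class size)", k, kk))
  with_seed(seed, {
    fold <- integer(length(labels))
    start <- 0L
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((start + seq_along(idx) - 1L) %% kk) + 1L
      start <- (start + length(idx)) %% kk
    }
    fold
  })
}

# ---- base learners -----------------------------------------------------------

# glmnet insists on >= 2 columns; pad single-feature inputs with a zero column.
.pad2 <- function(x) if (ncol(x) >= 2) x else cbind(x, .pad = 0)

.fit_base <- function(learner, x, y, seed, num_trees) {
  switch(learner,
    ridge = {
      fit <- glmnet::glmnet(.pad2(x), y, family = "binomial", alpha = 0,
                            lambda = c(10, 1, 0.1, 0.01))
      structure(list(fit = fit), class = "dfa_base_ridge")
    },
    rf = {
      fit <- ranger::ranger(x = x, y = y, probability = TRUE,
                            num.trees = num_trees, seed = seed,
                            num.threads = 1)
      structure(list(fit = fit), class = "dfa_base_rf")
    },
    nb = {
      keep <- apply(x, 2, function(v) sd(v) > 0)
      if (!any(keep)) {
        structure(list(prior = mean(y == levels(y)[2])), class = "dfa_base_const")
      } else {
        fit <- e1071::naiveBayes(x[, keep, drop = FALSE], y)
        structure(list(fit = fit, keep = keep), class = "dfa_base_nb")
      }
    },
    stop(sprintf("unknown learner '%s'", learner)))
}

# Probability of the second factor level.
.predict_base <- function(model, x) {
  if (inherits(model, "dfa_base_ridge")) {
    as.numeric(predict(model$fit, .pad2(x), s = 0.01, type = "response"))
  } else if (inherits(model, "dfa_base_rf")) {
    predict(model$fit, data = as.data.frame(x), num.threads = 1)$predictions[, 2]
  } else if (inherits(model, "dfa_base_nb")) {
    p <- predict(model$fit, x[, model$keep, drop = FALSE], type = "raw")[, 2]
    p[!is.finite(p)] <- 0.5
    p
  } else if (inherits(model, "dfa_base_const")) {
    rep(model$prior, nrow(x))
  } else stop("unknown base model")
}

#' Fit a stacked ensemble with out-of-fold meta-training
#'
#' Base learners (ridge logistic regression, probability random forest, naive
#' Bayes by default) are cross-fit over inner stratified folds; the ridge
#' meta-learner sees only their out-of-fold predictions, then the base
#' learners are refit on the full training set for test-time prediction.
#' `meta_input = "insample"` deliberately trains the meta-learner on leaky
#' in-sample predictions and exists only as a diagnostic contrast.
#'
#' @param x feature matrix or data frame.
#' @param y two-level factor.
#' @param inner_folds inner stratification folds (default 10).
#' @param seed integer seed.
#' @param learners subset of `c("ridge", "rf", "nb")`.
#' @param num_trees random-forest size.
#' @param meta_input `"oof"` (default, leakage-safe) or `"insample"`.
#' @return object of class `stacked_ensemble`; `inner_auc` holds the apparent
#'   AUC of the meta-learner on its own training predictions.
#' @export
fit_stacked <- function(x, y, inner_folds = 10, seed = NULL,
                        learners = c("ridge", "rf", "nb"), num_trees = 100,
                        meta_input = c("oof", "insample")) {
  meta_input <- match.arg(meta_input)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("training labels must contain both classes")
  if (anyNA(x)) stop("missing cells in features; no imputation is performed")
  with_seed(seed, {
    fold <- suppressWarnings(stratified_folds(y, inner_folds,
                                              seed = draw_seeds(1)))
    seeds <- draw_seeds(length(learners) * (max(fold) + 1))
    si <- 0L
    oof <- matrix(NA_real_, nrow(x), length(learners),
                  dimnames = list(NULL, learners))
    for (f in seq_len(max(fold))) {
      tr <- fold != f
      for (l in seq_along(learners)) {
        si <- si + 1L
        m <- .fit_base(learners[l], x[tr, , drop = FALSE], y[tr], seeds[si],
                       num_trees)
        oof[!tr, l] <- .predict_base(m, x[!tr, , drop = FALSE])
      }
    }
    base_full <- lapply(seq_along(learners), function(l) {
      .fit_base(learners[l], x, y, seeds[length(learners) * max(fold) + l],
                num_trees)
    })
    meta_x <- if (meta_input == "oof") oof else
      sapply(base_full, .predict_base, x)
    meta <- glmnet::glmnet(.pad2(meta_x), y, family = "binomial", alpha = 0,
                           lambda = c(10, 1, 0.1, 0.01))
    scores <- as.numeric(predict(meta, .pad2(meta_x), s = 0.01,
                                 type = "response"))
    structure(list(base = base_full, meta = meta, learners = learners,
                   levels = levels(y), features = colnames(x),
                   meta_input = meta_input,
                   inner_auc = auc_score(scores, y)),
              class = "stacked_ensemble")
  })
}

#' @export
predict.stacked_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$features
  base_p <- sapply(object$base, .predict_base, newdata)
  if (nrow(newdata) == 1) base_p <- matrix(base_p, 1)
  as.numeric(predict(object$meta, .pad2(base_p), s = 0.01, type = "response"))
}

#' Area under the ROC curve (rank statistic)
#'
#' @param scores numeric classifier scores.
#' @param y two-level factor; the second level is the positive class.
#' @return AUC in \[0, 1\], or NA if a class is absent.
#' @export
auc_score <- function(scores, y) {
  y <- as.factor(y)
  pos <- y == levels(y)[2]
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Staircase ROC of one fold evaluated on a fixed FPR grid (vertical averaging):
# TPR(g) = max TPR attainable at FPR <= g.
.tpr_on_grid <- function(scores, y, grid) {
  pos <- y == levels(y)[2]
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  tpr <- c(0, tp / max(sum(pos), 1))
  fpr <- c(0, fp / max(sum(!pos), 1))
  vapply(grid, function(g) max(tpr[fpr <= g + 1e-12]), numeric(1))
}

#' Permutation feature importance on a held-out fold
#'
#' Importance of a feature is the mean drop in test-fold AUC when that feature
#' column is shuffled within the fold, over `n_repeats` shuffles.
#'
#' @param model a fitted [fit_stacked()] ensemble.
#' @param x_test,y_test held-out features and labels (>= 4 subjects, both
#'   classes present).
#' @param n_repeats shuffles per feature (>= 1).
#' @param seed integer seed.
#' @return named numeric vector of importances.
#' @export
permutation_importance <- function(model, x_test, y_test, n_repeats = 5,
                                   seed = NULL) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  x_test <- as.matrix(x_test)
  if (is.null(colnames(x_test))) colnames(x_test) <- model$features
  if (nrow(x_test) < 4) stop("test fold must have >= 4 subjects")
  y_test <- factor(y_test, levels = model$levels)
  base <- auc_score(predict(model, x_test), y_test)
  with_seed(seed, {
    imp <- vapply(seq_len(ncol(x_test)), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        xs <- x_test
        xs[, j] <- xs[sample.int(nrow(xs)), j]
        base - auc_score(predict(model, xs), y_test)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    names(imp) <- colnames(x_test) %||% paste0("V", seq_len(ncol(x_test)))
    imp
  })
}

#' Nested cross-validated evaluation of the stacked ensemble
#'
#' Outer stratified k-fold: each fold in turn is the untouched test set and a
#' stacked ensemble is fit on the remainder. Reports per-fold accuracy,
#' sensitivity and specificity at the 0.5 score threshold, the vertically
#' averaged ROC curve (mean TPR on a fixed FPR grid across folds) with its
#' AUC, the pooled-prediction AUC, and (optionally) permutation feature
#' importance averaged over the test folds.
#'
#' @param x feature matrix or data frame with no missing cells.
#' @param y two-level factor; the second level is the positive class.
#' @param outer_folds,inner_folds protocol sizes (default 10 and 10).
#' @param seed integer seed; the whole report is a pure function of
#'   (x, y, protocol, seed).
#' @param learners,num_trees passed to [fit_stacked()].
#' @param importance compute permutation feature importance per test fold.
#' @param n_repeats shuffles per feature for the importance.
#' @param fpr_grid FPR grid for ROC averaging (default 101 points).
#' @return list of class `nested_cv`: `folds` (per-fold metrics), `roc`
#'   (fpr, mean_tpr), `auc`, `auc_pooled`, `accuracy`, `sensitivity`,
#'   `specificity`, `importance` (data frame or NULL), `scores`.
#' @export
evaluate_nested <- function(x, y, outer_folds = 10, inner_folds = 10,
                            seed = NULL, learners = c("ridge", "rf", "nb"),
                            num_trees = 100, importance = FALSE, n_repeats = 5,
                            fpr_grid = seq(0, 1, length.out = 101)) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("y must have two classes")
  if (anyNA(x)) stop("missing cells in features; no imputation is performed")
  with_seed(seed, {
    fold <- stratified_folds(y, outer_folds, seed = draw_seeds(1))
    k <- max(fold)
    fold_seeds <- draw_seeds(2 * k)
    scores <- numeric(length(y))
    tpr_mat <- matrix(NA_real_, k, length(fpr_grid))
    imp_mat <- NULL
    per_fold <- data.frame(fold = seq_len(k), n_test = NA_real_,
                           accuracy = NA_real_, sensitivity = NA_real_,
                           specificity = NA_real_, auc = NA_real_)
    for (f in seq_len(k)) {
      te <- fold == f
      model <- fit_stacked(x[!te, , drop = FALSE], y[!te], inner_folds,
                           seed = fold_seeds[f], learners = learners,
                           num_trees = num_trees)
      sc <- predict(model, x[te, , drop = FALSE])
      scores[te] <- sc
      yt <- y[te]
      pos <- yt == levels(y)[2]
      pred_pos <- sc >= 0.5
      per_fold$n_test[f] <- sum(te)
      per_fold$accuracy[f] <- mean(pred_pos == pos)
      per_fold$sensitivity[f] <- if (any(pos)) mean(pred_pos[pos]) else NA
      per_fold$specificity[f] <- if (any(!pos)) mean(!pred_pos[!pos]) else NA
      per_fold$auc[f] <- auc_score(sc, yt)
      tpr_mat[f, ] <- .tpr_on_grid(sc, yt, fpr_grid)
      if (importance) {
        imp <- permutation_importance(model, x[te, , drop = FALSE], yt,
                                      n_repeats, seed = fold_seeds[k + f])
        if (is.null(imp_mat)) imp_mat <- matrix(NA_real_, k, length(imp),
                                                dimnames = list(NULL, names(imp)))
        imp_mat[f, ] <- imp
      }
    }
    mean_tpr <- colMeans(tpr_mat)
    imp_df <- NULL
    if (importance) {
      imp_df <- data.frame(feature = colnames(imp_mat),
                           importance = colMeans(imp_mat),
                           importance_sd = apply(imp_mat, 2, sd))
      imp_df <- imp_df[order(-imp_df$importance), ]
      rownames(imp_df) <- NULL
    }
    structure(list(folds = per_fold,
                   roc = data.frame(fpr = fpr_grid, mean_tpr = mean_tpr),
                   auc = trapz(fpr_grid, mean_tpr),
                   auc_pooled = auc_score(scores, y),
                   accuracy = mean(per_fold$accuracy),
                   sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
                   specificity = mean(per_fold$specificity, na.rm = TRUE),
                   importance = imp_df, scores = scores, fold = fold,
                   positive = levels(y)[2]),
              class = "nested_cv")
  })
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("<nested_cv> AUC (averaged ROC) = %.3f, pooled = %.3f; accuracy = %.3f, sensitivity = %.3f, specificity = %.3f\n",
              x$auc, x$auc_pooled, x$accuracy, x$sensitivity, x$specificity))
  if (!is.null(x$importance))
    cat(sprintf("top feature: %s (importance %.3f)\n",
                x$importance$feature[1], x$importance$importance[1]))
  invisible(x)
}

#' Top-k features normalized to the maximum importance
#'
#' @param report a [evaluate_nested()] result computed with
#'   `importance = TRUE`.
#' @param k number of features to report (default 10).
#' @return data frame with `feature`, `importance`, `importance_sd`,
#'   `normalized` (max = 1).
#' @export
top_features <- function(report, k = 10) {
  stopifnot(inherits(report, "nested_cv"))
  if (is.null(report$importance)) stop("report was computed without importance")
  imp <- head(report$importance, k)
  mx <- max(imp$importance)
  imp$normalized <- if (mx > 0) imp$importance / mx else 0
  imp
}
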