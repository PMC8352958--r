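# Random-forest disease classifier over gene features, with the
# cross-validated minimum-plus-standard-deviation feature-selection rule and
# rank-formulation ROC/AUC evaluation.

#' Candidate genes for the classifier
#'
#' The top differentially abundant genes, ordered by ascending q, then
#' ascending raw P, then descending mean-rank gap (a deterministic
#' tie-break). Defaults to 100 candidates; fewer are returned if fewer are
#' available.
#'
#' @param diff a `differential_result` data.frame (gene level).
#' @param top_n number of candidates (default 100).
#' @return character vector of gene ids.
#' @export
candidate_genes <- function(diff, top_n = 100) {
  gap <- abs(diff$mean_rank_case - diff$mean_rank_control)
  ord <- order(diff$q, diff$p, -gap, diff$feature)
  diff$feature[ord][seq_len(min(top_n, nrow(diff)))]
}

# Stratified fold assignment: each class is split as evenly as possible.
.stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

#' Cross-validated error curve over nested top-m gene sets
#'
#' Runs `n_trials` rounds of stratified `folds`-fold cross-validation. Within
#' each training fold a forest ranks the candidate genes by importance (mean
#' decrease in Gini impurity); genes are then added sequentially and the
#' held-out misclassification error of a forest on the top-m genes is
#' recorded for `m = 1..max_genes`. Per-trial curves and their mean and
#' standard deviation are returned, together with a reference importance
#' ranking fit on all samples (used to name the selected gene set).
#'
#' By default the importance ranking is re-fit inside each training fold
#' (no selection leakage into the held-out fold); `importance = "global"`
#' ranks once per trial on all samples, the higher-fidelity but leakier
#' variant.
#'
#' @param x samples x genes matrix (candidate genes).
#' @param y two-level factor; each class needs >= `folds` samples.
#' @param n_trials CV repetitions (default 5).
#' @param folds folds per trial (default 10).
#' @param seed RNG seed.
#' @param ntree trees per forest (default 500).
#' @param max_genes largest gene-set size on the curve (default all).
#' @param importance `"fold"` (default) or `"global"` ranking.
#' @return list of class `cv_error_curve`: `m`, `mean_error`, `sd_error`,
#'   `trial_errors` (trials x m), `ranking` (gene ids by reference
#'   importance), `seed`, `ntree`.
#' @export
cv_error_curve <- function(x, y, n_trials = 5, folds = 10, seed = 1L,
                           ntree = 500, max_genes = ncol(x),
                           importance = c("fold", "global")) {
  importance <- match.arg(importance)
  y <- droplevels(as.factor(y))
  stopifnot(is.matrix(x), nlevels(y) == 2, length(y) == nrow(x))
  if (any(table(y) < folds)) stop_invalid("each class needs >= %d samples", folds)
  M <- min(max_genes, ncol(x))
  set.seed(as.integer(seed))
  errs <- matrix(NA_real_, n_trials, M)

  rank_genes <- function(xi, yi) {
    rf <- randomForest::randomForest(xi, yi, ntree = ntree)
    imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
    order(imp, decreasing = TRUE)
  }

  for (tr in seq_len(n_trials)) {
    fold_id <- .stratified_folds(y, folds)
    wrong <- numeric(M)
    glob_rank <- if (importance == "global") rank_genes(x, y)
    for (f in seq_len(folds)) {
      tr_idx <- fold_id != f
      rk <- if (importance == "global") glob_rank
            else rank_genes(x[tr_idx, , drop = FALSE], y[tr_idx])
      for (m in seq_len(M)) {
        sel <- rk[seq_len(m)]
        rf <- randomForest::randomForest(x[tr_idx, sel, drop = FALSE],
                                         y[tr_idx], ntree = ntree)
        pred <- stats::predict(rf, x[!tr_idx, sel, drop = FALSE])
        wrong[m] <- wrong[m] + sum(pred != y[!tr_idx])
      }
    }
    errs[tr, ] <- wrong / length(y)
  }

  ref_rank <- rank_genes(x, y)
  structure(list(m = seq_len(M),
                 mean_error = colMeans(errs),
                 sd_error = apply(errs, 2, stats::sd),
                 trial_errors = errs,
                 ranking = colnames(x)[ref_rank],
                 seed = as.integer(seed), ntree = ntree,
                 importance = importance),
            class = "cv_error_curve")
}

#' Minimum-plus-standard-deviation feature selection
#'
#' The cutoff is the minimum of the averaged error curve plus the standard
#' deviation (across trials) at that point; the chosen gene-set size is the
#' smallest `m` whose mean error does not exceed the cutoff (so with sd 0 the
#' smallest argmin is chosen; ties at the cutoff are kept, which only matters
#' on exactly tied curves). The rule depends only on the curve.
#'
#' @param curve a `cv_error_curve`, or any list with `m`, `mean_error`,
#'   `sd_error` (and optionally `ranking`).
#' @return list: `m` (selected size), `cutoff`, `genes` (top-m of the
#'   ranking, NULL if the curve carries none).
#' @export
select_features <- function(curve) {
  me <- curve$mean_error
  if (!length(me)) stop_invalid("empty error curve")
  argmin <- which.min(me)
  cutoff <- me[argmin] + curve$sd_error[argmin]
  # small numeric slack so curves specified at printed precision (0.20 vs
  # 0.18 + 0.02) compare as equal
  m <- min(which(me <= cutoff + 1e-10))
  genes <- if (!is.null(curve$ranking)) curve$ranking[seq_len(m)]
  list(m = curve$m[m], cutoff = cutoff, genes = genes)
}

#' Train a forest on the selected genes and score samples
#'
#' Fits a random forest on the full training profile restricted to the
#' selected genes; the score of a sample is the forest's class probability
#' for the case level (the second factor level).
#'
#' @param x samples x genes training matrix.
#' @param y two-level factor (second level = case).
#' @param genes selected gene ids, all present in `x`.
#' @param seed RNG seed.
#' @param ntree trees (default 500).
#' @return list of class `classifier_model`: `forest`, `genes`, `scores`
#'   (training-sample case probabilities), `seed`, `ntree`.
#' @export
train_and_score <- function(x, y, genes, seed = 1L, ntree = 500) {
  y <- droplevels(as.factor(y))
  missing <- setdiff(genes, colnames(x))
  if (length(missing)) {
    stop_invalid("gene columns absent from profile: %s",
                 paste(missing, collapse = ", "))
  }
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x[, genes, drop = FALSE], y, ntree = ntree)
  case_level <- levels(y)[2]
  scores <- stats::predict(rf, x[, genes, drop = FALSE],
                           type = "prob")[, case_level]
  structure(list(forest = rf, genes = genes, scores = scores,
                 case_level = case_level, seed = as.integer(seed),
                 ntree = ntree),
            class = "classifier_model")
}

#' Score new samples with a trained classifier
#' @param model a `classifier_model`.
#' @param x samples x genes matrix containing the model's genes.
#' @return named numeric vector of case probabilities.
#' @export
score_samples <- function(model, x) {
  missing <- setdiff(model$genes, colnames(x))
  if (length(missing)) {
    stop_invalid("gene columns absent from profile: %s",
                 paste(missing, collapse = ", "))
  }
  stats::predict(model$forest, x[, model$genes, drop = FALSE],
                 type = "prob")[, model$case_level]
}

#' ROC curve and AUC by the rank formulation
#'
#' AUC is computed from the Mann-Whitney identity
#' `(sum of case ranks - n1 (n1 + 1) / 2) / (n1 * n0)` (ties share ranks, so
#' tied pairs count one half). The ROC staircase sweeps the unique score
#' thresholds from high to low.
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param labels two-level factor or logical; the second factor level (or
#'   `TRUE`) is the positive class. Both classes must be present.
#' @return list: `auc`, `roc` (data.frame `fpr`, `tpr`, staircase including
#'   (0,0) and (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) {
    pos <- labels
  } else {
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) != 2) stop_invalid("need both classes present")
    pos <- labels == levels(labels)[2]
  }
  if (!any(pos) || all(pos)) stop_invalid("need both classes present")
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  list(auc = auc,
       roc = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
}
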