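#' Select differentially expressed features for classification
#'
#' @param de_results a `DifferentialResult`.
#' @param lfc_cut,padj_cut selection thresholds (|log2FC| > 1, padj < 0.05).
#' @return character vector of feature ids (warns if empty).
#' @export
select_de_features <- function(de_results, lfc_cut = 1, padj_cut = 0.05) {
  sel <- classify_significant(de_results, lfc_cut, padj_cut)
  out <- c(sel$up, sel$down)
  if (length(out) == 0) warning("no feature passes the selection thresholds")
  out
}

#' Information gain of a continuous feature for binary labels
#'
#' IG = H(labels) - min over single thresholds t of the weighted conditional
#' entropy H(labels | value <= t vs > t), in bits, by exhaustive enumeration
#' of the midpoints between sorted distinct values. Constant features score 0.
#'
#' @param feature_values numeric vector.
#' @param labels two-level factor/vector of the same length.
#' @return information gain in bits.
#' @export
information_gain <- function(feature_values, labels) {
  labels <- as.factor(labels)
  stopifnot(length(feature_values) == length(labels))
  ent <- function(y) {
    p <- table(y) / length(y)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  u <- sort(unique(feature_values))
  if (length(u) < 2) return(0)
  thr <- (u[-1] + u[-length(u)]) / 2
  n <- length(labels)
  cond <- vapply(thr, function(t) {
    lo <- feature_values <= t
    sum(lo) / n * ent(labels[lo]) + sum(!lo) / n * ent(labels[!lo])
  }, 0)
  max(ent(labels) - min(cond), 0)
}

#' Random-forest impurity importance
#'
#' Mean-decrease-in-impurity importance from a seeded classification forest
#' (ranger) with sqrt(p) feature subsampling and bootstrap resampling.
#'
#' @param x samples x features numeric matrix.
#' @param labels two-level factor of length nrow(x).
#' @param n_trees number of trees (>= 100).
#' @param seed RNG seed (fixed seed gives identical scores).
#' @return named numeric importance vector (>= 0), one per feature.
#' @export
forest_importance <- function(x, labels, n_trees = 500, seed = 1) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("labels must contain two classes")
  if (n_trees < 100) stop("n_trees must be >= 100")
  df <- as.data.frame(x)
  fit <- ranger::ranger(x = df, y = labels, num.trees = n_trees,
                        importance = "impurity",
                        mtry = max(1, floor(sqrt(ncol(df)))),
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  imp[colnames(x)]
}

#' Combine two feature rankings by rank sum
#'
#' combined_rank = rank of (ig_rank + imp_rank); ties are broken by the
#' information-gain rank, then by feature id, giving a total order.
#'
#' @param ig_ranks,imp_ranks named integer rank vectors (1..n permutations)
#'   over the same feature set.
#' @return data.table(feature_id, ig_rank, imp_rank, combined_rank), ordered
#'   by combined rank.
#' @export
combine_ranks <- function(ig_ranks, imp_ranks) {
  if (!setequal(names(ig_ranks), names(imp_ranks))) {
    stop("rankings cover different feature sets")
  }
  ids <- names(ig_ranks)
  dt <- data.table(feature_id = ids, ig_rank = as.integer(ig_ranks),
                   imp_rank = as.integer(imp_ranks[ids]))
  dt[, rank_sum := ig_rank + imp_rank]
  setorder(dt, rank_sum, ig_rank, feature_id)
  dt[, combined_rank := seq_len(.N)]
  dt[, rank_sum := NULL]
  dt[]
}

#' Dual-rank feature scoring
#'
#' Ranks features in parallel by information gain and by forest importance
#' (higher score = rank 1; score ties broken by feature id), then combines
#' the two rankings by rank sum.
#'
#' @param x samples x features matrix.
#' @param labels two-level factor.
#' @param n_trees forest size.
#' @param seed forest seed.
#' @return A `FeatureRank` data.table: feature_id, ig_score, ig_rank,
#'   imp_score, imp_rank, combined_rank.
#' @export
rank_features <- function(x, labels, n_trees = 500, seed = 1) {
  ig <- vapply(seq_len(ncol(x)), function(j) information_gain(x[, j], labels), 0)
  names(ig) <- colnames(x)
  imp <- forest_importance(x, labels, n_trees = n_trees, seed = seed)
  rank_of <- function(score) {
    ord <- order(-score, names(score))
    r <- integer(length(score)); r[ord] <- seq_along(score)
    names(r) <- names(score)
    r
  }
  igr <- rank_of(ig); impr <- rank_of(imp)
  comb <- combine_ranks(igr, impr)
  comb[, `:=`(ig_score = ig[feature_id], imp_score = imp[feature_id])]
  setcolorder(comb, c("feature_id", "ig_score", "ig_rank", "imp_score",
                      "imp_rank", "combined_rank"))
  setorder(comb, combined_rank)
  comb[]
}

#' Default SVM hyperparameter grid
#'
#' Cost {0.1, 1, 10, 100}; gamma {0.001, 0.01, 0.1, 1} (rbf/polynomial);
#' kernels linear, rbf (radial) and polynomial with degree {2, 3}.
#' @return data.table of configurations (cost, gamma, kernel, degree).
#' @export
default_svm_grid <- function() {
  rbind(
    CJ(cost = c(0.1, 1, 10, 100), gamma = NA_real_, kernel = "linear",
       degree = NA_integer_),
    CJ(cost = c(0.1, 1, 10, 100), gamma = c(0.001, 0.01, 0.1, 1),
       kernel = "radial", degree = NA_integer_),
    CJ(cost = c(0.1, 1, 10, 100), gamma = c(0.001, 0.01, 0.1, 1),
       kernel = "polynomial", degree = c(2L, 3L)))
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into k folds.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

svm_fit_raw <- function(x, y, cfg, probability = TRUE) {
  args <- list(x = x, y = y, kernel = cfg$kernel, cost = cfg$cost,
               scale = FALSE, probability = probability)
  if (cfg$kernel %in% c("radial", "polynomial")) args$gamma <- cfg$gamma
  if (cfg$kernel == "polynomial") args$degree <- cfg$degree
  do.call(e1071::svm, args)
}

svm_prob <- function(fit, x, positive) {
  pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
  pr[, positive]
}

#' Tune and train an SVM with probability outputs
#'
#' Grid search over cost, gamma, kernel and degree by stratified inner-CV
#' AUC on the training set; the winning configuration is refit on the full
#' training set with sigmoid probability calibration. Features are z-scored
#' with training statistics stored in the model (applied to any test data).
#'
#' @param x samples x features training matrix.
#' @param labels two-level factor; the second level is the positive class.
#' @param grid configuration table (default [default_svm_grid()]).
#' @param inner_cv_folds inner folds (reduced with a warning if n is small).
#' @param seed RNG seed for fold assignment.
#' @return A `circlr_svm` model list (fit, center, scale, features, config,
#'   inner_auc, positive).
#' @export
tune_and_train_svm <- function(x, labels, grid = default_svm_grid(),
                               inner_cv_folds = 5, seed = 1) {
  labels <- droplevels(as.factor(labels))
  stopifnot(nlevels(labels) == 2, nrow(x) == length(labels))
  positive <- levels(labels)[2]
  k <- inner_cv_folds
  min_cl <- min(table(labels))
  if (k > min_cl) {
    warning("reducing inner folds from ", k, " to ", min_cl)
    k <- max(2, min_cl)
  }
  center <- colMeans(x)
  scl <- apply(x, 2, sd); scl[scl == 0 | is.na(scl)] <- 1
  xs <- scale(x, center = center, scale = scl)
  fold <- stratified_folds(labels, k, seed)
  grid <- as.data.table(grid)
  aucs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- grid[i]
    scores <- rep(NA_real_, nrow(xs))
    ok <- TRUE
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2) { ok <- FALSE; break }
      fit <- tryCatch(svm_fit_raw(xs[tr, , drop = FALSE], labels[tr], cfg),
                      error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      scores[!tr] <- tryCatch(
        svm_prob(fit, xs[!tr, , drop = FALSE], positive),
        error = function(e) rep(NA_real_, sum(!tr)))
    }
    aucs[i] <- if (ok && !anyNA(scores)) auc(scores, labels) else NA_real_
  }
  best <- which.max(ifelse(is.na(aucs), -Inf, aucs))
  cfg <- grid[best]
  fit <- svm_fit_raw(xs, labels, cfg)
  structure(list(fit = fit, center = center, scale = scl,
                 features = colnames(x), config = as.list(cfg),
                 inner_auc = aucs[best], positive = positive,
                 grid_auc = data.table(grid, inner_auc = aucs)),
            class = "circlr_svm")
}

#' @export
predict.circlr_svm <- function(object, newdata, ...) {
  missing_f <- setdiff(object$features, colnames(newdata))
  if (length(missing_f) > 0) {
    stop("features missing in test matrix: ", paste(missing_f, collapse = ", "))
  }
  xs <- scale(newdata[, object$features, drop = FALSE],
              center = object$center, scale = object$scale)
  svm_prob(object$fit, xs, object$positive)
}

#' Evaluate a trained classifier on a held-out cohort
#'
#' Standardizes the test matrix with the training statistics stored in the
#' model, computes per-sample probabilities and returns the ROC result.
#'
#' @param model a `circlr_svm`.
#' @param test_matrix samples x features matrix (must contain the model's
#'   features; an informative error lists any missing ids).
#' @param test_labels two-level factor.
#' @return A `RocResult`.
#' @export
evaluate_on_cohort <- function(model, test_matrix, test_labels) {
  scores <- predict(model, test_matrix)
  roc_result(scores, test_labels, positive = model$positive)
}

#' Area under the ROC curve by pairwise concordance
#'
#' AUC = mean over (positive, negative) pairs of [score_pos > score_neg]
#' + 1/2 [score_pos == score_neg], computed via the Mann-Whitney rank
#' identity (exactly equivalent, ties get average ranks).
#'
#' @param scores numeric prediction scores.
#' @param labels two-level factor; the second level is positive.
#' @param positive optional explicit positive class.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels, positive = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("both classes must be present")
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC from scores and labels
#'
#' @inheritParams auc
#' @return A `RocResult` list: scores, labels, `roc` (data.table fpr, tpr,
#'   threshold; monotone in both axes) and `auc`.
#' @export
roc_result <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(droplevels(labels))[2]
  pos <- labels == positive
  ord <- order(-scores)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))          # tie groups share one ROC point
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.table(threshold = c(Inf, s[last]),
                    fpr = c(0, fp[last] / sum(!pos)),
                    tpr = c(0, tp[last] / sum(pos)))
  structure(list(scores = scores, labels = labels, positive = positive,
                 roc = roc, auc = auc(scores, labels, positive)),
            class = "RocResult")
}

#' Stratified k-fold cross-validated classification
#'
#' Splits samples into stratified folds, trains the learner on each
#' training partition only (any feature selection or standardization inside
#' the learner sees training folds exclusively) and pools the out-of-fold
#' probabilities into a single ROC result.
#'
#' @param x samples x features matrix.
#' @param labels two-level factor.
#' @param k number of folds (default 10; error if k > n).
#' @param learner function(x_train, labels_train) returning an object whose
#'   `predict(object, x_test)` yields positive-class probabilities; default
#'   is [tune_and_train_svm()] with the default grid.
#' @param seed RNG seed for fold assignment (and passed to the default
#'   learner).
#' @return A `RocResult` of pooled out-of-fold scores (one per sample), with
#'   the fold assignment in `$folds`.
#' @export
kfold_cv_classify <- function(x, labels, k = 10, learner = NULL, seed = 1) {
  labels <- droplevels(as.factor(labels))
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of samples")
  if (is.null(learner)) {
    learner <- function(xt, yt) tune_and_train_svm(xt, yt, seed = seed)
  }
  fold <- stratified_folds(labels, k, seed)
  scores <- rep(NA_real_, n)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    model <- learner(x[tr, , drop = FALSE], labels[tr])
    scores[!tr] <- predict(model, x[!tr, , drop = FALSE])
  }
  out <- roc_result(scores, labels)
  out$folds <- fold
  out
}
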