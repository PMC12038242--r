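test_that("DE-based feature selection applies both thresholds", {
  res <- data.table(feature_id = c("a", "b", "c"),
                    log2FoldChange = c(2, 0.5, 2),
                    padj = c(0.001, 0.001, 0.5))
  expect_equal(select_de_features(res), "a")
  res_none <- data.table(feature_id = "a", log2FoldChange = 0.1, padj = 0.9)
  expect_warning(out <- select_de_features(res_none), "no feature")
  expect_length(out, 0)
})

test_that("information gain matches exhaustive threshold enumeration", {
  expect_equal(information_gain(c(1, 2, 10, 11), c("x", "x", "y", "y")), 1)
  expect_equal(information_gain(rep(3, 6), rep(c("x", "y"), 3)), 0)
  expect_equal(information_gain(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # a partially separating feature: verify against direct enumeration
  v <- c(1, 2, 3, 4, 5, 6); y <- c(0, 0, 1, 0, 1, 1)
  ent <- function(z) { p <- table(z) / length(z); -sum(p * log2(p)) }
  thr <- (head(sort(v), -1) + tail(sort(v), -1)) / 2
  best <- min(vapply(thr, function(t) {
    lo <- v <= t
    mean(lo) * ent(y[lo]) + mean(!lo) * ent(y[!lo])
  }, 0))
  expect_equal(information_gain(v, y), ent(y) - best)
})

test_that("forest importance is seeded and flags the separating feature", {
  sim <- simulate_cohort_matrix(51, 20, 1, effect_log2fc = 4,
                                dispersion = 0.05, seed = 601)
  x <- t(compute_cpm(sim$counts))
  imp1 <- forest_importance(x, sim$classes, seed = 7)
  imp2 <- forest_importance(x, sim$classes, seed = 7)
  expect_identical(imp1, imp2)
  expect_equal(names(which.max(imp1)), sim$informative)
  expect_true(all(imp1 >= 0))
  expect_error(forest_importance(x, rep("A", nrow(x))), "two classes")
  expect_error(forest_importance(x, sim$classes, n_trees = 10), "100")
})

test_that("rank combination is a deterministic rank-sum with stated ties", {
  igr <- c(A = 1L, B = 2L, C = 3L)
  impr <- c(A = 3L, B = 1L, C = 2L)
  comb <- combine_ranks(igr, impr)
  expect_equal(comb$feature_id[1], "B")          # sum 3 beats sum 4
  # identical rankings reproduce themselves
  same <- combine_ranks(igr, igr)
  expect_equal(same$combined_rank, same$ig_rank)
  # tie in sums: lower ig_rank wins (A sum 4 vs C sum 5; craft a tie)
  tie <- combine_ranks(c(A = 1L, B = 2L), c(A = 2L, B = 1L))
  expect_equal(tie$feature_id[1], "A")
  expect_error(combine_ranks(igr, impr[1:2]), "different feature sets")
})

test_that("AUC equals brute-force pairwise concordance", {
  brute_auc <- function(scores, labels, positive) {
    pos <- which(labels == positive); neg <- which(labels != positive)
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    tot / (length(pos) * length(neg))
  }
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.1), factor(c("p", "p", "n", "n"),
                                                 levels = c("n", "p"))), 0.75)
  expect_equal(auc(c(3, 4, 1, 2), c("n", "n", "p", "p") == "p"), 0)
  expect_equal(auc(rep(0.5, 10), rep(c("n", "p"), 5)), 0.5)
  expect_error(auc(1:3, rep("p", 3)), "both classes")
  set.seed(602)
  for (i in 1:300) {
    n <- sample(4:30, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # force ties
    lb <- factor(sample(c("n", "p"), n, replace = TRUE), levels = c("n", "p"))
    if (length(unique(lb)) < 2) next
    expect_equal(auc(sc, lb), brute_auc(sc, lb, "p"))
  }
})

test_that("ROC curves are monotone and degenerate cases step correctly", {
  set.seed(603)
  rr <- roc_result(runif(40), factor(sample(c("n", "p"), 40, replace = TRUE),
                                     levels = c("n", "p")))
  expect_true(all(diff(rr$roc$fpr) >= 0))
  expect_true(all(diff(rr$roc$tpr) >= 0))
  expect_equal(rr$roc$fpr[1], 0)
  expect_equal(tail(rr$roc$tpr, 1), 1)
  one <- roc_result(c(0.8, 0.3), factor(c("p", "n"), levels = c("n", "p")))
  expect_equal(one$auc, 1)
  expect_true(roc_result(c(0.3, 0.8), factor(c("p", "n"),
                                             levels = c("n", "p")))$auc %in% c(0, 1))
  # cross-check against the pROC reference on a random set
  sc <- runif(60); lb <- factor(sample(c("n", "p"), 60, replace = TRUE),
                                levels = c("n", "p"))
  expect_equal(auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<", levels = c("n", "p")))))
})

test_that("SVM tuning separates separable data and is seed-stable", {
  set.seed(604)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 4), 20, 2))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("lo", "hi"), each = 20), levels = c("lo", "hi"))
  grid <- data.table(cost = c(1, 10), gamma = c(NA, 0.1),
                     kernel = c("linear", "radial"), degree = NA_integer_)
  m1 <- tune_and_train_svm(x, y, grid = grid, seed = 8)
  m2 <- tune_and_train_svm(x, y, grid = grid, seed = 8)
  expect_identical(m1$config, m2$config)
  expect_equal(auc(predict(m1, x), y), 1)
  # shuffled labels: inner-CV AUC near chance
  y_sh <- circlr:::with_seed(605, sample(y))
  m0 <- tune_and_train_svm(x, y_sh, grid = grid, seed = 8)
  expect_gt(max(m0$grid_auc$inner_auc, na.rm = TRUE), 0.2)
  expect_lt(min(m0$grid_auc$inner_auc, na.rm = TRUE), 0.8)
})

test_that("cohort evaluation standardizes with training statistics", {
  set.seed(606)
  xtr <- matrix(rnorm(60 * 3, 10, 2), 60, 3,
                dimnames = list(NULL, c("f1", "f2", "f3")))
  xtr[31:60, 1] <- xtr[31:60, 1] + 6
  y <- factor(rep(c("a", "b"), each = 30), levels = c("a", "b"))
  grid <- data.table(cost = 1, gamma = NA_real_, kernel = "linear",
                     degree = NA_integer_)
  mod <- tune_and_train_svm(xtr, y, grid = grid, seed = 9)
  # test matrix on a shifted scale still classifies via stored training stats
  xte <- xtr + 100
  ev <- evaluate_on_cohort(mod, xte, y)
  expect_s3_class(ev, "RocResult")
  expect_error(evaluate_on_cohort(mod, xte[, 1:2], y), "f3")
})

test_that("stratified k-fold CV partitions samples and never leaks test rows", {
  set.seed(607)
  x <- matrix(rnorm(200), 40, 5, dimnames = list(sprintf("s%02d", 1:40), NULL))
  y <- factor(rep(c("a", "b"), 20), levels = c("a", "b"))
  seen <- list()
  recorder <- function(xt, yt) {
    seen[[length(seen) + 1]] <<- rownames(xt)
    structure(list(), class = "const_model")
  }
  assign("predict.const_model", function(object, newdata, ...)
    rep(0.5, nrow(newdata)), envir = globalenv())
  on.exit(rm("predict.const_model", envir = globalenv()), add = TRUE)
  cv <- kfold_cv_classify(x, y, k = 5, learner = recorder, seed = 10)
  expect_length(cv$scores, 40)                 # every sample scored once
  expect_equal(sort(unique(cv$folds)), 1:5)
  for (f in 1:5) {                             # training never sees its fold
    test_ids <- rownames(x)[cv$folds == f]
    expect_length(intersect(seen[[f]], test_ids), 0)
  }
  # folds are stratified: each fold holds both classes
  for (f in 1:5) expect_equal(uniqueN(y[cv$folds == f]), 2)
  expect_error(kfold_cv_classify(x, y, k = 50, seed = 1), "exceeds")
})

test_that("cross-validated SVM achieves perfect AUC on separable data", {
  set.seed(608)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("a", "b"), each = 30), levels = c("a", "b"))
  grid <- data.table(cost = 1, gamma = NA_real_, kernel = "linear",
                     degree = NA_integer_)
  cv <- kfold_cv_classify(x, y, k = 2, seed = 11,
                          learner = function(xt, yt)
                            tune_and_train_svm(xt, yt, grid = grid, seed = 11))
  expect_equal(cv$auc, 1)
})
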