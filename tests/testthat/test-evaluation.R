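test_that("stratified folds balance classes to within one member", {
  set.seed(51)
  labels <- rep(c(TRUE, FALSE), c(10, 90))
  f <- stratified_folds(labels, 5)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f[labels]) == 2))
  expect_true(all(table(f[!labels]) == 18))
  # permuting row order preserves per-fold class counts
  o <- sample(100)
  f2 <- stratified_folds(labels[o], 5)
  expect_true(all(table(f2[labels[o]]) == 2))
  expect_error(stratified_folds(rep(c(TRUE, FALSE), c(3, 97)), 5),
               "fewer than k")
})

test_that("rows visit each fold uniformly over repeated draws", {
  labels <- rep(c(TRUE, FALSE), c(10, 40))
  counts <- matrix(0, length(labels), 5)
  set.seed(52)
  for (i in 1:1000) {
    f <- stratified_folds(labels, 5)
    counts[cbind(seq_along(labels), f)] <- counts[cbind(seq_along(labels), f)] + 1
  }
  freq <- counts / 1000
  expect_lt(max(abs(freq - 0.2)), 0.06)  # ~1/k everywhere
})

test_that("AUROC equals the tie-corrected pairwise concordance oracle", {
  concordance_auc <- function(scores, labels) {
    pos <- which(labels); neg <- which(!labels)
    tot <- 0
    for (i in pos) for (j in neg)
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    tot / (length(pos) * length(neg))
  }
  expect_equal(auroc(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auroc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)), 0)
  set.seed(53)
  for (rep_i in 1:25) {
    n <- sample(10:60, 1)
    scores <- sample(seq_len(8), n, replace = TRUE) + # heavy ties
      ifelse(runif(n) < 0.5, 0, 0.5)
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(auroc(scores, labels), concordance_auc(scores, labels))
    # reversal symmetry
    expect_equal(auroc(-scores, labels), 1 - auroc(scores, labels))
  }
})

test_that("AUROC/AUPRC agree with pROC / are invariant to monotone maps", {
  set.seed(54)
  scores <- rnorm(100)
  labels <- runif(100) < plogis(scores)
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
  expect_equal(auroc(exp(scores), labels), auroc(scores, labels))
  expect_equal(auprc(exp(scores), labels), auprc(scores, labels))
})

test_that("ROC curves span (0,0) to (1,1) with one vertex per tie group", {
  set.seed(55)
  scores <- c(3, 3, 2, 1); labels <- c(TRUE, FALSE, TRUE, FALSE)
  cur <- roc_with_auc(scores, labels)
  expect_equal(cur$points$x[1], 0)
  expect_equal(cur$points$y[1], 0)
  expect_equal(cur$points$x[nrow(cur$points)], 1)
  expect_equal(cur$points$y[nrow(cur$points)], 1)
  expect_equal(nrow(cur$points), 4)  # 3 distinct scores + origin
  # trapezoid area equals the rank-statistic AUROC
  tr <- sum(diff(cur$points$x) *
              (utils::head(cur$points$y, -1) + utils::tail(cur$points$y, -1)) / 2)
  expect_equal(tr, cur$auc)
  expect_error(roc_with_auc(1:3, c(TRUE, TRUE, TRUE)), "one class")
})

test_that("average precision handles rank extremes and ties", {
  expect_equal(auprc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # single positive ranked first of 10 -> 1; ranked last -> 0.1
  expect_equal(auprc(10:1, c(TRUE, rep(FALSE, 9))), 1)
  expect_equal(auprc(10:1, c(rep(FALSE, 9), TRUE)), 0.1)
  # all scores tied collapses to prevalence
  expect_equal(auprc(rep(1, 20), rep(c(TRUE, FALSE), c(5, 15))), 0.25)
  expect_equal(auroc(rep(1, 20), rep(c(TRUE, FALSE), c(5, 15))), 0.5)
  cur <- prc_with_auc(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE))
  expect_equal(cur$baseline, 2 / 3)
  expect_equal(range(cur$points$x), c(1 / 2, 1))
  expect_error(prc_with_auc(1:3, rep(FALSE, 3)), "no positives")
})

test_that("hold-out R2 distinguishes correlation from calibration", {
  obs <- c(1, 2, 3, 4, 5)
  expect_equal(holdout_r2(obs, obs), 1)
  expect_equal(holdout_r2(obs, obs, "ss"), 1)
  # affine but miscalibrated predictions: cor^2 = 1, 1-SSE/SST < 1
  pred <- 2 * obs + 1
  expect_equal(holdout_r2(pred, obs), 1)
  expect_lt(holdout_r2(pred, obs, "ss"), 1)
  expect_error(holdout_r2(1:5, rep(2, 5)), "zero variance")
  expect_error(holdout_r2(1, 1), ">= 3")
  # sampling check: bivariate normal with rho = 0.5 -> mean R2 ~ 0.25
  set.seed(56)
  r2s <- replicate(150, {
    z <- rnorm(300); x <- z + rnorm(300, 0, sqrt(3)) # cor = 0.5
    holdout_r2(x, z)
  })
  expect_lt(abs(mean(r2s) - 0.25), 0.05)
})

test_that("cross-validation scores every row once and is seed-reproducible", {
  tab <- toy_feature_table(n = 100, prevalence = 0.2)
  cv <- cv_spec(k = 5, repeats = 6, seed = 31)
  res <- cross_validate(tab, model_spec("ATAC"), cv)
  expect_equal(dim(res$scores), c(100, 6))
  expect_false(anyNA(res$scores))
  res2 <- cross_validate(tab, model_spec("ATAC"), cv)
  expect_identical(res, res2)
  res3 <- cross_validate(tab, model_spec("ATAC"), cv_spec(k = 5, repeats = 6,
                                                          seed = 32))
  expect_false(identical(res$scores, res3$scores))
})

test_that("label-scoring models and constant scores hit the CV baselines", {
  tab <- toy_feature_table(n = 100, prevalence = 0.2)
  # feature equal to a scaled label: every repetition separates perfectly
  tab$ATAC_sum <- ifelse(tab$active, 100, 0)
  res <- cross_validate(tab, model_spec("ATAC"), cv_spec(repeats = 5, seed = 2))
  expect_true(all(res$metrics$auroc == 1))
  expect_true(all(res$metrics$auprc == 1))
  # metric-level random-guess baselines under constant scores
  y <- tab$active
  expect_equal(auroc(rep(0.3, 100), y), 0.5)
  expect_equal(auprc(rep(0.3, 100), y), mean(y))
})

test_that("permuted labels give chance-level CV performance", {
  set.seed(57)
  tab <- toy_feature_table(n = 120, prevalence = 0.2)
  tab$active <- sample(tab$active)
  res <- cross_validate(tab, model_spec("ATAC"), cv_spec(repeats = 25,
                                                         seed = 3))
  expect_gt(res$summary$auroc[["mean"]], 0.40)
  expect_lt(res$summary$auroc[["mean"]], 0.60)
  expect_lt(abs(res$summary$auprc[["mean"]] - mean(tab$active)), 0.08)
})

test_that("subset evaluation trains on all rows but scores the subset", {
  tab <- toy_feature_table(n = 120, prevalence = 0.25)
  tab$promoter_overlap[seq(1, 120, by = 4)] <- TRUE  # mixes both classes
  res <- cross_validate(tab, model_spec("ATAC"), cv_spec(repeats = 4,
                                                         seed = 8),
                        eval_subset = tab$promoter_overlap)
  expect_equal(res$eval_n, 30)
  expect_equal(nrow(res$scores), 30)
  expect_equal(res$prevalence, mean(tab$active[tab$promoter_overlap]))
  # train-within-subset mode restricts rows end to end
  res2 <- cross_validate(tab, model_spec("ATAC"), cv_spec(repeats = 4,
                                                          seed = 8),
                         eval_subset = tab$promoter_overlap,
                         train_on = "subset")
  expect_equal(res2$eval_n, 30)
  expect_false(identical(res$metrics$auroc, res2$metrics$auroc))
})

test_that("degenerate training folds are redrawn and logged", {
  tab <- toy_feature_table(n = 40, prevalence = 0.15)
  # unstratified folds + few positives: some draws have single-class folds
  res <- cross_validate(tab, model_spec("ATAC"),
                        cv_spec(k = 5, repeats = 10, stratified = FALSE,
                                seed = 12))
  expect_false(anyNA(res$scores))
  expect_gte(res$n_redraws, 0)
})

test_that("pooled curves from a CV run are well-formed", {
  tab <- toy_feature_table(n = 80, prevalence = 0.25)
  res <- cross_validate(tab, model_spec("ATAC"), cv_spec(repeats = 3,
                                                         seed = 5))
  roc <- cv_curve(res, "roc")
  prc <- cv_curve(res, "prc")
  expect_equal(roc$auc, auroc(as.vector(res$scores),
                              rep(res$truth, 3)))
  expect_equal(prc$baseline, mean(tab$active))
})
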