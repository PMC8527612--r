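#' Cross-validation specification
#'
#' Repeated stratified k-fold cross-validation, the evaluation scheme for
#' all classifiers and regressors: 5 folds repeated 200 times by default.
#'
#' @param k number of folds (`>= 2`).
#' @param repeats number of repetitions.
#' @param stratified preserve class balance within folds (default `TRUE`;
#'   regression folds stratify on the activity label).
#' @param seed master random seed; per-repetition seeds are derived from
#'   it by a counter scheme, so results are fully reproducible.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(k = 5, repeats = 200, stratified = TRUE, seed = 1) {
  stopifnot(k >= 2, repeats >= 1)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_spec")
}

## Counter-based seed derivation keeps repetitions independent and
## order-insensitive; results stay within 32-bit integer range.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) %% 2147483629 * 48271 +
                as.double(counter) * 1664525 + 1013904223) %% 2147483629) + 1L
}

#' Stratified fold assignment
#'
#' Partitions rows into `k` folds; within each class the fold sizes differ
#' by at most one. Fold labels are rotated by a random offset per class so
#' that, over repeated draws, every row lands in each fold with frequency
#' about `1/k`.
#'
#' @param labels vector of class labels (any atomic type); use a constant
#'   vector for unstratified folds.
#' @param k number of folds.
#' @return Integer vector of fold ids in `1:k`, aligned with `labels`.
#'   Uses the current RNG state.
#' @export
stratified_folds <- function(labels, k) {
  n <- length(labels)
  stopifnot(k >= 2, n >= k)
  folds <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop(sprintf("class '%s' has %d member(s), fewer than k = %d folds",
                   as.character(cl), length(idx), k))
    idx <- sample(idx)
    offset <- sample.int(k, 1) - 1L
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
  }
  folds
}

group_by_score <- function(scores, labels) {
  ## descending score with ties grouped: cumulative TP/FP at each distinct
  ## score threshold
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- as.numeric(labels[o])
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  ctp <- cumsum(y)[last]
  cfp <- cumsum(1 - y)[last]
  list(threshold = s[last], tp = ctp, fp = cfp,
       P = sum(y), N = sum(1 - y))
}

#' AUROC (tie-corrected rank statistic)
#'
#' Area under the ROC curve computed as the tie-corrected Mann-Whitney
#' statistic `U / (n+ * n-)` via midranks; identical to the trapezoidal
#' area of the tie-grouped ROC curve.
#'
#' @param scores numeric classifier scores.
#' @param labels logical/0-1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: one class absent")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve with area
#'
#' Curve points by descending score with ties grouped (one vertex per
#' distinct score), from (0, 0) to (1, 1); the area equals [auroc()].
#'
#' @inheritParams auroc
#' @return An object of class `perf_curve` with `points` (threshold, x =
#'   FPR, y = TPR), `auc`, `type = "roc"` and `baseline = 0.5`.
#' @export
roc_with_auc <- function(scores, labels) {
  g <- group_by_score(scores, labels)
  if (g$P == 0 || g$N == 0) stop("ROC undefined: one class absent")
  pts <- data.frame(threshold = c(Inf, g$threshold),
                    x = c(0, g$fp / g$N), y = c(0, g$tp / g$P))
  structure(list(points = pts, auc = auroc(scores, labels), type = "roc",
                 baseline = 0.5),
            class = "perf_curve")
}

#' Average precision (AUPRC)
#'
#' Area under the precision-recall curve as tie-grouped average precision:
#' the step-wise sum of (recall increment) x (precision at the
#' threshold). With all scores tied this collapses to the positive-class
#' prevalence, the random-guess baseline.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  g <- group_by_score(scores, labels)
  if (g$P == 0) stop("AUPRC undefined: no positives")
  dtp <- diff(c(0, g$tp))
  prec <- g$tp / (g$tp + g$fp)
  sum(dtp / g$P * prec)
}

#' Precision-recall curve with area
#'
#' Precision and recall at each distinct-score threshold (ties grouped);
#' the area is the average precision [auprc()] and the baseline is the
#' positive-class prevalence.
#'
#' @inheritParams auroc
#' @return An object of class `perf_curve` with `points` (threshold, x =
#'   recall, y = precision), `auc`, `type = "prc"` and `baseline` =
#'   prevalence.
#' @export
prc_with_auc <- function(scores, labels) {
  g <- group_by_score(scores, labels)
  if (g$P == 0) stop("PRC undefined: no positives")
  pts <- data.frame(threshold = g$threshold, x = g$tp / g$P,
                    y = g$tp / (g$tp + g$fp))
  structure(list(points = pts, auc = auprc(scores, labels), type = "prc",
                 baseline = g$P / (g$P + g$N)),
            class = "perf_curve")
}

#' @export
print.perf_curve <- function(x, ...) {
  cat(sprintf("%s curve: %d points, AUC = %.4f (baseline %.4f)\n",
              toupper(x$type), nrow(x$points), x$auc, x$baseline))
  invisible(x)
}

#' @export
plot.perf_curve <- function(x, ...) {
  lab <- if (x$type == "roc") c("False positive rate", "True positive rate")
         else c("Recall", "Precision")
  graphics::plot(x$points$x, x$points$y, type = "l", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = lab[1], ylab = lab[2],
                 main = sprintf("%s (AUC = %.3f)", toupper(x$type), x$auc), ...)
  if (x$type == "roc") graphics::abline(0, 1, lty = 3)
  else graphics::abline(h = x$baseline, lty = 3)
  invisible(x)
}

#' Hold-out R-squared
#'
#' Agreement between held-out predictions and observed reporter
#' expression. The default is the squared Pearson correlation of the
#' pooled held-out pairs; `method = "ss"` gives `1 - SSE/SST`, which
#' additionally penalizes miscalibrated (affinely shifted) predictions and
#' can be negative.
#'
#' @param predicted,observed numeric vectors (`>= 3` pairs; `observed`
#'   must have positive variance).
#' @param method `"cor"` (squared correlation, default) or `"ss"`
#'   (`1 - SSE/SST`).
#' @return R-squared (may be `NA` for `"cor"` when predictions are
#'   constant).
#' @export
holdout_r2 <- function(predicted, observed, method = c("cor", "ss")) {
  method <- match.arg(method)
  stopifnot(length(predicted) == length(observed))
  if (length(observed) < 3) stop("need >= 3 prediction pairs")
  if (stats::sd(observed) == 0) stop("observed values have zero variance")
  if (method == "cor") {
    if (stats::sd(predicted) == 0) return(NA_real_)
    stats::cor(predicted, observed)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
}

#' Repeated stratified cross-validation of an activity model
#'
#' For each repetition, draws fresh stratified folds from a seed derived
#' from the master seed, fits the model on k-1 folds (transform and
#' standardization learned on the training folds only), scores the
#' held-out fold, pools held-out predictions within the repetition (every
#' row exactly once) and computes per-repetition metrics: AUROC and AUPRC
#' for classification, hold-out R-squared (both estimators) for
#' regression. A repetition whose training folds degenerate to a single
#' class is redrawn with the next derived seed and logged.
#'
#' Subset evaluation supports the two stratified analyses: with
#' `eval_subset` and `train_on = "all"`, models are trained on the full
#' table but metrics use only the held-out rows in the subset (e.g.
#' promoter-overlapping CRMs); with `train_on = "subset"`, training and
#' testing are confined to the subset.
#'
#' @param table feature table with the spec's predictors plus `active`
#'   and/or `expr`.
#' @param spec a [model_spec].
#' @param cv a [cv_spec].
#' @param eval_subset optional logical vector (aligned with `table` rows)
#'   selecting the evaluation subset.
#' @param train_on `"all"` or `"subset"`.
#' @return An object of class `cv_result`: per-repetition `metrics` data
#'   frame, `scores` matrix (rows = evaluated table rows, columns =
#'   repetitions), `truth`, `summary` (mean/sd/quantiles per metric),
#'   `n_redraws`, and the specs.
#' @export
cross_validate <- function(table, spec, cv = cv_spec(),
                           eval_subset = NULL, train_on = c("all", "subset")) {
  train_on <- match.arg(train_on)
  stopifnot(inherits(spec, "model_spec"), inherits(cv, "cv_spec"))
  n <- nrow(table)
  if (is.null(eval_subset)) eval_subset <- rep(TRUE, n)
  stopifnot(length(eval_subset) == n)
  if (train_on == "subset") {
    table <- as.data.frame(table)[eval_subset, , drop = FALSE]
    n <- nrow(table)
    eval_subset <- rep(TRUE, n)
  }
  y_class <- table$active
  y_resp <- if (spec$task == "classify") as.numeric(table$active) else table$expr
  if (is.null(y_resp))
    stop("response column ('active' or 'expr') not found in table")
  strat_labels <- if (!cv$stratified) rep(1L, n)
                  else if (!is.null(y_class)) as.integer(y_class)
                  else {
                    brks <- unique(stats::quantile(
                      y_resp, probs = seq(0, 1, length.out = min(cv$k, 5) + 1)))
                    if (length(brks) < 3) rep(1L, n)
                    else as.integer(cut(y_resp, brks, include.lowest = TRUE))
                  }
  eval_idx <- which(eval_subset)
  scores <- matrix(NA_real_, nrow = length(eval_idx), ncol = cv$repeats)
  metric_names <- if (spec$task == "classify") c("auroc", "auprc")
                  else c("r2_cor", "r2_ss")
  metrics <- matrix(NA_real_, nrow = cv$repeats, ncol = length(metric_names),
                    dimnames = list(NULL, metric_names))
  counter <- 0L
  n_redraws <- 0L
  for (rep_i in seq_len(cv$repeats)) {
    repeat {
      counter <- counter + 1L
      if (counter > cv$repeats + 50L + n_redraws)
        stop("too many degenerate fold draws; check class balance and k")
      seed_r <- derive_seed(cv$seed, counter)
      set.seed(seed_r)
      folds <- stratified_folds(strat_labels, cv$k)
      pred <- rep(NA_real_, n)
      ok <- TRUE
      for (j in seq_len(cv$k)) {
        tr <- folds != j
        fit <- tryCatch(
          crm_model(as.data.frame(table)[tr, , drop = FALSE], spec,
                    y = y_resp[tr]),
          crmpred_single_class = function(e) NULL,
          error = function(e) {
            if (grepl("single class|more observations", conditionMessage(e)))
              NULL else stop(e)
          })
        if (is.null(fit)) { ok <- FALSE; break }
        pred[!tr] <- predict(fit, as.data.frame(table)[!tr, , drop = FALSE])
      }
      if (ok) break
      n_redraws <- n_redraws + 1L
    }
    scores[, rep_i] <- pred[eval_idx]
    if (spec$task == "classify") {
      metrics[rep_i, "auroc"] <- auroc(pred[eval_idx], y_class[eval_idx])
      metrics[rep_i, "auprc"] <- auprc(pred[eval_idx], y_class[eval_idx])
    } else {
      metrics[rep_i, "r2_cor"] <- holdout_r2(pred[eval_idx], y_resp[eval_idx],
                                             "cor")
      metrics[rep_i, "r2_ss"] <- holdout_r2(pred[eval_idx], y_resp[eval_idx],
                                            "ss")
    }
  }
  metrics <- as.data.frame(metrics)
  metrics$repetition <- seq_len(cv$repeats)
  summ <- lapply(metric_names, function(m) {
    v <- metrics[[m]]
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
      stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE))
  })
  names(summ) <- metric_names
  truth <- if (spec$task == "classify") as.logical(y_class[eval_idx])
           else y_resp[eval_idx]
  baseline <- if (spec$task == "classify") mean(y_class[eval_idx]) else NA_real_
  structure(list(metrics = metrics, scores = scores, truth = truth,
                 summary = summ, spec = spec, cv = cv,
                 eval_n = length(eval_idx), train_on = train_on,
                 prevalence = baseline, n_redraws = n_redraws),
            class = "cv_result")
}

#' Pooled performance curves from a cross-validation result
#'
#' Builds the displayed ROC or PRC from held-out predictions pooled over
#' all repetitions.
#'
#' @param result a `cv_result` from a classification run.
#' @param type `"roc"` or `"prc"`.
#' @return A `perf_curve`.
#' @export
cv_curve <- function(result, type = c("roc", "prc")) {
  type <- match.arg(type)
  stopifnot(inherits(result, "cv_result"))
  if (result$spec$task != "classify")
    stop("curves are defined for classification results")
  sc <- as.vector(result$scores)
  y <- rep(result$truth, times = ncol(result$scores))
  if (type == "roc") roc_with_auc(sc, y) else prc_with_auc(sc, y)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: model '%s' (%s), %d-fold x %d repetitions, n = %d%s\n",
              x$spec$label, x$spec$task, x$cv$k, x$cv$repeats, x$eval_n,
              if (x$n_redraws) sprintf(" [%d repetition redraw(s)]",
                                       x$n_redraws) else ""))
  for (m in setdiff(names(x$metrics), "repetition")) {
    s <- x$summary[[m]]
    cat(sprintf("  %-7s mean %.4f (sd %.4f, 95%% CI %.4f-%.4f)\n", m,
                s[["mean"]], s[["sd"]], s[["2.5%"]], s[["97.5%"]]))
  }
  if (x$spec$task == "classify")
    cat(sprintf("  prevalence (AUPRC baseline) %.4f; AUPRC - baseline = %.4f\n",
                x$prevalence, x$summary$auprc[["mean"]] - x$prevalence))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  print(object)
  invisible(object$summary)
}

#' @export
plot.cv_result <- function(x, metric = NULL, ...) {
  metric <- metric %||% setdiff(names(x$metrics), "repetition")[
    if (x$spec$task == "classify") 2 else 1]
  graphics::boxplot(x$metrics[[metric]], ylab = metric,
                    main = sprintf("%s over %d repetitions", metric,
                                   x$cv$repeats), ...)
  if (metric == "auprc") graphics::abline(h = x$prevalence, lty = 3)
  if (metric == "auroc") graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
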