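#' Model specification
#'
#' Declares the predictors and preprocessing of an activity model. Named
#' presets expand deterministically to feature-table columns:
#'
#' * `"ATAC"` — `ATAC_sum`
#' * `"dREG"` — `dREG_sum` (PRO-seq reads at TRE predictions)
#' * `"ATAC+dREG"` — both sum features
#' * `"PolII"` — `PolII_sum`
#' * `"All"` — sum and max of all three assays with pairwise interactions
#' * `"dREG-max"` — `dREG_max` (sum of summit values at TRE predictions)
#' * `"ATAC*dREG"` — the quantitative-activity model: `ATAC_sum` main
#'   effect plus the `ATAC_sum:dREG_sum` product, without the `dREG` main
#'   effect (set `hierarchical = TRUE` for the conventional variant with
#'   both main effects).
#'
#' @param preset one of the preset names above, or `NULL` to give
#'   `predictors` explicitly.
#' @param predictors character vector of feature-table column names.
#' @param interactions `"none"`, `"pairwise"` (all second-order products),
#'   or a list of character pairs of column names.
#' @param transform `"log1p"` (default; the features span orders of
#'   magnitude) or `"raw"`.
#' @param standardize center/scale design columns using training-fold
#'   statistics (default `TRUE`).
#' @param ridge L2 penalty for the logistic fit; the near-zero default
#'   keeps estimates finite under quasi-separation in small folds.
#' @param task `"classify"` (logistic, on activity labels) or `"regress"`
#'   (ordinary least squares, on reporter expression).
#' @param hierarchical for `"ATAC*dREG"`: include the dREG main effect.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(preset = NULL, predictors = NULL,
                       interactions = "none", transform = c("log1p", "raw"),
                       standardize = TRUE, ridge = 1e-6,
                       task = c("classify", "regress"),
                       hierarchical = FALSE) {
  transform <- match.arg(transform)
  task <- match.arg(task)
  all6 <- paste(rep(c("ATAC", "dREG", "PolII"), each = 2),
                c("sum", "max"), sep = "_")
  label <- preset
  if (!is.null(preset)) {
    if (!is.null(predictors))
      stop("give either a preset or explicit predictors, not both")
    switch(preset,
      "ATAC" = { predictors <- "ATAC_sum" },
      "dREG" = { predictors <- "dREG_sum" },
      "ATAC+dREG" = { predictors <- c("ATAC_sum", "dREG_sum") },
      "PolII" = { predictors <- "PolII_sum" },
      "All" = { predictors <- all6; interactions <- "pairwise" },
      "dREG-max" = { predictors <- "dREG_max" },
      "ATAC*dREG" = {
        predictors <- if (hierarchical) c("ATAC_sum", "dREG_sum") else "ATAC_sum"
        interactions <- list(c("ATAC_sum", "dREG_sum"))
      },
      stop("unknown model preset: ", preset)
    )
  }
  if (is.null(predictors) || !length(predictors))
    stop("predictors must be non-empty")
  if (is.null(label))
    label <- paste(predictors, collapse = "+")
  stopifnot(is.numeric(ridge), ridge >= 0)
  structure(list(label = label, predictors = predictors,
                 interactions = interactions, transform = transform,
                 standardize = standardize, ridge = ridge, task = task),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s' (%s): %s; transform=%s, standardize=%s, ridge=%g\n",
              x$label, x$task, paste(x$predictors, collapse = ", "),
              x$transform, x$standardize, x$ridge))
  invisible(x)
}

interaction_pairs <- function(spec) {
  base <- unique(c(spec$predictors, if (is.list(spec$interactions))
    unlist(spec$interactions)))
  if (identical(spec$interactions, "none")) return(list())
  if (identical(spec$interactions, "pairwise")) {
    if (length(spec$predictors) < 2) return(list())
    cmb <- utils::combn(spec$predictors, 2, simplify = FALSE)
    return(cmb)
  }
  stopifnot(is.list(spec$interactions))
  spec$interactions
}

#' Build a design matrix from a feature table
#'
#' Extracts the spec's predictor columns, applies the transform, optionally
#' centers and scales using supplied (training) statistics, and appends
#' interaction products of the transformed columns in a deterministic
#' order.
#'
#' @param table a feature table ([build_features()] output or any data
#'   frame with the required columns).
#' @param spec a [model_spec].
#' @param params optional list with `center` and `scale` vectors learned on
#'   training data; when `NULL` they are computed from `table`.
#' @return A list with `X` (the design matrix, named columns), `center`
#'   and `scale` (the standardization parameters used, `NULL` when
#'   `standardize = FALSE`).
#' @export
design_matrix <- function(table, spec, params = NULL) {
  pairs <- interaction_pairs(spec)
  base_cols <- unique(c(spec$predictors, unlist(pairs)))
  miss <- setdiff(base_cols, names(table))
  if (length(miss)) stop("unknown predictor column(s): ",
                         paste(miss, collapse = ", "))
  B <- as.matrix(as.data.frame(table)[, base_cols, drop = FALSE])
  storage.mode(B) <- "double"
  if (spec$transform == "log1p") B <- log1p(B)
  center <- scale_ <- NULL
  if (spec$standardize) {
    if (is.null(params)) {
      center <- colMeans(B)
      scale_ <- apply(B, 2, stats::sd)
      scale_[scale_ == 0 | is.na(scale_)] <- 1
    } else {
      center <- params$center
      scale_ <- params$scale
    }
    B <- sweep(sweep(B, 2, center[base_cols]), 2, scale_[base_cols], "/")
  }
  X <- B[, spec$predictors, drop = FALSE]
  for (p in pairs) {
    X <- cbind(X, B[, p[1]] * B[, p[2]])
    colnames(X)[ncol(X)] <- paste(p, collapse = ":")
  }
  list(X = X, center = center, scale = scale_)
}

condition_single_class <- function(msg) {
  structure(class = c("crmpred_single_class", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Penalized logistic regression by iteratively reweighted least squares
#'
#' Maximizes the Bernoulli log-likelihood with logit link minus
#' `lambda/2 * ||beta||^2` on the non-intercept coefficients. Convergence
#' is declared when the relative change in the penalized log-likelihood
#' falls below `tol` (default 1e-10) or after `max_iter` iterations
#' (non-convergence raises a warning; the fit is retained).
#'
#' @param X design matrix (no intercept column; one is added internally).
#' @param y logical or 0/1 labels; both classes must be present.
#' @param lambda ridge penalty (`>= 0`).
#' @param max_iter,tol IRLS controls.
#' @return A list with `coefficients` (intercept first), `loglik`,
#'   `converged`, `iterations`.
#' @export
fit_logistic <- function(X, y, lambda = 1e-6, max_iter = 100, tol = 1e-10) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    stop(condition_single_class("training labels contain a single class"))
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- c(stats::qlogis(mean(y)), rep(0, p - 1))
  pll <- function(b) {
    eta <- drop(X1 %*% b)
    # numerically stable log(1 + exp(eta))
    lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    sum(y * eta - lse) - lambda / 2 * sum(b[-1]^2)
  }
  ll_old <- pll(beta)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X1 * w)
    beta_new <- tryCatch(
      solve(XtW %*% X1 + pen, XtW %*% z),
      error = function(e) stop("IRLS failed: singular weighted system")
    )
    beta_new <- drop(beta_new)
    ll_new <- pll(beta_new)
    ## step-halve if the penalized likelihood decreases
    step <- 1
    while (ll_new < ll_old && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      ll_new <- pll(beta_new)
    }
    beta <- beta_new
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  if (!converged) warning("IRLS did not converge in ", max_iter, " iterations")
  names(beta) <- colnames(X1)
  list(coefficients = beta, loglik = ll_old, converged = converged,
       iterations = iter)
}

#' Ordinary least squares
#'
#' QR-based least squares; under rank deficiency a warning is issued and
#' the minimum-norm solution (SVD pseudo-inverse) is returned.
#'
#' @param X design matrix (no intercept column; one is added internally).
#' @param y numeric response; needs `length(y) > ncol(X) + 1`.
#' @return A list with `coefficients` (intercept first), `fitted`,
#'   `residuals`.
#' @export
fit_linear <- function(X, y) {
  X1 <- cbind(`(Intercept)` = 1, X)
  if (length(y) <= ncol(X1) - 1)
    stop("need more observations than predictors")
  qr_ <- qr(X1)
  if (qr_$rank < ncol(X1)) {
    warning("rank-deficient design; using minimum-norm (pseudo-inverse) solution")
    sv <- svd(X1)
    pos <- sv$d > max(dim(X1)) * .Machine$double.eps * sv$d[1]
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qr_, y)
  }
  names(beta) <- colnames(X1)
  fitted <- drop(X1 %*% beta)
  list(coefficients = beta, fitted = fitted, residuals = y - fitted)
}

#' Fit an enhancer-activity model
#'
#' The single fitting entry point: builds the design matrix from a feature
#' table per the model spec (transform and standardization statistics are
#' learned from this table, i.e. the training data) and fits either the
#' penalized logistic classifier of activity labels or the least-squares
#' regressor of reporter expression.
#'
#' @param table feature table with the spec's predictor columns plus
#'   `active` (classify) or `expr` (regress).
#' @param spec a [model_spec].
#' @param y optional response override (activity labels or expression).
#' @return An object of class `crm_fit` with `print`, `summary`, `coef`,
#'   `predict`, `fitted` and `residuals` methods.
#' @examples
#' tab <- data.frame(ATAC_sum = c(0, 1, 2, 5, 9, 20),
#'                   active = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
#' fit <- crm_model(tab, model_spec("ATAC"))
#' predict(fit, tab)
#' @export
crm_model <- function(table, spec, y = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  dm <- design_matrix(table, spec)
  if (is.null(y))
    y <- if (spec$task == "classify") table$active else table$expr
  if (is.null(y))
    stop("response column ('active' or 'expr') not found in table")
  fit <- if (spec$task == "classify")
    fit_logistic(dm$X, y, lambda = spec$ridge)
  else fit_linear(dm$X, y)
  structure(list(spec = spec, coefficients = fit$coefficients,
                 center = dm$center, scale = dm$scale, fit = fit,
                 y = as.numeric(y), n = nrow(dm$X)),
            class = c(if (spec$task == "classify") "crm_logit" else "crm_ols",
                      "crm_fit"))
}

#' @export
coef.crm_fit <- function(object, ...) object$coefficients

#' Predict from a fitted activity model
#'
#' Applies the stored transform and training-fold standardization, then
#' the linear predictor; classification fits return probabilities in
#' (0, 1), regression fits return expression in basal-promoter units.
#' Prediction is a pure function of the feature row and the fitted
#' parameters.
#'
#' @param object a `crm_fit`.
#' @param newdata feature table containing the required columns.
#' @param ... unused.
#' @return Numeric vector of scores.
#' @export
predict.crm_fit <- function(object, newdata, ...) {
  dm <- design_matrix(newdata, object$spec,
                      params = list(center = object$center,
                                    scale = object$scale))
  eta <- drop(cbind(1, dm$X) %*% object$coefficients)
  if (object$spec$task == "classify") stats::plogis(eta) else eta
}

#' @export
fitted.crm_fit <- function(object, ...) {
  if (inherits(object, "crm_ols")) object$fit$fitted
  else stop("use predict() on the training table for logistic fits")
}

#' @export
residuals.crm_fit <- function(object, ...) {
  if (inherits(object, "crm_ols")) object$fit$residuals
  else stop("residuals are defined for regression fits")
}

#' @export
print.crm_fit <- function(x, ...) {
  cat(sprintf("crm_fit (%s, model '%s', n = %d)\ncoefficients:\n",
              x$spec$task, x$spec$label, x$n))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
summary.crm_fit <- function(object, ...) {
  cat(sprintf("Enhancer-activity %s model '%s'\n",
              if (object$spec$task == "classify") "classification"
              else "regression", object$spec$label))
  cat(sprintf("  n = %d, transform = %s, standardize = %s\n", object$n,
              object$spec$transform, object$spec$standardize))
  if (inherits(object, "crm_logit"))
    cat(sprintf("  penalized log-likelihood = %.4f (converged: %s)\n",
                object$fit$loglik, object$fit$converged))
  else
    cat(sprintf("  residual SD = %.4f\n", stats::sd(object$fit$residuals)))
  print(round(object$coefficients, 6))
  invisible(object)
}
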