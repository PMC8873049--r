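#' Regression problem container
#'
#' Bundles the design matrix, response and feature names for the base
#' learners, together with the standardization statistics used by the
#' penalized fits (per-feature mean and scale, response mean). Penalties are
#' scale-sensitive, so features are z-scored and the response centered
#' before fitting; coefficients are reported back on the original scale with
#' an unpenalized intercept.
#'
#' @param x numeric matrix or data.frame of features (no missing values).
#' @param y numeric response.
#' @return list of class `regression_problem`.
#' @export
regression_problem <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y disagree in length")
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in the regression problem")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1          # constant feature: kept, coefficient will be 0
  structure(list(x = x, y = y, names = colnames(x),
                 center = ctr, scale = scl, y_center = mean(y)),
            class = "regression_problem")
}

standardized <- function(problem) {
  xs <- sweep(sweep(problem$x, 2, problem$center), 2, problem$scale, "/")
  list(x = xs, y = problem$y - problem$y_center)
}

#' Fit a linear model with optional L1/L2 penalty
#'
#' Minimizes `sum((y_i - w'x_i)^2)` plus `lambda * ||w||_2^2` (ridge) or
#' `lambda * ||w||_1` (lasso) — the raw, un-normalized objective with no
#' `1/m` factor — on standardized features with an unpenalized intercept.
#' Ridge is solved through the SVD of the standardized design; lasso by
#' cyclic coordinate descent with soft-thresholding at `lambda / 2`.
#'
#' @param problem a [regression_problem()].
#' @param penalty `"none"`, `"L2"` or `"L1"`.
#' @param lambda non-negative penalty weight (`lambda = 0` reduces any
#'   penalty to ordinary least squares).
#' @param standardize fit on z-scored features and centered response with an
#'   unpenalized intercept (default, appropriate for covariates on mixed
#'   scales); `FALSE` fits the raw objective verbatim with zero intercept.
#' @return `fitted_model` with fields `kind`, `coefficients` (original
#'   scale), `intercept`, `lambda`.
#' @export
fit_linear <- function(problem, penalty = c("none", "L2", "L1"), lambda = 0,
                       standardize = TRUE) {
  penalty <- match.arg(penalty)
  stopifnot(length(lambda) == 1L, is.finite(lambda), lambda >= 0)
  s <- if (standardize) standardized(problem) else
    list(x = problem$x, y = problem$y)
  w <- if (penalty == "L2" && lambda > 0) {
    sv <- svd(s$x)
    keep <- sv$d > max(sv$d) * 1e-12
    as.numeric(sv$v[, keep, drop = FALSE] %*%
      ((sv$d[keep] / (sv$d[keep]^2 + lambda)) *
         crossprod(sv$u[, keep, drop = FALSE], s$y)))
  } else if (penalty == "L1" && lambda > 0) {
    lasso_cd(s$x, s$y, lambda)
  } else {
    ols_fit(s$x, s$y)
  }
  if (standardize) {
    coef <- w / problem$scale
    intercept <- problem$y_center - sum(coef * problem$center)
  } else {
    coef <- w
    intercept <- 0
  }
  structure(list(kind = switch(penalty, none = "ols", L2 = "ridge",
                               L1 = "lasso"),
                 coefficients = stats::setNames(coef, problem$names),
                 intercept = intercept, lambda = lambda,
                 features = problem$names),
            class = "fitted_model")
}

ols_fit <- function(x, y) {
  fit <- stats::lm.fit(x, y)
  co <- fit$coefficients
  co[is.na(co)] <- 0          # rank deficiency: redundant columns get 0
  as.numeric(co)
}

# Cyclic coordinate descent for min ||y - Xw||^2 + lambda ||w||_1 in
# covariance form (updates cost O(d) independent of m). Stationarity per
# coordinate soft-thresholds the partial-residual correlation at lambda/2
# (the objective carries no 1/2 on the quadratic term). `w0` warm-starts
# the path solver below.
lasso_cd <- function(x, y, lambda, tol = 1e-10, max_sweeps = 5000L,
                     w0 = NULL, xtx = NULL, xty = NULL) {
  d <- ncol(x)
  if (is.null(xtx)) xtx <- crossprod(x)
  if (is.null(xty)) xty <- as.numeric(crossprod(x, y))
  dg <- diag(xtx)
  w <- if (is.null(w0)) numeric(d) else w0
  sweep_set <- function(idx, w) {
    ch <- 0
    for (j in idx) {
      if (dg[j] == 0) next
      rho <- xty[j] - sum(xtx[j, ] * w) + dg[j] * w[j]
      wj <- sign(rho) * max(abs(rho) - lambda / 2, 0) / dg[j]
      if (wj != w[j]) {
        ch <- max(ch, abs(wj - w[j]))
        w[j] <- wj
      }
    }
    list(w = w, change = ch)
  }
  all_idx <- seq_len(d)
  s_used <- 0L
  repeat {
    full <- sweep_set(all_idx, w)   # full sweep refreshes the active set
    w <- full$w
    s_used <- s_used + 1L
    if (full$change < tol * max(1, max(abs(w))) || s_used >= max_sweeps)
      break
    active <- which(w != 0)
    while (length(active) && s_used < max_sweeps) {
      as <- sweep_set(active, w)
      w <- as$w
      s_used <- s_used + 1L
      if (as$change < tol * max(1, max(abs(w)))) break
    }
  }
  w
}

# Coefficient paths over a lambda grid on standardized data, one column per
# lambda. Ridge reuses one SVD across the grid; lasso warm-starts from the
# most regularized end. Coefficients returned on the original scale with
# intercepts.
linear_path <- function(problem, penalty, lambdas) {
  s <- standardized(problem)
  d <- ncol(s$x)
  nl <- length(lambdas)
  W <- matrix(0, d, nl)
  if (penalty == "L2") {
    sv <- svd(s$x)
    keep <- sv$d > max(sv$d) * 1e-12
    uy <- crossprod(sv$u[, keep, drop = FALSE], s$y)
    for (i in seq_len(nl))
      W[, i] <- sv$v[, keep, drop = FALSE] %*%
        ((sv$d[keep] / (sv$d[keep]^2 + lambdas[i])) * uy)
  } else {
    ord <- order(lambdas, decreasing = TRUE)
    xtx <- crossprod(s$x)
    xty <- as.numeric(crossprod(s$x, s$y))
    w <- numeric(d)
    for (i in ord) {
      # path solves feed cross-validation; a practical tolerance suffices
      w <- if (lambdas[i] > 0)
        lasso_cd(s$x, s$y, lambdas[i], tol = 1e-7, max_sweeps = 600L,
                 w0 = w, xtx = xtx, xty = xty)
      else ols_fit(s$x, s$y)
      W[, i] <- w
    }
  }
  coefs <- W / problem$scale
  intercepts <- problem$y_center - as.numeric(crossprod(coefs, problem$center))
  list(coefs = coefs, intercepts = intercepts)
}

#' Select the penalty weight by cross-validation
#'
#' K-fold cross-validation over a grid of `lambda` values; the winner
#' minimizes the mean held-out RMSE, with ties broken toward the larger
#' (more regularized) `lambda`.
#'
#' @param problem a [regression_problem()].
#' @param penalty `"L2"` or `"L1"`.
#' @param grid non-empty vector of candidate `lambda >= 0`.
#' @param folds number of folds (2..m).
#' @param seed integer seed for the fold assignment.
#' @return list: `lambda` (winner), `cv_rmse` (per grid point).
#' @export
select_lambda_cv <- function(problem, penalty, grid = default_lambda_grid(),
                             folds = 5, seed = 1) {
  if (!length(grid)) stop("empty lambda grid")
  m <- length(problem$y)
  if (folds < 2 || folds > m) stop("folds must be in [2, m]")
  fold_id <- cv_folds(m, folds, seed)
  grid <- sort(grid)
  se <- matrix(0, length(grid), folds)   # per-fold sum of squared errors
  nv <- integer(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    path <- linear_path(regression_problem(problem$x[tr, , drop = FALSE],
                                           problem$y[tr]), penalty, grid)
    pred <- problem$x[!tr, , drop = FALSE] %*% path$coefs
    pred <- sweep(pred, 2, path$intercepts, "+")
    se[, f] <- colSums((pred - problem$y[!tr])^2)
    nv[f] <- sum(!tr)
  }
  rmse <- rowMeans(sqrt(sweep(se, 2, nv, "/")))
  best <- max(which(rmse <= min(rmse) + 1e-12))   # ties -> larger lambda
  list(lambda = grid[best], cv_rmse = stats::setNames(rmse, grid))
}

#' @rdname select_lambda_cv
#' @export
default_lambda_grid <- function() 10^seq(-3, 3, length.out = 13)

cv_folds <- function(m, folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(folds), m))
}

#' Fit a tree ensemble with grid-searched hyperparameters
#'
#' Exhaustive grid search by K-fold cross-validated RMSE, then a final refit
#' on all data at the best grid point. `kind = "rf"` is bootstrap-aggregated
#' regression trees with per-split feature subsampling (randomForest);
#' `kind = "gbt"` is gradient-boosted additive trees with shrinkage and L2
#' leaf regularization (xgboost, single-threaded for determinism). Identical
#' seed and data give identical fits.
#'
#' @param problem a [regression_problem()].
#' @param kind `"rf"` or `"gbt"`.
#' @param param_grid data.frame of grid points (see [default_tree_grid()]),
#'   one row per candidate.
#' @param folds CV folds.
#' @param seed integer seed (folds, bootstrap, refit).
#' @return `fitted_model` with the chosen grid point in `$params`.
#' @export
fit_tree_ensemble <- function(problem, kind = c("rf", "gbt"),
                              param_grid = NULL, folds = 5, seed = 1) {
  kind <- match.arg(kind)
  m <- length(problem$y)
  if (m < folds) stop("fewer samples than folds")
  if (is.null(param_grid)) param_grid <- default_tree_grid(kind, ncol(problem$x))
  if (!nrow(param_grid)) stop("empty hyperparameter grid")
  fold_id <- cv_folds(m, folds, seed)
  per_fold <- vapply(seq_len(nrow(param_grid)), function(gi) {
    p <- param_grid[gi, , drop = FALSE]
    vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- tree_fit(problem$x[tr, , drop = FALSE], problem$y[tr], kind, p,
                      seed + f)
      pred <- tree_predict(fit, kind, problem$x[!tr, , drop = FALSE])
      sqrt(mean((pred - problem$y[!tr])^2))
    }, numeric(1))
  }, numeric(folds))
  cv <- colMeans(per_fold)
  # one-standard-error rule: among grid points within one SE of the CV
  # minimum, take the least complex (CV-RMSE at a few dozen samples is too
  # noisy to separate them, and the simpler model generalizes better)
  imin <- which.min(cv)
  se <- stats::sd(per_fold[, imin]) / sqrt(folds)
  cand <- which(cv <= cv[imin] + se)
  cx <- grid_complexity(kind, param_grid)
  best <- cand[order(cx[cand], cv[cand])][1]
  bp <- param_grid[best, , drop = FALSE]
  model <- tree_fit(problem$x, problem$y, kind, bp, seed)
  structure(list(kind = if (kind == "rf") "random_forest" else
                   "gradient_boosted_trees",
                 model = model, params = bp, cv_rmse = cv,
                 features = problem$names, seed = seed),
            class = "fitted_model")
}

#' Default hyperparameter grids for the tree ensembles
#'
#' Sized for small plot surveys (tens of samples): random forest varies the
#' per-split feature count and minimum leaf size at 300 trees; gradient
#' boosting crosses tree count, depth and learning rate.
#'
#' @param kind `"rf"` or `"gbt"`.
#' @param d number of features.
#' @return data.frame, one row per grid point.
#' @export
default_tree_grid <- function(kind, d) {
  if (kind == "rf")
    expand.grid(ntree = 300,
                mtry = unique(pmax(1, c(ceiling(d / 3), ceiling(sqrt(d))))),
                nodesize = c(4, 7))
  else
    expand.grid(nrounds = c(75, 150, 250), max_depth = c(2, 3),
                eta = c(0.05, 0.1), min_child_weight = 5)
}

# effective-capacity ordering used by the one-SE rule: for boosting the
# shrinkage budget times leaf count; for forests the inverse leaf size
grid_complexity <- function(kind, grid) {
  if (kind == "rf") (grid$mtry + 1) / grid$nodesize
  else grid$nrounds * grid$eta * (2^grid$max_depth) / grid$min_child_weight
}

tree_fit <- function(x, y, kind, p, seed) {
  set.seed(seed)
  if (kind == "rf") {
    randomForest::randomForest(x = x, y = y, ntree = p$ntree,
                               mtry = min(p$mtry, ncol(x)),
                               nodesize = p$nodesize)
  } else {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    mcw <- if (is.null(p$min_child_weight)) 1 else p$min_child_weight
    xgboost::xgb.train(params = list(max_depth = p$max_depth, eta = p$eta,
                                     lambda = 1, min_child_weight = mcw,
                                     objective = "reg:squarederror",
                                     nthread = 1, seed = seed),
                       data = dtrain, nrounds = p$nrounds, verbose = 0)
  }
}

tree_predict <- function(model, kind, x) {
  if (kind == "rf") as.numeric(stats::predict(model, x))
  else as.numeric(stats::predict(model,
                                 xgboost::xgb.DMatrix(x, nthread = 1)))
}

#' Predict from a fitted model
#'
#' @param object a `fitted_model`.
#' @param newdata matrix or data.frame with the model's feature columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(colnames(x))) {
    miss <- setdiff(object$features, colnames(x))
    if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
    x <- x[, object$features, drop = FALSE]
  } else if (ncol(x) != length(object$features)) {
    stop("newdata has ", ncol(x), " columns, model expects ",
         length(object$features))
  }
  storage.mode(x) <- "double"
  if (object$kind %in% c("ols", "ridge", "lasso"))
    as.numeric(x %*% object$coefficients + object$intercept)
  else if (object$kind == "random_forest")
    tree_predict(object$model, "rf", x)
  else
    tree_predict(object$model, "gbt", x)
}

#' Predict a surface from a band stack
#'
#' Applies a fitted model cell-by-cell over the feature layers of a stack.
#' Cells with nodata in any required layer are nodata in the output. This
#' surface is the fusion driver.
#'
#' @param model a `fitted_model`.
#' @param stack a [band_stack()] providing every model feature as a layer.
#' @return [grid_surface()] of predictions.
#' @export
predict_raster <- function(model, stack) {
  stopifnot(inherits(stack, "band_stack"))
  miss <- setdiff(model$features, stack_names(stack))
  if (length(miss)) stop("missing feature layer(s): ",
                         paste(miss, collapse = ", "))
  g <- stack[[1]]
  X <- vapply(model$features, function(nm) as.numeric(stack[[nm]]$values),
              numeric(length(g$values)))
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (any(ok))
    out[ok] <- predict(model, X[ok, , drop = FALSE])
  grid_surface(matrix(out, nrow(g$values), ncol(g$values)),
               g$cellsize, g$xll, g$yll)
}
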