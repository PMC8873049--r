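#' Method identifiers
#'
#' The eight method variants compared by the package: each of the four base
#' learners, plain and fused with HASM.
#' @return character vector of the eight method ids.
#' @export
method_ids <- function() {
  base <- c("lasso", "ridge", "xgboost", "random_forest")
  c(base, paste0("hasm_", base))
}

base_learner_of <- function(method) sub("^hasm_", "", method)
is_hasm_method <- function(method) grepl("^hasm_", method)

#' Residual constraints at sample plots
#'
#' Computes the observed-minus-predicted residual of a driver surface at
#' each plot, collapsing plots that share a grid cell to their mean, and
#' returns the residuals as sampling constraints on the residual field.
#'
#' @param driver prediction surface ([grid_surface()]).
#' @param plots data.frame with columns `plot_id`, `x`, `y`, and the
#'   observed value in `obs`.
#' @return a [constraint_set()] of residuals.
#' @export
residuals_at_samples <- function(driver, plots) {
  stopifnot(inherits(driver, "grid_surface"),
            all(c("plot_id", "x", "y", "obs") %in% names(plots)))
  rc <- xy_to_cell(driver, plots$x, plots$y)
  if (anyNA(rc$row))
    stop("plot(s) outside grid: ",
         paste(plots$plot_id[is.na(rc$row)], collapse = ", "))
  pred <- driver$values[cbind(rc$row, rc$col)]
  if (anyNA(pred))
    stop("driver is nodata at plot(s): ",
         paste(plots$plot_id[is.na(pred)], collapse = ", "))
  constraint_set(rc$row, rc$col, plots$obs - pred)
}

#' Inverse-distance-weighted surface from constraints
#'
#' Power-2 inverse-distance interpolation over all constraint points,
#' exact at the constraint cells; used as the initial surface handed to the
#' HASM iteration.
#'
#' @param constraints a [constraint_set()] (>= 1 row).
#' @param geometry target [grid_geometry()] (or a grid to copy it from).
#' @return [grid_surface()].
#' @export
idw_surface <- function(constraints, geometry) {
  if (!nrow(constraints)) stop("need at least one constraint")
  g <- geometry_of(geometry)
  cc <- cell_centers(g)
  px <- cc$x[constraints$col]
  py <- cc$y[constraints$row]
  X <- matrix(cc$x, g$nrow, g$ncol, byrow = TRUE)
  Y <- matrix(cc$y, g$nrow, g$ncol)
  num <- matrix(0, g$nrow, g$ncol); den <- matrix(0, g$nrow, g$ncol)
  for (j in seq_len(nrow(constraints))) {
    d2 <- (X - px[j])^2 + (Y - py[j])^2
    w <- 1 / pmax(d2, .Machine$double.eps)
    num <- num + w * constraints$value[j]
    den <- den + w
  }
  out <- num / den
  out[cbind(constraints$row, constraints$col)] <- constraints$value
  grid_surface(out, g$cellsize, g$xll, g$yll)
}

#' Fuse a driver surface with plot observations through HASM
#'
#' The headline operation: HASM integrates the extrinsic information of a
#' machine-learning prediction surface with the intrinsic information of the
#' field observations. In residual mode (default) the observed-minus-
#' predicted residuals become sampling constraints on a residual field,
#' HASM solves that field starting from its inverse-distance interpolation,
#' and the fused map is driver + residual surface. In direct mode HASM runs
#' on the driver itself with the raw observations as constraints. Either
#' way the fused surface honors every training observation at its cell to
#' solver tolerance.
#'
#' @param driver prediction surface.
#' @param plots data.frame with `plot_id`, `x`, `y`, `obs`.
#' @param hasm a [hasm_config()].
#' @param mode `"residual"` or `"direct"`.
#' @param clip_at optional lower bound applied to the returned map (e.g. 0
#'   for non-negative diversity indices); the raw surface is kept in
#'   attribute `raw`.
#' @return fused [grid_surface()] with attributes `raw` and `diagnostics`.
#' @export
hasm_fuse <- function(driver, plots, hasm = hasm_config(),
                      mode = c("residual", "direct"), clip_at = NULL) {
  mode <- match.arg(mode)
  if (mode == "residual") {
    cons <- residuals_at_samples(driver, plots)
    init <- idw_surface(cons, driver)
    init$values[is.na(driver$values)] <- NA_real_
    res <- hasm_iterate(init, cons, hasm)
    fused <- driver
    fused$values <- driver$values + res$values
    diagnostics <- attr(res, "diagnostics")
  } else {
    rc <- xy_to_cell(driver, plots$x, plots$y)
    if (anyNA(rc$row))
      stop("plot(s) outside grid: ",
           paste(plots$plot_id[is.na(rc$row)], collapse = ", "))
    cons <- constraint_set(rc$row, rc$col, plots$obs)
    fused <- hasm_iterate(driver, cons, hasm)
    diagnostics <- attr(fused, "diagnostics")
  }
  raw <- fused$values
  if (!is.null(clip_at)) fused$values <- pmax(fused$values, clip_at)
  attr(fused, "raw") <- raw
  attr(fused, "diagnostics") <- diagnostics
  fused
}

#' Run one of the eight mapping methods
#'
#' Dispatch for the comparative study: fit the base learner named by the
#' method id on the training plots, predict the full raster, and for
#' `hasm_*` variants fuse the prediction with the training observations.
#' Deterministic given the seed.
#'
#' @param method one of [method_ids()].
#' @param train data.frame of training plots: `plot_id`, `x`, `y`, `obs`,
#'   plus one column per feature.
#' @param stack a [band_stack()] of the feature layers.
#' @param features character vector naming the feature columns/layers.
#' @param config a [study_config()] (learner grids, folds, HASM settings).
#' @param seed integer seed.
#' @return fused or plain prediction [grid_surface()]; attribute `model`
#'   carries the fitted learner.
#' @export
run_method <- function(method, train, stack, features, config = study_config(),
                       seed = 1) {
  if (!method %in% method_ids()) stop("unknown method id: ", method)
  model <- fit_base_learner(base_learner_of(method), train, features, config,
                            seed)
  driver <- predict_raster(model, stack)
  out <- if (is_hasm_method(method))
    hasm_fuse(driver, train, hasm = config$hasm, mode = config$fusion_mode,
              clip_at = config$clip_at)
  else driver
  attr(out, "model") <- model
  out
}

fit_base_learner <- function(learner, train, features, config, seed) {
  x <- as.matrix(train[, features, drop = FALSE])
  problem <- regression_problem(x, train$obs)
  folds <- min(config$folds, nrow(x))
  switch(learner,
    lasso = {
      pr <- screened_problem(problem, config$collinearity_threshold)
      lam <- select_lambda_cv(pr, "L1", config$lambda_grid, folds, seed)$lambda
      fit_linear(pr, "L1", lam)
    },
    ridge = {
      pr <- screened_problem(problem, config$collinearity_threshold)
      lam <- select_lambda_cv(pr, "L2", config$lambda_grid, folds, seed)$lambda
      fit_linear(pr, "L2", lam)
    },
    xgboost = fit_tree_ensemble(problem, "gbt", config$gbt_grid, folds, seed),
    random_forest = fit_tree_ensemble(problem, "rf", config$rf_grid, folds,
                                      seed),
    stop("unknown learner: ", learner))
}

# collinearity screen applied to linear learners only (tree learners take
# the full feature set)
screened_problem <- function(problem, threshold) {
  if (is.null(threshold) || ncol(problem$x) < 2L) return(problem)
  df <- as.data.frame(problem$x)
  kept <- suppressWarnings(collinearity_screen(df, threshold))
  regression_problem(as.matrix(kept[, setdiff(names(kept), "complete"),
                                    drop = FALSE]), problem$y)
}

#' Study configuration
#'
#' Collects the tunable settings of the full mapping pipeline with defaults
#' matching the package's study design: 10 repeated 90/10 holdouts, 5-fold
#' hyperparameter CV, residual-mode fusion, and a collinearity screen
#' (|r| > 0.95) applied to the linear learners only.
#'
#' @param repeats holdout repeats.
#' @param train_fraction fraction of plots used for training in each repeat.
#' @param folds CV folds for hyperparameter selection.
#' @param lambda_grid candidate penalty weights for ridge/lasso.
#' @param rf_grid,gbt_grid tree hyperparameter grids (`NULL` = defaults
#'   from [default_tree_grid()]).
#' @param hasm a [hasm_config()].
#' @param fusion_mode `"residual"` or `"direct"`.
#' @param collinearity_threshold screen threshold for linear learners
#'   (`NULL` disables).
#' @param clip_at lower clip for fused maps (diversity indices are
#'   non-negative).
#' @param seed base seed; derived seeds stay below 2^31.
#' @return list of class `study_config`.
#' @export
study_config <- function(repeats = 10, train_fraction = 0.9, folds = 5,
                         lambda_grid = default_lambda_grid(),
                         rf_grid = NULL, gbt_grid = NULL,
                         hasm = hasm_config(), fusion_mode = "residual",
                         collinearity_threshold = 0.95, clip_at = 0,
                         seed = 1) {
  stopifnot(repeats >= 1, train_fraction > 0, train_fraction < 1, folds >= 2)
  structure(list(repeats = repeats, train_fraction = train_fraction,
                 folds = folds, lambda_grid = lambda_grid,
                 rf_grid = rf_grid, gbt_grid = gbt_grid, hasm = hasm,
                 fusion_mode = fusion_mode,
                 collinearity_threshold = collinearity_threshold,
                 clip_at = clip_at, seed = as.integer(seed)),
            class = "study_config")
}
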