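test_that("ridge matches the normal-equations closed form", {
  set.seed(41)
  x <- matrix(stats::rnorm(40 * 6), 40, 6)
  y <- stats::rnorm(40)
  prob <- regression_problem(x, y)
  for (lam in c(0.01, 1, 50)) {
    fit <- fit_linear(prob, "L2", lam)
    # independent oracle: dense normal equations on the standardized data
    xs <- scale(x)
    ys <- y - mean(y)
    w_std <- solve(crossprod(xs) + lam * diag(6), crossprod(xs, ys))
    w_orig <- as.numeric(w_std) / attr(xs, "scaled:scale")
    expect_equal(unname(fit$coefficients), w_orig, tolerance = 1e-8)
    expect_equal(fit$intercept,
                 mean(y) - sum(w_orig * attr(xs, "scaled:center")),
                 tolerance = 1e-8)
  }
  # identity design closed form w_i = y_i / (1 + lambda) on the raw objective
  raw <- fit_linear(regression_problem(diag(2), c(1, 2)), "L2", 1,
                    standardize = FALSE)
  expect_equal(unname(raw$coefficients), c(0.5, 1.0), tolerance = 1e-12)
})

test_that("lasso matches soft-thresholding on orthonormal designs", {
  raw <- fit_linear(regression_problem(diag(2), c(3, -0.5)), "L1", 1,
                    standardize = FALSE)
  expect_equal(unname(raw$coefficients), c(2.5, 0), tolerance = 1e-6)
  set.seed(42)
  for (i in 1:5) {
    d <- 6
    Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))  # orthonormal columns
    y <- stats::rnorm(d, sd = 2)
    lam <- stats::runif(1, 0.1, 2)
    fit <- fit_linear(regression_problem(Q, y), "L1", lam,
                      standardize = FALSE)
    z <- crossprod(Q, y)
    oracle <- sign(z) * pmax(abs(z) - lam / 2, 0)
    expect_equal(unname(fit$coefficients), as.numeric(oracle),
                 tolerance = 1e-6)
  }
})

test_that("lambda = 0 reduces both penalties to ordinary least squares", {
  set.seed(43)
  x <- matrix(stats::rnorm(30 * 4), 30, 4)
  y <- stats::rnorm(30)
  prob <- regression_problem(x, y)
  ols <- fit_linear(prob, "none")
  expect_equal(fit_linear(prob, "L2", 0)$coefficients, ols$coefficients,
               tolerance = 1e-10)
  expect_equal(fit_linear(prob, "L1", 0)$coefficients, ols$coefficients,
               tolerance = 1e-10)
  expect_error(fit_linear(regression_problem(x, c(y[-1], NA)), "none"),
               "non-finite")
})

test_that("lasso agrees with glmnet as an independent cross-check", {
  # glmnet minimizes RSS/(2m) + lambda_g * ||w||_1, so lambda_g = lambda/(2m)
  set.seed(44)
  m <- 50; d <- 8
  x <- matrix(stats::rnorm(m * d), m, d)
  y <- x[, 1] - 2 * x[, 3] + stats::rnorm(m)
  lam <- 8
  mine <- fit_linear(regression_problem(x, y), "L1", lam,
                     standardize = FALSE)
  gl <- glmnet::glmnet(x, y, lambda = lam / (2 * m), standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  expect_equal(unname(mine$coefficients),
               as.numeric(gl$beta), tolerance = 1e-4)
})

test_that("the L1 coefficient norm is non-increasing in lambda", {
  set.seed(45)
  x <- matrix(stats::rnorm(40 * 7), 40, 7)
  y <- x %*% stats::rnorm(7) + stats::rnorm(40)
  prob <- regression_problem(x, y)
  norms <- vapply(default_lambda_grid(), function(l)
    sum(abs(fit_linear(prob, "L1", l)$coefficients *
              prob$scale)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("cross-validated lambda selection behaves at the extremes", {
  set.seed(46)
  x <- matrix(stats::rnorm(30 * 4), 30, 4)
  beta <- c(2, -1, 0.5, 0)
  prob_exact <- regression_problem(x, as.numeric(x %*% beta))
  expect_equal(select_lambda_cv(prob_exact, "L2", grid = 0, folds = 5)$lambda,
               0)
  sel <- select_lambda_cv(prob_exact, "L2", grid = c(0, 1, 10), folds = 5,
                          seed = 2)
  expect_lt(sel$cv_rmse[["0"]], 1e-8)      # noiseless linear: zero CV error
  expect_equal(sel$lambda, 0)
  expect_error(select_lambda_cv(prob_exact, "L2", grid = c(0, 1), folds = 40),
               "folds")
  # pure-noise response: heavy regularization wins most seeds
  grid <- default_lambda_grid()
  top <- vapply(1:10, function(s) {
    set.seed(s + 100)
    xn <- matrix(stats::rnorm(36 * 5), 36, 5)
    yn <- stats::rnorm(36)
    sel <- select_lambda_cv(regression_problem(xn, yn), "L2", grid,
                            folds = 5, seed = s)
    sel$lambda >= grid[9]
  }, logical(1))
  expect_gte(sum(top), 8)
})

test_that("tree ensembles fit constants, steps, and are deterministic", {
  set.seed(47)
  x <- matrix(stats::rnorm(40 * 3), 40, 3)
  const <- regression_problem(x, rep(2.5, 40))
  for (kind in c("rf", "gbt")) {
    # randomForest warns about few unique response values; irrelevant here
    fit <- suppressWarnings(fit_tree_ensemble(const, kind, folds = 5,
                                              seed = 1))
    expect_equal(unname(predict(fit, x)), rep(2.5, 40), tolerance = 1e-6)
  }
  # step response: boosting with enough capacity drives training error to ~0
  ystep <- ifelse(x[, 2] > 0, 4, -1)
  stepg <- expand.grid(nrounds = 400, max_depth = 3, eta = 0.3,
                       min_child_weight = 1)
  fit <- suppressWarnings(fit_tree_ensemble(regression_problem(x, ystep),
                                            "gbt", param_grid = stepg,
                                            folds = 5, seed = 1))
  expect_lt(sqrt(mean((predict(fit, x) - ystep)^2)), 0.05)
  expect_error(fit_tree_ensemble(const, "rf",
                                 param_grid = data.frame()[0, ]), "grid")
  # determinism: same seed, same data -> identical predictions
  prob <- regression_problem(x, as.numeric(x %*% c(1, -1, 2)) +
                               stats::rnorm(40, sd = 0.3))
  f1 <- fit_tree_ensemble(prob, "rf", folds = 5, seed = 9)
  f2 <- fit_tree_ensemble(prob, "rf", folds = 5, seed = 9)
  expect_identical(predict(f1, x), predict(f2, x))
  g1 <- fit_tree_ensemble(prob, "gbt", folds = 5, seed = 9)
  g2 <- fit_tree_ensemble(prob, "gbt", folds = 5, seed = 9)
  expect_identical(predict(g1, x), predict(g2, x))
})

test_that("tree ensembles out-fit OLS on nonlinear responses", {
  wins <- vapply(1:10, function(s) {
    set.seed(s + 200)
    x <- matrix(stats::rnorm(45 * 4), 45, 4)
    y <- 3 * sin(2 * x[, 1]) + 2 * (x[, 2] > 0.5) * x[, 3] +
      stats::rnorm(45, sd = 0.2)
    prob <- regression_problem(x, y)
    ols_rmse <- sqrt(mean((predict(fit_linear(prob, "none"), x) - y)^2))
    grid <- expand.grid(nrounds = 300, max_depth = 3, eta = 0.2,
                        min_child_weight = 1)
    gbt_rmse <- sqrt(mean((predict(
      fit_tree_ensemble(prob, "gbt", grid, folds = 5, seed = s), x) - y)^2))
    gbt_rmse <= ols_rmse
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("raster prediction matches tabular prediction and handles nodata", {
  n <- 6
  set.seed(48)
  l1 <- grid_surface(matrix(stats::rnorm(n * n), n, n), 30)
  l2 <- grid_surface(matrix(stats::rnorm(n * n), n, n), 30)
  st <- band_stack(list(a = l1, b = l2))
  model <- structure(list(kind = "ols", coefficients = c(a = 1, b = 0),
                          intercept = 0, features = c("a", "b")),
                     class = "fitted_model")
  out <- predict_raster(model, st)
  expect_equal(out$values, l1$values)

  cst <- band_stack(list(a = grid_surface(matrix(2, n, n), 30),
                         b = grid_surface(matrix(3, n, n), 30)))
  model2 <- structure(list(kind = "ols", coefficients = c(a = 1, b = 2),
                           intercept = 1, features = c("a", "b")),
                      class = "fitted_model")
  expect_true(all(predict_raster(model2, cst)$values == 9))

  l1na <- l1; l1na$values[2, 2] <- NA
  stna <- band_stack(list(a = l1na, b = l2))
  expect_true(is.na(predict_raster(model, stna)$values[2, 2]))
  expect_error(predict_raster(model, st["a"]), "missing feature")

  # consistency: raster predictions at plot cells equal tabular predictions
  plots <- data.frame(plot_id = 1:3, x = c(15, 75, 135), y = c(15, 75, 135))
  ft <- extract_at_plots(st, plots)
  rc <- xy_to_cell(st[[1]], plots$x, plots$y)
  expect_equal(out$values[cbind(rc$row, rc$col)],
               predict(model, ft[, c("a", "b")]))
})
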