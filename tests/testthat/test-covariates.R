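test_that("vegetation indices match direct band arithmetic", {
  vi <- vegetation_indices(tiny_bands())
  at <- function(l) vi[[l]]$values[3, 3]
  expect_equal(at("NDVI"), 0.6)
  expect_equal(at("SRI"), 4.0)
  expect_equal(at("DVI"), 0.3)
  expect_equal(at("NDWI"), (0.4 - 0.2) / (0.4 + 0.2))
  expect_equal(at("CRI"), 1 / 0.05 - 1 / 0.08)
  # EVI with the standard coefficients G=2.5, C1=6, C2=7.5, L=1
  expect_equal(at("EVI"), 2.5 * 0.3 / (0.4 + 6 * 0.1 - 7.5 * 0.05 + 1),
               tolerance = 1e-12)
  expect_equal(at("EVI"), 0.75 / 1.625, tolerance = 1e-12)

  eq <- vegetation_indices(tiny_bands(nir = 0.2, red = 0.2))
  expect_equal(eq[["NDVI"]]$values[2, 2], 0)
  expect_equal(eq[["DVI"]]$values[2, 2], 0)
  expect_equal(eq[["SRI"]]$values[2, 2], 1)

  zero <- vegetation_indices(tiny_bands(nir = 0, red = 0))
  expect_true(is.na(zero[["NDVI"]]$values[1, 1]))   # zero denominator

  expect_error(vegetation_indices(tiny_bands()[c("red", "NIR")]), "missing")
})

test_that("NDVI and NDWI stay in [-1, 1] for random reflectances", {
  set.seed(21)
  n <- 8
  mk <- function() grid_surface(matrix(stats::runif(n * n, 0.01, 1), n, n), 30)
  st <- band_stack(list(blue = mk(), green = mk(), red = mk(), NIR = mk(),
                        SWIR1 = mk()))
  vi <- vegetation_indices(st)
  expect_true(all(abs(vi[["NDVI"]]$values) <= 1))
  expect_true(all(abs(vi[["NDWI"]]$values) <= 1))
})

test_that("max-NDVI compositing picks all bands from the greenest scene", {
  n <- 3
  mk <- function(nir, red) {
    g <- function(v) grid_surface(matrix(v, n, n), 30)
    band_stack(list(blue = g(0.05), green = g(0.08), red = g(red),
                    NIR = g(nir), SWIR1 = g(0.2)))
  }
  s1 <- mk(0.24, 0.16)   # NDVI 0.2
  s2 <- mk(0.30, 0.10)   # NDVI 0.5
  comp <- max_ndvi_composite(list(s1, s2))
  expect_equal(comp[["NIR"]]$values, s2[["NIR"]]$values)
  expect_equal(comp[["red"]]$values, s2[["red"]]$values)
  # single scene is the identity
  expect_equal(max_ndvi_composite(list(s1))[["NIR"]]$values,
               s1[["NIR"]]$values)
  # nodata in the greener scene falls back to the other one
  s2b <- s2; s2b$NIR$values[1, 1] <- NA; s2b$red$values[1, 1] <- NA
  comp2 <- max_ndvi_composite(list(s2b, s1))
  expect_equal(comp2[["NIR"]]$values[1, 1], 0.24)
  expect_equal(comp2[["NIR"]]$values[2, 2], 0.30)
  # composited NDVI equals the per-cell max over scenes
  set.seed(9)
  rmk <- function() {
    g <- function() grid_surface(matrix(stats::runif(n * n, .01, .9), n, n), 30)
    band_stack(list(blue = g(), green = g(), red = g(), NIR = g(),
                    SWIR1 = g()))
  }
  scenes <- list(rmk(), rmk(), rmk())
  nd <- function(s) (s[["NIR"]]$values - s[["red"]]$values) /
    (s[["NIR"]]$values + s[["red"]]$values)
  comp3 <- max_ndvi_composite(scenes)
  expect_equal(nd(comp3), pmax(nd(scenes[[1]]), nd(scenes[[2]]),
                               nd(scenes[[3]])))
})

test_that("terrain derivatives follow Horn and Zevenbergen-Thorne", {
  flat <- grid_surface(matrix(5, 6, 6), 10)
  tf <- terrain_derivatives(flat)
  inner <- tf[["slope"]]$values[2:5, 2:5]
  expect_true(all(inner == 0))
  expect_true(all(is.na(tf[["aspect"]]$values)))
  expect_true(all(tf[["plan_curvature"]]$values[2:5, 2:5] == 0))

  # east-rising ramp f = x with unit cells: slope 45 deg, aspect west (270)
  n <- 7
  ramp <- grid_surface(matrix(rep(1:n, each = n), n, n), 1)
  tr <- terrain_derivatives(ramp)
  expect_equal(tr[["slope"]]$values[4, 4], 45)
  expect_equal(tr[["aspect"]]$values[4, 4], 270)
  expect_equal(tr[["plan_curvature"]]$values[4, 4], 0)
  expect_equal(tr[["profile_curvature"]]$values[4, 4], 0)
  # boundary ring is nodata
  expect_true(all(is.na(tr[["slope"]]$values[1, ])))
  expect_error(terrain_derivatives(grid_surface(matrix(0, 2, 2), 1)), "3x3")
})

test_that("bilinear resampling is exact on constants and linear ramps", {
  src <- analytic_test_surface("plane", grid_geometry(10, 10, 2),
                               list(a = 1.5, b = -0.5, c = 3))
  same <- resample_to_grid(src, geometry_of(src))
  expect_equal(same$values, src$values, tolerance = 1e-12)

  const <- grid_surface(matrix(4, 6, 6), 3)
  up <- resample_to_grid(const, grid_geometry(9, 9, 2, xll = 1, yll = 1))
  expect_true(all(up$values == 4))

  # 2x upsampling of a linear field reproduces the field at new centers
  fine <- grid_geometry(18, 18, 1, xll = 0.5, yll = 0.5)
  expect_equal(resample_to_grid(src, fine)$values,
               analytic_test_surface("plane", fine,
                                     list(a = 1.5, b = -0.5, c = 3))$values,
               tolerance = 1e-10)

  far <- grid_geometry(4, 4, 1, xll = 1e6, yll = 1e6)
  expect_error(resample_to_grid(src, far), "overlap")
})

test_that("plot extraction uses the half-open cell convention", {
  n <- 4
  vals <- matrix(seq_len(n * n), n, n)
  st <- band_stack(list(layer = grid_surface(vals, 10)))
  # cell (row 4, col 1) covers [0,10) x [0,10): its center is (5,5)
  plots <- data.frame(plot_id = c("a", "b", "c"), x = c(5, 5, 10),
                      y = c(5, 5, 10))
  ft <- extract_at_plots(st, plots)
  expect_equal(ft$layer[1], vals[4, 1])
  expect_identical(ft$layer[1], ft$layer[2])    # same cell, same features
  # boundary point (10,10) belongs to the cell east/north of the edge
  expect_equal(ft$layer[3], vals[3, 2])
  outside <- data.frame(plot_id = "z", x = -1, y = 5)
  expect_error(extract_at_plots(st, outside), "z")
})

test_that("collinearity screen drops later correlated columns greedily", {
  set.seed(31)
  x1 <- stats::rnorm(200)
  x2 <- 0.99 * x1 + sqrt(1 - 0.99^2) * stats::rnorm(200)   # r ~ 0.99
  x3 <- 0.2 * x1 + sqrt(1 - 0.2^2) * stats::rnorm(200)     # r ~ 0.2
  tb <- data.frame(f1 = x1, f2 = x2, f3 = x3)
  out <- collinearity_screen(tb, threshold = 0.95)
  expect_named(out, c("f1", "f3"))
  expect_equal(attr(out, "dropped"), "f2")

  dup <- data.frame(a = x1, b = x1)
  expect_named(collinearity_screen(dup, 0.95), "a")

  ind <- as.data.frame(matrix(stats::rnorm(200 * 4), 200, 4))
  expect_equal(ncol(collinearity_screen(ind, 0.95)), 4)

  cst <- data.frame(a = x1, b = rep(1, 200), c = x3)
  expect_warning(out2 <- collinearity_screen(cst, 0.95), "constant")
  expect_named(out2, c("a", "c"))

  # retained columns are pairwise below the threshold
  set.seed(32)
  z <- stats::rnorm(100)
  noisy <- as.data.frame(sapply(1:8, function(i)
    z * stats::runif(1) + stats::rnorm(100)))
  kept <- collinearity_screen(noisy, threshold = 0.6)
  cm <- abs(stats::cor(kept[setdiff(names(kept), "complete")]))
  expect_true(all(cm[upper.tri(cm)] <= 0.6))
})
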