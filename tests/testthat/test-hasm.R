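test_that("finite differences are exact on low-order polynomials", {
  g <- grid_geometry(8, 8, 1)
  pl <- analytic_test_surface("plane", g, list(a = 2, b = 3, c = 1))
  fd <- finite_differences(pl)
  inner <- function(m) m[2:7, 2:7]
  expect_true(all(abs(inner(fd$f_x) - 2) < 1e-12))
  expect_true(all(abs(inner(fd$f_y) - 3) < 1e-12))
  expect_true(all(abs(inner(fd$f_xx)) < 1e-12))
  expect_true(all(abs(inner(fd$f_yy)) < 1e-12))
  expect_true(all(abs(inner(fd$f_xy)) < 1e-12))

  cst <- grid_surface(matrix(7, 5, 5), 1)
  fdc <- finite_differences(cst)
  expect_true(all(vapply(fdc, function(m) all(m[2:4, 2:4] == 0), logical(1))))

  # f = x^2: central second difference is exact for quadratics
  cc <- cell_centers(g)
  quad <- grid_surface(matrix(cc$x^2, 8, 8, byrow = TRUE), 1)
  fq <- finite_differences(quad)
  expect_true(all(abs(inner(fq$f_xx) - 2) < 1e-10))
  expect_error(finite_differences(grid_surface(matrix(0, 2, 5), 1)), "3x3")
})

test_that("fundamental coefficients satisfy the Monge-patch identities", {
  g <- grid_geometry(8, 8, 1)
  pl <- analytic_test_surface("plane", g, list(a = 2, b = 3, c = 0))
  fc <- fundamental_coefficients(finite_differences(pl), 1)
  inner <- function(m) m[3:6, 3:6]
  expect_true(all(abs(inner(fc$E) - 5) < 1e-12))
  expect_true(all(abs(inner(fc$F) - 6) < 1e-12))
  expect_true(all(abs(inner(fc$G) - 10) < 1e-12))
  for (nm in c("L", "M", "N", "G111", "G211", "G112", "G212", "G122", "G222"))
    expect_true(all(abs(inner(fc[[nm]])) < 1e-12), label = nm)

  cst <- fundamental_coefficients(finite_differences(
    grid_surface(matrix(4, 6, 6), 1)), 1)
  expect_true(all(cst$E[2:5, 2:5] == 1))
  expect_true(all(cst$F[2:5, 2:5] == 0))

  # E G - F^2 = 1 + f_x^2 + f_y^2 >= 1 on any surface
  set.seed(55)
  f <- grid_surface(matrix(stats::rnorm(100), 10, 10), 1)
  rc <- fundamental_coefficients(finite_differences(f), 1)
  detg <- (rc$E * rc$G - rc$F^2)[2:9, 2:9]
  expect_true(all(detg >= 1 - 1e-12))
  expect_equal(detg, rc$W[2:9, 2:9], tolerance = 1e-12)
})

test_that("system assembly has the right shape and degenerate right sides", {
  flat <- grid_surface(matrix(3, 5, 5), 1)
  sys <- assemble_system(flat)
  expect_equal(nrow(sys$A), 9)   # 3x3 interior of a 5x5 grid
  expect_equal(nrow(sys$B), 9)
  expect_equal(nrow(sys$C), 9)
  expect_true(all(sys$d == 0) && all(sys$q == 0) && all(sys$h == 0))

  pl <- analytic_test_surface("plane", grid_geometry(6, 6, 1),
                              list(a = 1, b = -2, c = 5))
  sysp <- assemble_system(pl)
  expect_true(max(abs(c(sysp$d, sysp$q, sysp$h))) < 1e-12)

  expect_error(assemble_system(flat, constraint_set(9, 1, 1)),
               "outside grid")
})

test_that("constraint sets deduplicate repeated cells by their mean", {
  cs <- constraint_set(c(2, 2, 3), c(4, 4, 1), c(1, 3, 7))
  expect_equal(nrow(cs), 2)
  expect_equal(cs$value[cs$row == 2 & cs$col == 4], 2)
  expect_error(constraint_set(1, 1, Inf), "non-finite")
})

test_that("penalty solve matches a dense KKT oracle on random systems", {
  for (n in c(6, 8)) {
    for (s in 1:4) {
      set.seed(n * 100 + s)
      f <- grid_surface(matrix(stats::rnorm(n * n), n, n), 1)
      cons <- random_constraints(n, 5, seed = n * 100 + s)
      sys <- assemble_system(f, cons)
      sol <- solve_constrained(sys, hasm_config())
      sole <- solve_constrained(sys, hasm_config(mode = "exact"))
      oracle <- dense_kkt_oracle(sys)
      expect_lt(max(abs(sol$x - oracle)), 1e-6)
      expect_lt(max(abs(sole$x - oracle)), 1e-6)
      # constraint contract
      krange <- diff(range(cons$value))
      expect_lte(sol$violation, 1e-6 * max(krange, max(abs(cons$value))))
    }
  }
})

test_that("zero data gives the zero surface and affine data are preserved", {
  z <- grid_surface(matrix(0, 6, 6), 1)
  out <- hasm_iterate(z, config = hasm_config(max_iter = 1))
  expect_true(all(out$values == 0))

  pl <- analytic_test_surface("plane", grid_geometry(7, 7, 1),
                              list(a = 1, b = 2, c = 0))
  kept <- hasm_iterate(pl, config = hasm_config(max_iter = 2))
  expect_lt(max(abs(kept$values - pl$values)), 1e-5)
})

test_that("HASM is translation-equivariant and deterministic", {
  g <- grid_geometry(15, 15, 1)
  f0 <- gaussian_random_field(g, 3, 1, seed = 61)
  cons <- random_constraints(15, 10, seed = 62)
  a <- hasm_iterate(f0, cons, hasm_config())
  f0c <- f0; f0c$values <- f0$values + 5
  consc <- constraint_set(cons$row, cons$col, cons$value + 5)
  b <- hasm_iterate(f0c, consc, hasm_config())
  expect_lt(max(abs(b$values - a$values - 5)), 1e-5)

  a2 <- hasm_iterate(f0, cons, hasm_config())
  expect_identical(a$values, a2$values)   # bitwise determinism

  d <- attr(a, "diagnostics")
  expect_true(all(c("iteration", "objective", "violation", "delta")
                  %in% names(d)))
})

test_that("nodata cells are excluded from unknowns and preserved", {
  g <- grid_geometry(12, 12, 1)
  f0 <- analytic_test_surface("gaussian_hill", g, list(amp = 5, sigma = 3))
  f0$values[5:6, 5:6] <- NA
  cons <- constraints_from(f0, c(2, 9, 10, 3), c(2, 3, 10, 9))
  out <- hasm_iterate(f0, cons, hasm_config())
  expect_true(all(is.na(out$values[5:6, 5:6])))
  expect_true(all(is.finite(out$values[-(5:6), -(5:6)])))
  expect_error(hasm_iterate(f0, constraint_set(5, 5, 1), hasm_config()),
               "nodata")
})
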