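#' Central finite differences of a grid surface
#'
#' First and second partial derivatives on interior cells, by second-order
#' central differences (`x` east along columns, `y` north): boundary cells
#' and cells with any nodata neighbor in the 3x3 stencil are `NA`.
#'
#' @param f a [grid_surface()] with at least 3 rows and columns.
#' @return list of matrices `f_x`, `f_y`, `f_xx`, `f_yy`, `f_xy`.
#' @export
finite_differences <- function(f) {
  stopifnot(inherits(f, "grid_surface"))
  z <- f$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("grid must be at least 3x3")
  h <- f$cellsize
  zN <- shift_mat(z, -1, 0); zS <- shift_mat(z, 1, 0)
  zE <- shift_mat(z, 0, 1);  zW <- shift_mat(z, 0, -1)
  zNE <- shift_mat(z, -1, 1); zNW <- shift_mat(z, -1, -1)
  zSE <- shift_mat(z, 1, 1);  zSW <- shift_mat(z, 1, -1)
  list(
    f_x  = (zE - zW) / (2 * h),
    f_y  = (zN - zS) / (2 * h),
    f_xx = (zE - 2 * z + zW) / h^2,
    f_yy = (zN - 2 * z + zS) / h^2,
    f_xy = (zNE - zNW - zSE + zSW) / (4 * h^2)
  )
}

#' Fundamental forms and Christoffel symbols of a surface iterate
#'
#' For the graph `z = f(x, y)` (Monge patch), the first fundamental form is
#' `E = 1 + f_x^2`, `F = f_x f_y`, `G = 1 + f_y^2`; with
#' `W = 1 + f_x^2 + f_y^2` the second fundamental form is `L = f_xx /
#' sqrt(W)`, `M = f_xy / sqrt(W)`, `N = f_yy / sqrt(W)`. The six Christoffel
#' symbols follow from `E`, `F`, `G` and the central differences of those
#' coefficient grids by the standard intrinsic formulas. Before
#' differencing, the coefficient grids are padded one ring outward by edge
#' replication so the symbols stay defined on every interior cell.
#' Differencing the coefficient grids (rather than expanding the partials
#' analytically) is deliberate: the analytic expansion collapses the
#' discrete Gauss equations into an identity satisfied by any surface,
#' which would make every iterate a fixed point of the solver.
#' `E G - F^2 = W >= 1` always, so no division can degenerate.
#'
#' @param derivs output of [finite_differences()].
#' @param cellsize grid spacing used to difference the coefficient grids.
#' @return list of matrices `E`, `F`, `G`, `L`, `M`, `N`, `W`, and
#'   `G111`, `G211`, `G112`, `G212`, `G122`, `G222` (Christoffel symbols
#'   \eqn{\Gamma^1_{11}, \Gamma^2_{11}, \Gamma^1_{12}, \Gamma^2_{12},
#'   \Gamma^1_{22}, \Gamma^2_{22}}).
#' @export
fundamental_coefficients <- function(derivs, cellsize = 1) {
  fx <- derivs$f_x; fy <- derivs$f_y
  fxx <- derivs$f_xx; fyy <- derivs$f_yy; fxy <- derivs$f_xy
  E <- 1 + fx^2; Fm <- fx * fy; G <- 1 + fy^2
  W <- 1 + fx^2 + fy^2
  sw <- sqrt(W)
  L <- fxx / sw; M <- fxy / sw; N <- fyy / sw
  Ep <- fill_undefined(E); Fp <- fill_undefined(Fm); Gp <- fill_undefined(G)
  ddx <- function(m) (shift_mat(m, 0, 1) - shift_mat(m, 0, -1)) / (2 * cellsize)
  ddy <- function(m) (shift_mat(m, -1, 0) - shift_mat(m, 1, 0)) / (2 * cellsize)
  Ex <- ddx(Ep); Ey <- ddy(Ep)
  Fx <- ddx(Fp); Fy <- ddy(Fp)
  Gx <- ddx(Gp); Gy <- ddy(Gp)
  den <- 2 * (E * G - Fm^2)
  list(E = E, F = Fm, G = G, L = L, M = M, N = N, W = W,
       G111 = (G * Ex - 2 * Fm * Fx + Fm * Ey) / den,
       G211 = (2 * E * Fx - E * Ey - Fm * Ex) / den,
       G112 = (G * Ey - Fm * Gx) / den,
       G212 = (E * Gx - Fm * Ey) / den,
       G122 = (2 * G * Fy - G * Gx - Fm * Gy) / den,
       G222 = (E * Gy - 2 * Fm * Fy + Fm * Gx) / den)
}

#' Constraint set for the surface solver
#'
#' Sampling constraints `S x = k`: observed surface values pinned at grid
#' cells. Duplicate cells are collapsed to their (weighted) mean before
#' solving.
#'
#' @param row,col 1-based cell indices.
#' @param value observed values `k`.
#' @param weight optional positive weights (penalty mode only).
#' @return data.frame of class `constraint_set`.
#' @export
constraint_set <- function(row, col, value, weight = 1) {
  stopifnot(length(row) == length(col), length(col) == length(value))
  df <- data.frame(row = as.integer(row), col = as.integer(col),
                   value = as.numeric(value),
                   weight = rep_len(as.numeric(weight), length(row)))
  if (any(!is.finite(df$value))) stop("non-finite constraint values")
  if (any(df$weight <= 0)) stop("constraint weights must be positive")
  key <- paste(df$row, df$col)
  if (anyDuplicated(key)) {
    agg <- lapply(split(df, key), function(d)
      data.frame(row = d$row[1], col = d$col[1],
                 value = sum(d$value * d$weight) / sum(d$weight),
                 weight = sum(d$weight)))
    df <- do.call(rbind, agg)
    df <- df[order(df$row, df$col), ]
    rownames(df) <- NULL
  }
  class(df) <- c("constraint_set", "data.frame")
  df
}

#' Solver configuration
#'
#' @param max_iter maximum outer (surface re-linearization) iterations.
#' @param tol outer convergence tolerance: stop when the maximum absolute
#'   surface update falls below `tol * range(values)`.
#' @param mode `"penalty"` (augmented-Lagrangian penalty; default) or
#'   `"exact"` (sparse KKT solve of the equality-constrained problem).
#' @param mu penalty weight; `NULL` auto-scales it from the stencil
#'   magnitude.
#' @param constraint_tol maximum allowed constraint violation, relative to
#'   the range of the constraint values.
#' @param anchor relative weight of a proximal term tying the solution to
#'   the current iterate. Default 0 (the pure constrained problem); when the
#'   constraints are too few to pin the affine null space of the stencil
#'   operator the solver automatically falls back to a tiny anchor
#'   (`1e-9` relative) so the factorization exists, which returns the
#'   iterate itself in the fully degenerate no-constraint case.
#' @return list of class `hasm_config`.
#' @export
hasm_config <- function(max_iter = 3, tol = 1e-4, mode = c("penalty", "exact"),
                        mu = NULL, constraint_tol = 1e-6, anchor = 0) {
  mode <- match.arg(mode)
  stopifnot(max_iter >= 1, tol > 0, constraint_tol > 0, anchor >= 0)
  structure(list(max_iter = max_iter, tol = tol, mode = mode, mu = mu,
                 constraint_tol = constraint_tol, anchor = anchor),
            class = "hasm_config")
}

# single-slot cache: repeated solves on one grid geometry (the common case
# in the comparative study) skip stencil reassembly
.stencil_cache <- new.env(parent = emptyenv())

build_stencils_cached <- function(geom, mask) {
  key <- list(geom = unclass(geom), mask = mask)
  if (!is.null(.stencil_cache$key) && identical(.stencil_cache$key, key))
    return(.stencil_cache$value)
  st <- build_stencils(geom, mask)
  .stencil_cache$key <- key
  .stencil_cache$value <- st
  st
}

# Sparse second-difference stencils on the valid (non-nodata) cells of a
# geometry. Unknowns are the valid cells in row-major order; one equation
# row per cell whose full 3x3 neighborhood is valid. Returns A (d2/dx2),
# B (d2/dy2), C (cross derivative) and the index bookkeeping.
build_stencils <- function(geom, mask) {
  nr <- geom$nrow; nc <- geom$ncol
  if (nr < 3 || nc < 3) stop("grid must be at least 3x3")
  h <- geom$cellsize
  valid <- which(t(mask))                       # row-major linear cell ids
  unk_of_cell <- rep(NA_integer_, nr * nc)
  unk_of_cell[valid] <- seq_along(valid)
  n_unk <- length(valid)

  rm_index <- function(i, j) (i - 1L) * nc + j  # row-major
  ok <- matrix(FALSE, nr, nc)
  ok[2:(nr - 1), 2:(nc - 1)] <- TRUE
  # full 3x3 neighborhood valid
  for (di in -1:1) for (dj in -1:1) {
    nb <- shift_mat(mask + 0, di, dj)
    ok <- ok & !is.na(nb) & nb > 0
  }
  eq <- which(ok, arr.ind = TRUE)               # equation cells (i, j)
  if (nrow(eq) == 0L) stop("no interior cells to assemble equations on")
  m <- nrow(eq)
  i <- eq[, 1]; j <- eq[, 2]
  u <- function(ii, jj) unk_of_cell[rm_index(ii, jj)]
  rows3 <- rep(seq_len(m), 3)
  A <- Matrix::sparseMatrix(
    i = rows3, j = c(u(i, j - 1), u(i, j), u(i, j + 1)),
    x = rep(c(1, -2, 1) / h^2, each = m), dims = c(m, n_unk))
  B <- Matrix::sparseMatrix(
    i = rows3, j = c(u(i - 1, j), u(i, j), u(i + 1, j)),
    x = rep(c(1, -2, 1) / h^2, each = m), dims = c(m, n_unk))
  C <- Matrix::sparseMatrix(
    i = rep(seq_len(m), 4),
    j = c(u(i - 1, j + 1), u(i - 1, j - 1), u(i + 1, j + 1), u(i + 1, j - 1)),
    x = rep(c(1, -1, -1, 1) / (4 * h^2), each = m), dims = c(m, n_unk))
  list(A = A, B = B, C = C, eq_cells = eq, n_unk = n_unk,
       unk_of_cell = unk_of_cell, valid = valid, geom = geom, mask = mask)
}

# Gauss-equation right-hand sides at the current iterate.
# replace undefined (NA) cells of a coefficient grid by the mean of their
# defined 4-neighbors; two passes cover the boundary ring and corners
fill_undefined <- function(m) {
  for (pass in 1:2) {
    na <- which(is.na(m), arr.ind = TRUE)
    if (!nrow(na)) break
    nr <- nrow(m); nc <- ncol(m)
    for (r in seq_len(nrow(na))) {
      i <- na[r, 1]; j <- na[r, 2]
      nb <- c(if (i > 1) m[i - 1, j], if (i < nr) m[i + 1, j],
              if (j > 1) m[i, j - 1], if (j < nc) m[i, j + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb)) m[i, j] <- mean(nb)
    }
  }
  m
}

hasm_rhs <- function(f, eq_cells) {
  dv <- finite_differences(f)
  fc <- fundamental_coefficients(dv, f$cellsize)
  sw <- sqrt(fc$W)
  d <- fc$G111 * dv$f_x + fc$G211 * dv$f_y + fc$L / sw
  q <- fc$G122 * dv$f_x + fc$G222 * dv$f_y + fc$N / sw
  hh <- fc$G112 * dv$f_x + fc$G212 * dv$f_y + fc$M / sw
  idx <- eq_cells
  list(d = d[idx], q = q[idx], h = hh[idx])
}

#' Assemble the HASM linear system at a surface iterate
#'
#' Discretizes the three Gauss equations of the current iterate on every
#' interior cell: `A`, `B` and `C` carry the second-difference stencils in
#' `x`, `y` and the cross direction acting on the next iterate, and the
#' right-hand vectors `d`, `q`, `h` collect the Christoffel and
#' curvature terms evaluated at the current iterate, e.g.
#' `d = G111 f_x + G211 f_y + L / sqrt(W)`. The sampling constraints become
#' `S x = k` with one unit row per (deduplicated) constrained cell.
#'
#' @param f current iterate, a [grid_surface()] (`NA` = nodata, excluded
#'   from unknowns and equations).
#' @param constraints a [constraint_set()] (may have zero rows).
#' @param stencils optional precomputed stencil structure (internal reuse).
#' @return list of class `hasm_system`: sparse `A`, `B`, `C`, vectors `d`,
#'   `q`, `h`, sparse `S`, vector `k`, weights `w`, and index bookkeeping.
#' @export
assemble_system <- function(f, constraints = constraint_set(integer(), integer(), numeric()),
                            stencils = NULL) {
  stopifnot(inherits(f, "grid_surface"))
  geom <- geometry_of(f)
  mask <- !is.na(f$values)
  if (is.null(stencils)) stencils <- build_stencils(geom, mask)
  rhs <- hasm_rhs(f, stencils$eq_cells)
  if (anyNA(rhs$d) || anyNA(rhs$q) || anyNA(rhs$h))
    stop("non-finite right-hand side: iterate has NA on equation cells")

  cs <- constraints
  if (nrow(cs)) {
    if (any(cs$row < 1 | cs$row > geom$nrow | cs$col < 1 | cs$col > geom$ncol))
      stop("constraint outside grid")
    cell <- (cs$row - 1L) * geom$ncol + cs$col
    u <- stencils$unk_of_cell[cell]
    if (anyNA(u)) stop("constraint on nodata cell")
    S <- Matrix::sparseMatrix(i = seq_len(nrow(cs)), j = u, x = 1,
                              dims = c(nrow(cs), stencils$n_unk))
    k <- cs$value; w <- cs$weight
  } else {
    S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(0L, stencils$n_unk))
    k <- numeric(); w <- numeric()
  }
  structure(list(A = stencils$A, B = stencils$B, C = stencils$C,
                 d = rhs$d, q = rhs$q, h = rhs$h, S = S, k = k, w = w,
                 stencils = stencils, geom = geom, mask = mask),
            class = "hasm_system")
}

# vector of iterate values at the unknowns (row-major valid cells)
iterate_vector <- function(f, stencils) {
  as.numeric(t(f$values))[stencils$valid]
}

#' Solve the constrained least-squares problem of one HASM step
#'
#' Minimizes `|| [A; B; C] x - [d; q; h] ||_2` subject to `S x = k`.
#' Penalty mode solves the augmented-Lagrangian normal equations
#' `(M'M + mu^2 S'WS + eps I) x = M'r + mu^2 S'Wk - S'lambda/2 + eps x0`
#' with multiplier updates until the worst constraint violation is below
#' `constraint_tol * range(k)`; exact mode solves the sparse KKT system of
#' the equality-constrained problem directly. Both are deterministic.
#'
#' @param system a `hasm_system` from [assemble_system()].
#' @param config a [hasm_config()].
#' @param x0 optional anchor vector (defaults to zero): the proximal center.
#' @return list: `x` (solution over unknowns), `surface` ([grid_surface()]),
#'   `objective` (`||Mx - r||^2`), `violation` (max `|Sx - k|`).
#' @export
solve_constrained <- function(system, config = hasm_config(), x0 = NULL) {
  stopifnot(inherits(system, "hasm_system"))
  st <- system$stencils
  M <- rbind(system$A, system$B, system$C)
  r <- c(system$d, system$q, system$h)
  n <- st$n_unk
  if (is.null(x0)) x0 <- numeric(n)
  sol <- solve_constrained_core(M, r, system$S, system$k, system$w,
                                config, x0)
  vals <- matrix(NA_real_, system$geom$nrow, system$geom$ncol)
  tvals <- t(vals)
  tvals[st$valid] <- sol$x
  vals <- t(tvals)
  list(x = sol$x,
       surface = grid_surface(vals, system$geom$cellsize, system$geom$xll,
                              system$geom$yll),
       objective = sol$objective, violation = sol$violation)
}

solve_constrained_core <- function(M, r, S, k, w, config, x0) {
  n <- ncol(M)
  ncons <- nrow(S)
  H0 <- Matrix::crossprod(M)
  diag_scale <- max(Matrix::colSums(M * M), 1e-12)
  eps <- config$anchor * diag_scale
  krange <- if (ncons) max(diff(range(k)), max(abs(k)), 1e-12) else 1
  ctol <- config$constraint_tol * krange
  Mr <- as.numeric(Matrix::crossprod(M, r))

  if (config$mode == "exact" && ncons > 0) {
    make_kkt <- function(e)
      rbind(cbind(2 * H0 + 2 * e * Matrix::Diagonal(n), Matrix::t(S)),
            cbind(S, Matrix::Matrix(0, ncons, ncons, sparse = TRUE)))
    sol <- tryCatch(
      as.numeric(Matrix::solve(make_kkt(eps), c(2 * Mr + 2 * eps * x0, k))),
      error = function(e) {
        ef <- max(eps, 1e-9 * diag_scale)
        as.numeric(Matrix::solve(make_kkt(ef), c(2 * Mr + 2 * ef * x0, k)))
      })
    x <- sol[seq_len(n)]
  } else {
    # moderate penalty: keeps the normal equations well conditioned, the
    # multiplier updates below drive the violation to tolerance
    mu2 <- if (is.null(config$mu)) 100 * max(diag_scale, 1) else config$mu^2
    Wd <- if (ncons) Matrix::Diagonal(ncons, w) else NULL
    make_h <- function(e) {
      H <- H0 + e * Matrix::Diagonal(n)
      if (ncons) H <- H + mu2 * Matrix::crossprod(S, Wd %*% S)
      Matrix::Cholesky(Matrix::forceSymmetric(H), LDL = FALSE, perm = TRUE)
    }
    ch <- tryCatch(suppressWarnings(make_h(eps)), error = function(e) {
      eps <<- max(eps, 1e-9 * diag_scale)
      make_h(eps)
    })
    lambda <- numeric(ncons)
    x <- NULL
    polish <- 0L   # extra multiplier updates after feasibility, for optimality
    for (it in seq_len(60L)) {
      b <- Mr + eps * x0
      if (ncons)
        b <- b + as.numeric(Matrix::crossprod(S, w * (mu2 * k - lambda / 2)))
      x <- as.numeric(Matrix::solve(ch, b))
      if (!ncons) break
      resid <- as.numeric(S %*% x) - k
      if (max(abs(resid)) <= ctol) {
        polish <- polish + 1L
        if (polish >= 3L) break
      }
      lambda <- lambda + 2 * mu2 * w * resid
      if (it == 60L)
        stop(sprintf(paste0("constraint enforcement did not converge: max ",
                            "violation %.3g (tolerance %.3g)"),
                     max(abs(resid)), ctol))
    }
  }
  viol <- if (ncons) max(abs(as.numeric(S %*% x) - k)) else 0
  obj <- sum((as.numeric(M %*% x) - r)^2)
  list(x = x, objective = obj, violation = viol)
}

#' Iterate HASM to convergence
#'
#' The outer loop of high-accuracy surface modeling: starting from an
#' initial surface, repeatedly assemble the Gauss-equation system at the
#' current iterate and solve the sampling-constrained least-squares problem,
#' until the maximum surface update drops below `tol * range` or the
#' iteration cap is reached. The stencil matrices and the penalty-mode
#' Cholesky factor depend only on the grid and constraint cells, so they are
#' built once and reused across iterations. Fully deterministic.
#'
#' @param initial starting surface ([grid_surface()]).
#' @param constraints a [constraint_set()].
#' @param config a [hasm_config()].
#' @return the final [grid_surface()], with attribute `diagnostics`: a
#'   data.frame of per-iteration objective, constraint violation and update
#'   size.
#' @export
hasm_iterate <- function(initial, constraints = constraint_set(integer(), integer(), numeric()),
                         config = hasm_config()) {
  stopifnot(inherits(initial, "grid_surface"))
  geom <- geometry_of(initial)
  mask <- !is.na(initial$values)
  if (!all(is.finite(initial$values[mask])))
    stop("initial surface must be finite on valid cells")
  st <- build_stencils_cached(geom, mask)
  f <- initial
  diag_rows <- list()
  obj0 <- NA_real_
  for (it in seq_len(config$max_iter)) {
    system <- assemble_system(f, constraints, stencils = st)
    x_prev <- iterate_vector(f, st)
    sol <- solve_constrained(system, config, x0 = x_prev)
    delta <- max(abs(sol$x - x_prev))
    rng <- max(diff(range(sol$x)), 1e-12)
    diag_rows[[it]] <- data.frame(iteration = it, objective = sol$objective,
                                  violation = sol$violation, delta = delta)
    if (it == 1L) obj0 <- sol$objective
    if (it > 1L && sol$objective > 10 * (obj0 + 1e-12))
      stop(sprintf("HASM diverged: objective %.3g exceeds 10x initial %.3g",
                   sol$objective, obj0))
    f <- sol$surface
    if (delta < config$tol * rng) break
  }
  attr(f, "diagnostics") <- do.call(rbind, diag_rows)
  f
}
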