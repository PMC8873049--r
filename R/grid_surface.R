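#' Regular-grid surface
#'
#' A `grid_surface` is a single-band field of values on a regular raster
#' grid: a numeric matrix whose first row is the northernmost row of cells,
#' together with the grid geometry (cell size and lower-left corner of the
#' extent). `NA` entries are nodata. It is the common currency of the
#' package: covariate layers, machine-learning prediction surfaces, HASM
#' iterates and final diversity maps are all `grid_surface` objects.
#'
#' Cell `(i, j)` (1-based, `i = 1` at the north edge) has center coordinates
#' `x = xll + (j - 1/2) * cellsize`, `y = yll + (nrow - i + 1/2) * cellsize`.
#' Point-in-cell membership is half-open: a point belongs to the cell with
#' `x` in `[x0, x0 + cellsize)`, `y` in `(y0, y0 + cellsize]` reading from
#' the cell's south-west corner, so boundary points resolve deterministically.
#'
#' @param values numeric matrix (row 1 = north); `NA` marks nodata cells.
#' @param cellsize positive cell edge length, in map units.
#' @param xll,yll coordinates of the lower-left corner of the grid extent.
#' @return An object of class `grid_surface`.
#' @examples
#' g <- grid_surface(matrix(1:12, 3, 4), cellsize = 30)
#' dim(g)
#' @export
grid_surface <- function(values, cellsize = 1, xll = 0, yll = 0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L, cellsize > 0,
            is.numeric(xll), is.numeric(yll))
  structure(list(values = values, cellsize = as.numeric(cellsize),
                 xll = as.numeric(xll), yll = as.numeric(yll)),
            class = "grid_surface")
}

#' @export
dim.grid_surface <- function(x) dim(x$values)

#' @export
print.grid_surface <- function(x, ...) {
  v <- x$values
  cat(sprintf("grid_surface: %d x %d cells, cellsize %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cellsize, x$xll, x$yll))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%g, %g], nodata cells: %d\n",
                min(fin), max(fin), sum(is.na(v))))
  else cat("  all nodata\n")
  invisible(x)
}

#' Grid geometry descriptor
#'
#' @param nrow,ncol grid dimensions.
#' @param cellsize,xll,yll as in [grid_surface()].
#' @return A list with class `grid_geometry`.
#' @export
grid_geometry <- function(nrow, ncol, cellsize = 1, xll = 0, yll = 0) {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellsize = as.numeric(cellsize),
                 xll = as.numeric(xll), yll = as.numeric(yll)),
            class = "grid_geometry")
}

#' @rdname grid_geometry
#' @param x a `grid_surface` or `grid_geometry`.
#' @export
geometry_of <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  stopifnot(inherits(x, "grid_surface"))
  grid_geometry(nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll)
}

same_geometry <- function(a, b, tol = 1e-9) {
  ga <- geometry_of(a); gb <- geometry_of(b)
  ga$nrow == gb$nrow && ga$ncol == gb$ncol &&
    abs(ga$cellsize - gb$cellsize) <= tol * ga$cellsize &&
    abs(ga$xll - gb$xll) <= tol * max(1, abs(ga$xll)) &&
    abs(ga$yll - gb$yll) <= tol * max(1, abs(ga$yll))
}

geometry_string <- function(g) {
  g <- geometry_of(g)
  sprintf("%dx%d @%g origin(%g,%g)", g$nrow, g$ncol, g$cellsize, g$xll, g$yll)
}

stop_geometry_mismatch <- function(a, b) {
  stop("grid geometry mismatch: ", geometry_string(a), " vs ",
       geometry_string(b), call. = FALSE)
}

#' Cell-center coordinates of a grid
#'
#' @param g `grid_surface` or `grid_geometry`.
#' @return list with `x` (length ncol, west to east) and `y`
#'   (length nrow, north to south, matching matrix row order).
#' @export
cell_centers <- function(g) {
  g <- geometry_of(g)
  list(x = g$xll + (seq_len(g$ncol) - 0.5) * g$cellsize,
       y = g$yll + (g$nrow - seq_len(g$nrow) + 0.5) * g$cellsize)
}

#' Locate points on a grid
#'
#' Maps map coordinates to (row, col) cell indices using the half-open
#' membership convention described in [grid_surface()].
#'
#' @param g grid or geometry.
#' @param x,y point coordinates (equal-length vectors).
#' @return data.frame with columns `row`, `col` (`NA` outside the extent).
#' @export
xy_to_cell <- function(g, x, y) {
  g <- geometry_of(g)
  stopifnot(length(x) == length(y))
  col <- floor((x - g$xll) / g$cellsize) + 1
  iy <- floor((y - g$yll) / g$cellsize) + 1   # 1 at south edge
  row <- g$nrow - iy + 1
  bad <- col < 1 | col > g$ncol | row < 1 | row > g$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Row-major linear index of grid cells
#' @param g grid or geometry.
#' @param row,col cell indices.
#' @return integer vector, `(row - 1) * ncol + col`.
#' @export
cell_index <- function(g, row, col) {
  g <- geometry_of(g)
  as.integer((row - 1L) * g$ncol + col)
}

#' Resample a surface onto a target grid
#'
#' Bilinear interpolation between source cell centers, for continuous
#' layers. Target cells whose interpolation corners include nodata become
#' nodata; target centers outside the source extent become nodata; centers
#' inside the extent but beyond the outermost cell centers are clamped to
#' the edge (so a constant raster resamples to the same constant).
#'
#' @param raster source `grid_surface`.
#' @param target target geometry (`grid_geometry` or `grid_surface`).
#' @return `grid_surface` on the target geometry.
#' @export
resample_to_grid <- function(raster, target) {
  stopifnot(inherits(raster, "grid_surface"))
  tg <- geometry_of(target)
  sg <- geometry_of(raster)
  # extent overlap check
  sx <- c(sg$xll, sg$xll + sg$ncol * sg$cellsize)
  sy <- c(sg$yll, sg$yll + sg$nrow * sg$cellsize)
  tx <- c(tg$xll, tg$xll + tg$ncol * tg$cellsize)
  ty <- c(tg$yll, tg$yll + tg$nrow * tg$cellsize)
  if (tx[1] >= sx[2] || tx[2] <= sx[1] || ty[1] >= sy[2] || ty[2] <= sy[1])
    stop("resample_to_grid: target extent does not overlap source extent")

  src <- cell_centers(sg)
  xs <- src$x                       # ascending
  ys <- rev(src$y)                  # ascending (south to north)
  vals <- raster$values[sg$nrow:1, , drop = FALSE]  # row 1 = south

  tc <- cell_centers(tg)
  px <- rep(tc$x, each = tg$nrow)       # column-major fill below
  py <- rep(tc$y, times = tg$ncol)

  inside <- px >= sx[1] & px <= sx[2] & py >= sy[1] & py <= sy[2]
  # clamp to center hull for interpolation
  cx <- pmin(pmax(px, xs[1]), xs[length(xs)])
  cy <- pmin(pmax(py, ys[1]), ys[length(ys)])
  j0 <- pmin(pmax(findInterval(cx, xs), 1L), length(xs) - 1L)
  i0 <- pmin(pmax(findInterval(cy, ys), 1L), length(ys) - 1L)
  if (length(xs) == 1L) j0 <- rep(1L, length(cx))
  if (length(ys) == 1L) i0 <- rep(1L, length(cy))
  j1 <- pmin(j0 + 1L, length(xs)); i1 <- pmin(i0 + 1L, length(ys))
  dx <- ifelse(j1 > j0, (cx - xs[j0]) / (xs[j1] - xs[j0]), 0)
  dy <- ifelse(i1 > i0, (cy - ys[i0]) / (ys[i1] - ys[i0]), 0)
  v00 <- vals[cbind(i0, j0)]; v01 <- vals[cbind(i0, j1)]
  v10 <- vals[cbind(i1, j0)]; v11 <- vals[cbind(i1, j1)]
  out <- (1 - dy) * ((1 - dx) * v00 + dx * v01) +
         dy * ((1 - dx) * v10 + dx * v11)
  out[!inside] <- NA_real_
  # column-major layout above puts y north->south down each column,
  # matching grid_surface row order
  m <- matrix(out, nrow = tg$nrow, ncol = tg$ncol)
  grid_surface(m, tg$cellsize, tg$xll, tg$yll)
}

#' Analytic validation surfaces
#'
#' Exact evaluation of simple analytic fields at cell centers, used to
#' validate the surface solver: `plane` (`a*x + b*y + c`), `gaussian_hill`
#' (`amp * exp(-((x-x0)^2+(y-y0)^2) / (2*sigma^2))`, centered on the grid
#' by default) and `sine_ridge` (`amp * sin(2*pi*x/period)`).
#'
#' @param name one of `"plane"`, `"gaussian_hill"`, `"sine_ridge"`.
#' @param geometry target `grid_geometry`.
#' @param params named list of parameters: plane `a`, `b`, `c`;
#'   gaussian_hill `amp`, `sigma`, optional `x0`, `y0`; sine_ridge `amp`,
#'   `period`.
#' @return `grid_surface`.
#' @export
analytic_test_surface <- function(name, geometry, params = list()) {
  g <- geometry_of(geometry)
  cc <- cell_centers(g)
  X <- matrix(cc$x, g$nrow, g$ncol, byrow = TRUE)
  Y <- matrix(cc$y, g$nrow, g$ncol)
  v <- switch(name,
    plane = {
      p <- modifyList(list(a = 1, b = 1, c = 0), params)
      p$a * X + p$b * Y + p$c
    },
    gaussian_hill = {
      ext <- list(x0 = g$xll + g$ncol * g$cellsize / 2,
                  y0 = g$yll + g$nrow * g$cellsize / 2,
                  amp = 1, sigma = g$ncol * g$cellsize / 6)
      p <- modifyList(ext, params)
      p$amp * exp(-((X - p$x0)^2 + (Y - p$y0)^2) / (2 * p$sigma^2))
    },
    sine_ridge = {
      p <- modifyList(list(amp = 1, period = g$ncol * g$cellsize / 4), params)
      p$amp * sin(2 * pi * X / p$period)
    },
    stop("unknown analytic surface: ", name)
  )
  grid_surface(v, g$cellsize, g$xll, g$yll)
}
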