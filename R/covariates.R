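#' Multi-band raster stack
#'
#' A named collection of [grid_surface()] layers sharing one grid geometry:
#' spectral bands, vegetation indices, terrain derivatives and environmental
#' layers all live in `band_stack`s.
#'
#' @param layers named list of `grid_surface` objects on a common geometry.
#' @return object of class `band_stack`.
#' @export
band_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            !is.null(names(layers)), all(nzchar(names(layers))))
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "grid_surface"))
      stop("layer '", nm, "' is not a grid_surface")
    if (!same_geometry(layers[[nm]], layers[[1]]))
      stop_geometry_mismatch(layers[[nm]], layers[[1]])
  }
  structure(layers, class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  cat(sprintf("band_stack of %d layers (%s): %s\n", length(x),
              geometry_string(x[[1]]), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' @export
`[.band_stack` <- function(x, i) band_stack(unclass(x)[i])

stack_names <- function(stack) names(unclass(stack))

ndvi_of <- function(stack) {
  v <- stack[["NIR"]]$values; r <- stack[["red"]]$values
  den <- v + r
  out <- (v - r) / den
  out[den == 0] <- NA_real_
  out
}

#' Maximum-NDVI composite of several scenes
#'
#' Merges multiple co-registered scenes into one cloud-reduced image: each
#' cell takes all bands from the scene whose NDVI at that cell is largest.
#' Scenes with nodata at a cell are skipped there; cells where every scene
#' is nodata stay nodata.
#'
#' @param scenes list of `band_stack`s with identical geometry and band
#'   names, each containing at least `NIR` and `red`.
#' @return composited `band_stack`.
#' @export
max_ndvi_composite <- function(scenes) {
  stopifnot(is.list(scenes), length(scenes) >= 1L)
  ref <- scenes[[1]]
  for (s in scenes) {
    if (!inherits(s, "band_stack")) stop("scenes must be band_stacks")
    if (!identical(stack_names(s), stack_names(ref)))
      stop("scenes have differing band names")
    if (!same_geometry(s[[1]], ref[[1]])) stop_geometry_mismatch(s[[1]], ref[[1]])
  }
  ndvis <- lapply(scenes, ndvi_of)
  nd <- array(unlist(ndvis), dim = c(dim(ref[[1]]$values), length(scenes)))
  nd[is.na(nd)] <- -Inf
  pick <- apply(nd, c(1, 2), which.max)
  all_na <- apply(nd, c(1, 2), function(z) all(!is.finite(z)))
  out <- lapply(stack_names(ref), function(bn) {
    v <- ref[[bn]]$values
    for (k in seq_along(scenes))
      v[pick == k] <- scenes[[k]][[bn]]$values[pick == k]
    v[all_na] <- NA_real_
    grid_surface(v, ref[[1]]$cellsize, ref[[1]]$xll, ref[[1]]$yll)
  })
  names(out) <- stack_names(ref)
  band_stack(out)
}

#' Vegetation indices from reflectance bands
#'
#' Per-cell band arithmetic for six standard indices:
#' \describe{
#'   \item{NDVI}{`(NIR - red) / (NIR + red)`}
#'   \item{EVI}{`G * (NIR - red) / (NIR + C1*red - C2*blue + L)`}
#'   \item{NDWI}{`(NIR - SWIR1) / (NIR + SWIR1)`}
#'   \item{CRI}{`1/blue - 1/green`}
#'   \item{SRI}{`NIR / red`}
#'   \item{DVI}{`NIR - red`}
#' }
#' Cells where a denominator is zero become nodata.
#'
#' @param bands `band_stack` with layers `blue`, `green`, `red`, `NIR`,
#'   `SWIR1`.
#' @param params EVI coefficients, see [veg_index_params()].
#' @return `band_stack` of the six index layers.
#' @export
vegetation_indices <- function(bands, params = veg_index_params()) {
  need <- c("blue", "green", "red", "NIR", "SWIR1")
  miss <- setdiff(need, stack_names(bands))
  if (length(miss)) stop("missing band(s): ", paste(miss, collapse = ", "))
  b <- lapply(need, function(nm) bands[[nm]]$values)
  names(b) <- need
  safe_div <- function(num, den) {
    out <- num / den
    out[!is.na(den) & den == 0] <- NA_real_
    out
  }
  g1 <- bands[[1]]
  mk <- function(v) grid_surface(v, g1$cellsize, g1$xll, g1$yll)
  evi_den <- b$NIR + params$C1 * b$red - params$C2 * b$blue + params$L
  band_stack(list(
    NDVI = mk(safe_div(b$NIR - b$red, b$NIR + b$red)),
    EVI  = mk(params$G * safe_div(b$NIR - b$red, evi_den)),
    NDWI = mk(safe_div(b$NIR - b$SWIR1, b$NIR + b$SWIR1)),
    CRI  = mk(safe_div(1, b$blue) - safe_div(1, b$green)),
    SRI  = mk(safe_div(b$NIR, b$red)),
    DVI  = mk(b$NIR - b$red)))
}

#' EVI coefficients
#'
#' Canonical enhanced-vegetation-index parameterization: gain `G = 2.5`,
#' aerosol resistance coefficients `C1 = 6`, `C2 = 7.5`, canopy background
#' `L = 1`.
#'
#' @param G,C1,C2,L numeric scalars, `G > 0`.
#' @return named list.
#' @export
veg_index_params <- function(G = 2.5, C1 = 6, C2 = 7.5, L = 1) {
  stopifnot(G > 0)
  list(G = G, C1 = C1, C2 = C2, L = L)
}

shift_mat <- function(m, di, dj) {
  # value of m at (i + di, j + dj), NA outside
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr) + di; rj <- seq_len(nc) + dj
  ok_i <- ri >= 1 & ri <= nr; ok_j <- rj >= 1 & rj <= nc
  out[ok_i, ok_j] <- m[ri[ok_i], rj[ok_j]]
  out
}

#' Terrain derivatives of a DEM
#'
#' Slope and aspect by Horn's 3x3 weighted differences; plan and profile
#' curvature by the Zevenbergen-Thorne quadratic fit. Conventions: slope in
#' degrees; aspect in degrees clockwise from north with flat cells nodata;
#' curvatures in 1/(100 map units) with flat cells 0; the outermost ring of
#' cells is nodata (no one-sided stencils).
#'
#' @param dem a `grid_surface` of elevations.
#' @return `band_stack` with layers `elevation`, `slope`, `aspect`,
#'   `plan_curvature`, `profile_curvature`.
#' @export
terrain_derivatives <- function(dem) {
  stopifnot(inherits(dem, "grid_surface"))
  z <- dem$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("DEM must be at least 3x3")
  h <- dem$cellsize
  # 3x3 neighborhood, grid_surface rows run north -> south:
  #  z1 z2 z3      (north row)
  #  z4 z5 z6
  #  z7 z8 z9      (south row)
  z1 <- shift_mat(z, -1, -1); z2 <- shift_mat(z, -1, 0); z3 <- shift_mat(z, -1, 1)
  z4 <- shift_mat(z,  0, -1); z5 <- z;                   z6 <- shift_mat(z,  0, 1)
  z7 <- shift_mat(z,  1, -1); z8 <- shift_mat(z,  1, 0); z9 <- shift_mat(z,  1, 1)

  # Horn gradients: x east, y north
  dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * h)
  dzdy <- ((z1 + 2 * z2 + z3) - (z7 + 2 * z8 + z9)) / (8 * h)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # aspect: direction of steepest descent, clockwise from north
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  flat <- !is.na(dzdx) & !is.na(dzdy) & dzdx == 0 & dzdy == 0
  aspect[flat] <- NA_real_

  # Zevenbergen-Thorne quadratic coefficients
  D <- ((z4 + z6) / 2 - z5) / h^2
  E <- ((z2 + z8) / 2 - z5) / h^2
  Fc <- (-z1 + z3 + z7 - z9) / (4 * h^2)
  G <- (-z4 + z6) / (2 * h)
  H <- (z2 - z8) / (2 * h)
  gh2 <- G^2 + H^2
  profile <- -2 * (D * G^2 + E * H^2 + Fc * G * H) / gh2 * 100
  plan <- 2 * (D * H^2 + E * G^2 - Fc * G * H) / gh2 * 100
  zero <- !is.na(gh2) & gh2 == 0
  profile[zero] <- 0; plan[zero] <- 0

  ring <- matrix(FALSE, nrow(z), ncol(z))
  ring[c(1, nrow(z)), ] <- TRUE; ring[, c(1, ncol(z))] <- TRUE
  mk <- function(v) { v[ring] <- NA_real_
    grid_surface(v, dem$cellsize, dem$xll, dem$yll) }
  band_stack(list(elevation = dem, slope = mk(slope), aspect = mk(aspect),
                  plan_curvature = mk(plan), profile_curvature = mk(profile)))
}

#' Extract stack values at plot locations
#'
#' Value of every layer at the cell containing each plot (cell-center,
#' half-open membership). Plots outside the raster extent are an error;
#' plots hitting nodata in any layer are flagged.
#'
#' @param stack a `band_stack`.
#' @param plots data.frame with columns `plot_id`, `x`, `y`.
#' @return `feature_table`: data.frame with `plot_id`, one column per layer,
#'   and logical column `complete` (no nodata in the row).
#' @export
extract_at_plots <- function(stack, plots) {
  stopifnot(inherits(stack, "band_stack"),
            all(c("plot_id", "x", "y") %in% names(plots)))
  g <- geometry_of(stack[[1]])
  rc <- xy_to_cell(g, plots$x, plots$y)
  if (anyNA(rc$row))
    stop("plot(s) outside raster extent: ",
         paste(plots$plot_id[is.na(rc$row)], collapse = ", "))
  idx <- cbind(rc$row, rc$col)
  out <- data.frame(plot_id = plots$plot_id)
  for (nm in stack_names(stack)) out[[nm]] <- stack[[nm]]$values[idx]
  out$complete <- stats::complete.cases(out[, stack_names(stack), drop = FALSE])
  if (!all(out$complete))
    warning("nodata at plot(s): ",
            paste(out$plot_id[!out$complete], collapse = ", "))
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("plot_id", "complete"))
}

#' Greedy collinearity screen
#'
#' Scans feature columns in their declared order and drops any later column
#' whose absolute Pearson correlation with an already-retained column
#' exceeds the threshold. Constant columns (undefined correlation) are
#' excluded with a warning.
#'
#' @param table a `feature_table` or plain data.frame of numeric columns.
#' @param threshold maximum allowed absolute pairwise correlation.
#' @return the table restricted to retained columns; attribute `dropped`
#'   names the removals.
#' @export
collinearity_screen <- function(table, threshold = 0.95) {
  cols <- feature_columns(table)
  if (length(cols) < 2L) stop("need at least two feature columns")
  constant <- cols[vapply(cols, function(cn)
    stats::sd(table[[cn]], na.rm = TRUE) == 0, logical(1))]
  if (length(constant)) {
    warning("constant column(s) excluded: ", paste(constant, collapse = ", "))
    cols <- setdiff(cols, constant)
  }
  kept <- character(0)
  dropped <- constant
  for (cn in cols) {
    r <- if (length(kept))
      suppressWarnings(abs(stats::cor(table[[cn]],
                                      as.matrix(table[kept]),
                                      use = "pairwise.complete.obs")))
    else 0
    if (any(r > threshold, na.rm = TRUE)) dropped <- c(dropped, cn)
    else kept <- c(kept, cn)
  }
  out <- table[, c(intersect(c("plot_id"), names(table)), kept,
                   intersect(c("complete"), names(table))), drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
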