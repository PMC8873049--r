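#' Stationary Gaussian random field on a grid
#'
#' Smooth mean-zero random field built by circular FFT convolution of white
#' noise with a Gaussian kernel. The kernel is normalized so each cell has
#' variance `sill` exactly; `range` is the kernel standard deviation in map
#' units (correlation decays on that length scale). The grid is padded by
#' three kernel widths before the FFT so wrap-around correlation is
#' negligible. Reproducible by seed.
#'
#' @param geometry target [grid_geometry()].
#' @param range correlation length, map units (> 0).
#' @param sill marginal variance.
#' @param seed integer seed.
#' @return [grid_surface()].
#' @export
gaussian_random_field <- function(geometry, range, sill = 1, seed = 1) {
  g <- geometry_of(geometry)
  stopifnot(range > 0, sill >= 0)
  if (sill == 0)
    return(grid_surface(matrix(0, g$nrow, g$ncol), g$cellsize, g$xll, g$yll))
  s_cells <- range / g$cellsize
  pad <- ceiling(3 * s_cells)
  P <- g$nrow + 2 * pad; Q <- g$ncol + 2 * pad
  # wrapped squared distances for the circulant kernel
  di <- pmin(0:(P - 1), P - (0:(P - 1)))
  dj <- pmin(0:(Q - 1), Q - (0:(Q - 1)))
  kern <- exp(-outer(di^2, dj^2, "+") / (2 * s_cells^2))
  kern <- kern / sqrt(sum(kern^2))
  set.seed(seed)
  noise <- matrix(stats::rnorm(P * Q), P, Q)
  conv <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (P * Q)
  field <- sqrt(sill) * conv[seq_len(g$nrow), seq_len(g$ncol)]
  grid_surface(field, g$cellsize, g$xll, g$yll)
}

#' Configuration of the synthetic landscape
#'
#' The generator emulates the covariate structure of a high-plateau
#' grassland study area: an elevation field with a regional trend; climate
#' (mean annual temperature and precipitation) driven by elevation plus
#' local variation; a greenness latent field responding to climate that
#' produces the reflectance bands; and three true diversity surfaces that
#' respond to greenness linearly, through a greenness-by-precipitation
#' interaction, and through a unimodal temperature term, plus a spatially
#' autocorrelated component that no covariate carries (the part only
#' spatial fusion can recover). Defaults: 60 x 60 cells of 30 m, elevation
#' ~3900 m with a 0.6 degC / 100 m lapse, diversity ranges matching an
#' alpine-meadow survey (richness ~10-31 species/m2, Shannon ~1-2.8 nats).
#'
#' @param nrow,ncol,cellsize,xll,yll grid geometry.
#' @param field_range correlation length of all random fields, map units.
#' @param elev_sd,temp_noise_sd,precip_noise_sd,green_noise_sd local
#'   variability of the covariate fields.
#' @param sr_noise_sd,sh_noise_sd spatially correlated residual sd of the
#'   true richness and Shannon surfaces (the ecological-diversity surface
#'   inherits both, being a deterministic transform of them).
#' @param band_noise_sd reflectance noise.
#' @param seed integer seed.
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 60, ncol = 60, cellsize = 30,
                             xll = 0, yll = 0, field_range = 450,
                             elev_sd = 120, temp_noise_sd = 0.3,
                             precip_noise_sd = 15, green_noise_sd = 0.35,
                             sr_noise_sd = 2.5, sh_noise_sd = 0.35,
                             band_noise_sd = 0.004, seed = 1) {
  structure(as.list(environment()), class = "landscape_config")
}

#' Generate a synthetic landscape
#'
#' Builds the full covariate [band_stack()] (seven reflectance bands, six
#' vegetation indices, five terrain derivatives, temperature, precipitation,
#' above-ground biomass) and the three true diversity surfaces, per
#' [landscape_config()]. Terrain derivatives are nodata on the outer cell
#' ring, so usable plots live in the interior.
#'
#' @param config a [landscape_config()].
#' @return list: `stack` (band_stack), `truth` (list of `SR`, `SH`, `ED`
#'   [grid_surface()]s), `config`.
#' @export
synthetic_landscape <- function(config = landscape_config()) {
  cf <- config
  g <- grid_geometry(cf$nrow, cf$ncol, cf$cellsize, cf$xll, cf$yll)
  grf <- function(sill, k)
    gaussian_random_field(g, cf$field_range, sill, seed = cf$seed + k)$values
  cc <- cell_centers(g)
  X <- matrix(cc$x, g$nrow, g$ncol, byrow = TRUE)
  xs <- (X - mean(cc$x)) / (g$ncol * g$cellsize)     # -0.5..0.5 across grid

  elev <- 3924 + 500 * xs + grf(cf$elev_sd^2, 1)
  temp <- 1.8 - 0.006 * (elev - 3924) + grf(cf$temp_noise_sd^2, 2)
  precip <- 626 - 0.15 * (elev - 3924) + grf(cf$precip_noise_sd^2, 3)

  ts <- (temp - 1.8) / 1.5
  ps <- (precip - 626) / 40
  green <- stats::plogis(0.9 * ts + 0.5 * ps + grf(cf$green_noise_sd^2, 4))
  agb <- 80 + 120 * (green - 0.5) + grf(8^2, 5)

  bn <- function(k) grf(cf$band_noise_sd^2, 10 + k)
  clip01 <- function(v) pmin(pmax(v, 0.003), 1)
  bands <- list(
    coastal = clip01(0.050 - 0.020 * green + bn(1)),
    blue    = clip01(0.060 - 0.030 * green + bn(2)),
    green   = clip01(0.090 - 0.030 * green + bn(3)),
    red     = clip01(0.120 - 0.070 * green + bn(4)),
    NIR     = clip01(0.150 + 0.250 * green + bn(5)),
    SWIR1   = clip01(0.200 - 0.100 * green + bn(6)),
    SWIR2   = clip01(0.150 - 0.090 * green + bn(7)))
  mk <- function(v) grid_surface(v, g$cellsize, g$xll, g$yll)
  band_layers <- lapply(bands, mk)

  zs <- 2 * green - 1
  sr_det <- 9 + 4 * zs + 8 * exp(-((temp - 2.2) / 0.5)^2) +
    5 * (green > 0.55) + 3 * (precip > 645) + 3 * zs * pmax(ps, 0)
  sr_true <- pmax(sr_det + grf(cf$sr_noise_sd^2, 6), 4)
  sh_true <- 2.0 + 0.7 * (sr_det - 17) / 6 + grf(cf$sh_noise_sd^2, 7)
  sh_true <- pmin(pmax(sh_true, 0.6), 0.95 * log(pmax(round(sr_true), 3)))
  # ED truth consistent with the community model: a quadrat at this cell has
  # round(SR) species with symmetric-Dirichlet cover (concentration matched
  # to the Shannon target), so the expected ED follows from
  # E[sqrt(p_i)] = Gamma(a + 1/2) Gamma(k a) / (Gamma(a) Gamma(k a + 1/2))
  ed_true <- matrix(mapply(function(sh, k) {
    a <- shannon_to_alpha(sh, k)
    esqrtp <- exp(lgamma(a + 0.5) + lgamma(k * a) -
                    lgamma(a) - lgamma(k * a + 0.5))
    log(k * esqrtp)^2 / log(exp(1) + 1)
  }, sh_true, pmax(round(sr_true), 3)), nrow(sh_true), ncol(sh_true))

  vi <- vegetation_indices(band_stack(band_layers))
  terr <- terrain_derivatives(mk(elev))
  stack <- band_stack(c(band_layers, unclass(vi),
                        unclass(terr)[c("slope", "aspect", "plan_curvature",
                                        "profile_curvature")],
                        list(elevation = mk(elev), temperature = mk(temp),
                             precipitation = mk(precip), AGB = mk(agb))))
  list(stack = stack,
       truth = list(SR = mk(sr_true), SH = mk(sh_true), ED = mk(ed_true)),
       config = cf)
}

# expected Shannon index of a symmetric Dirichlet(alpha) community of k
# species: digamma(k * alpha + 1) - digamma(alpha + 1)
dirichlet_shannon_mean <- function(alpha, k) {
  digamma(k * alpha + 1) - digamma(alpha + 1)
}

# concentration whose expected Shannon matches the target (target clamped
# into the attainable band (0, ln k))
shannon_to_alpha <- function(target, k) {
  lo <- 0.02 * log(k); hi <- 0.985 * log(k)
  target <- min(max(target, lo), hi)
  f <- function(la) dirichlet_shannon_mean(exp(la), k) - target
  exp(stats::uniroot(f, c(-6, 10), tol = 1e-10)$root)
}

#' Generate a synthetic quadrat survey
#'
#' Samples plot locations on the landscape (interior cells only, one plot
#' per cell) and emits raw species-cover records so the index pipeline is
#' exercised end to end. Per quadrat, the species count is the true
#' richness at the plot cell plus uniform jitter on ±2 (rounded, min 3),
#' and the cover vector is a symmetric Dirichlet draw whose concentration
#' is solved so the expected Shannon index matches the true Shannon surface
#' at the cell.
#'
#' @param landscape output of [synthetic_landscape()].
#' @param n_plots number of plots (default 36).
#' @param quadrats_per_plot quadrats of 1 m2 per plot (default 3).
#' @param seed integer seed.
#' @return a `plot_survey` (see [read_survey()]).
#' @export
synthetic_survey <- function(landscape, n_plots = 36, quadrats_per_plot = 3,
                             seed = 1) {
  g <- geometry_of(landscape$truth$SR)
  margin <- 2L
  rows <- seq(margin + 1L, g$nrow - margin)
  cols <- seq(margin + 1L, g$ncol - margin)
  cells <- expand.grid(row = rows, col = cols)
  if (n_plots > nrow(cells)) stop("n_plots exceeds available interior cells")
  set.seed(seed)
  pick <- cells[sample.int(nrow(cells), n_plots), ]
  cc <- cell_centers(g)
  recs <- vector("list", n_plots * quadrats_per_plot)
  ri <- 0L
  for (p in seq_len(n_plots)) {
    row <- pick$row[p]; col <- pick$col[p]
    sr_t <- landscape$truth$SR$values[row, col]
    sh_t <- landscape$truth$SH$values[row, col]
    for (q in seq_len(quadrats_per_plot)) {
      k <- max(3L, as.integer(round(sr_t + stats::runif(1, -2, 2))))
      alpha <- shannon_to_alpha(sh_t, k)
      props <- stats::rgamma(k, shape = alpha)
      props <- props / sum(props)
      total <- stats::runif(1, 40, 90)
      ri <- ri + 1L
      recs[[ri]] <- data.frame(
        plot_id = sprintf("plot%02d", p),
        quadrat_id = sprintf("q%d", q),
        x = cc$x[col], y = cc$y[row],
        area_m2 = 1,
        species = sprintf("sp%03d", seq_len(k)),
        cover = total * props)
    }
  }
  df <- do.call(rbind, recs)
  as_plot_survey(df)
}

#' Assemble the plot-level modeling table of a study
#'
#' Joins the plot-level diversity indices computed from the survey with the
#' covariates extracted from the stack at the plot locations. Rows with
#' nodata features are dropped with a warning.
#'
#' @param survey a `plot_survey`.
#' @param stack a [band_stack()].
#' @return data.frame: `plot_id`, `x`, `y`, `SR`, `SH`, `ED`, one column
#'   per layer.
#' @export
build_plot_table <- function(survey, stack) {
  idx <- plot_indices(survey)
  feats <- extract_at_plots(stack, idx)
  out <- merge(idx, feats, by = "plot_id", sort = FALSE)
  if (!all(out$complete)) {
    warning("dropping plot(s) with nodata features: ",
            paste(out$plot_id[!out$complete], collapse = ", "))
    out <- out[out$complete, , drop = FALSE]
  }
  out$complete <- NULL
  rownames(out) <- NULL
  out
}

#' One-call synthetic comparative study input
#'
#' Generates a landscape and survey from one seed and returns everything
#' [repeated_holdout()] needs.
#'
#' @param seed integer study seed.
#' @param config a [landscape_config()] (its `seed` is overridden).
#' @param n_plots,quadrats_per_plot survey size.
#' @return list: `plot_table`, `stack`, `truth`, `survey`.
#' @export
synthetic_study <- function(seed = 1, config = landscape_config(),
                            n_plots = 36, quadrats_per_plot = 3) {
  config$seed <- as.integer(seed) * 1000L
  land <- synthetic_landscape(config)
  survey <- synthetic_survey(land, n_plots, quadrats_per_plot,
                             seed = config$seed + 500L)
  list(plot_table = build_plot_table(survey, land$stack),
       stack = land$stack, truth = land$truth, survey = survey)
}
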