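# shared fixture builders; everything is generated in code, no stored data

# constraints at given cells sampled from a surface
constraints_from <- function(surface, rows, cols) {
  constraint_set(rows, cols, surface$values[cbind(rows, cols)])
}

# random constraint set on an n x n grid
random_constraints <- function(n, ncons, seed) {
  set.seed(seed)
  cells <- sample.int(n * n, ncons)
  constraint_set((cells - 1) %/% n + 1, (cells - 1) %% n + 1,
                 stats::rnorm(ncons))
}

# dense brute-force KKT solution of min ||Mx - r||^2 s.t. Sx = k, built
# independently of the package solver (base R linear algebra only)
dense_kkt_oracle <- function(system) {
  M <- as.matrix(rbind(system$A, system$B, system$C))
  r <- c(system$d, system$q, system$h)
  S <- as.matrix(system$S)
  ncons <- nrow(S)
  KKT <- rbind(cbind(2 * crossprod(M), t(S)),
               cbind(S, matrix(0, ncons, ncons)))
  sol <- solve(KKT, c(2 * crossprod(M, r), system$k))
  sol[seq_len(ncol(M))]
}

# small quadrat survey built by hand (2 plots x 2 quadrats)
tiny_survey <- function() {
  as_plot_survey(data.frame(
    plot_id = rep(c("p1", "p2"), each = 4),
    quadrat_id = rep(c("q1", "q1", "q2", "q2"), 2),
    x = rep(c(15, 45), each = 4), y = rep(c(45, 15), each = 4),
    area_m2 = 1,
    species = c("a", "b", "a", "c", "a", "b", "b", "c"),
    cover = c(2, 2, 5, 5, 1, 3, 4, 4)))
}

# uniform reflectance band stack on a small grid
tiny_bands <- function(n = 5, nir = 0.4, red = 0.1, blue = 0.05,
                       green = 0.08, swir1 = 0.2) {
  g <- grid_geometry(n, n, 30)
  mk <- function(v) grid_surface(matrix(v, n, n), 30)
  band_stack(list(blue = mk(blue), green = mk(green), red = mk(red),
                  NIR = mk(nir), SWIR1 = mk(swir1)))
}

# small fast synthetic study for pipeline tests
small_study <- function(seed = 1, n_plots = 20) {
  cfg <- landscape_config(nrow = 30, ncol = 30, field_range = 240,
                          seed = seed * 1000L)
  land <- synthetic_landscape(cfg)
  survey <- synthetic_survey(land, n_plots = n_plots, seed = seed * 1000L + 500L)
  list(plot_table = build_plot_table(survey, land$stack),
       stack = land$stack, truth = land$truth, survey = survey)
}
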