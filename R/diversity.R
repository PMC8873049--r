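#' Normalize species covers to proportions
#'
#' Converts raw cover/abundance values of one quadrat community to
#' proportional cover. Zero covers are dropped (the `0 * log 0` limit) and
#' the remainder divided by their sum, so the result is a valid probability
#' vector over the species actually present.
#'
#' @param covers non-negative numeric vector of cover values; names (species)
#'   are preserved.
#' @return numeric vector of proportions summing to 1, all entries > 0.
#' @export
normalize_abundances <- function(covers) {
  covers <- as.numeric_checked(covers, "covers")
  if (any(covers < 0)) stop("negative cover values are not allowed")
  covers <- covers[covers > 0]
  if (length(covers) == 0L) stop("empty community: no positive cover values")
  covers / sum(covers)
}

as.numeric_checked <- function(x, what) {
  if (length(x) == 0L) stop("empty community: no ", what)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("non-finite ", what)
  x
}

#' Species richness per unit area
#'
#' Richness is the number of species observed in a quadrat divided by the
#' quadrat area, so values from quadrats of different sizes are comparable.
#'
#' @param n non-negative integer species count.
#' @param area_m2 quadrat area in square metres (> 0).
#' @return richness, species per m².
#' @export
species_richness <- function(n, area_m2 = 1) {
  stopifnot(length(n) == 1L, length(area_m2) == 1L)
  if (!is.finite(n) || n < 0 || n != round(n))
    stop("n must be a non-negative integer")
  if (!is.finite(area_m2) || area_m2 <= 0) stop("area must be positive")
  n / area_m2
}

#' Shannon diversity index
#'
#' `H' = -sum(p_i * ln(p_i))` in nats, over the proportional covers of the
#' species present. Bounded by `ln(n)`, attained for a perfectly even
#' community.
#'
#' @param p proportions from [normalize_abundances()] (must sum to 1, all
#'   entries positive).
#' @return Shannon index, nats.
#' @export
shannon_index <- function(p) {
  p <- check_proportions(p)
  -sum(p * log(p))
}

check_proportions <- function(p) {
  p <- as.numeric_checked(p, "proportions")
  if (any(p <= 0)) stop("proportions must be strictly positive")
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")
  p
}

#' Ecological diversity index
#'
#' A joint richness-and-evenness index:
#' `ED = (ln(sum(sqrt(p_i))))^2 / ln(e + A)` with `A` the quadrat area in
#' m². The numerator grows with both the number of species and their
#' evenness (for a perfectly even community of `n` species it equals
#' `(ln(n) / 2)^2`); the denominator normalizes by quadrat area. Zero for a
#' single-species quadrat, and non-negative always.
#'
#' @param p proportions from [normalize_abundances()].
#' @param area_m2 quadrat area in m² (> 0).
#' @return ecological diversity (dimensionless).
#' @export
ecological_diversity <- function(p, area_m2 = 1) {
  p <- check_proportions(p)
  if (!is.finite(area_m2) || area_m2 <= 0) stop("area must be positive")
  log(sum(sqrt(p)))^2 / log(exp(1) + area_m2)
}

#' Diversity indices of one quadrat
#'
#' @param covers raw cover values of a quadrat community.
#' @param area_m2 quadrat area in m².
#' @return named numeric vector `c(SR, SH, ED)`.
#' @export
quadrat_indices <- function(covers, area_m2 = 1) {
  p <- normalize_abundances(covers)
  c(SR = species_richness(length(p), area_m2),
    SH = shannon_index(p),
    ED = ecological_diversity(p, area_m2))
}

#' Aggregate quadrat indices to the plot level
#'
#' Plot-level indices are the arithmetic mean of the per-quadrat index
#' values (the survey design places several 1 m² quadrats in each plot).
#'
#' @param quadrat_triples a matrix or data.frame with columns `SR`, `SH`,
#'   `ED`, one row per quadrat, or a list of such rows.
#' @return named numeric vector `c(SR, SH, ED)`.
#' @export
aggregate_plot <- function(quadrat_triples) {
  if (is.list(quadrat_triples) && !is.data.frame(quadrat_triples))
    quadrat_triples <- do.call(rbind, quadrat_triples)
  m <- as.matrix(quadrat_triples)
  if (nrow(m) == 0L) stop("no quadrats to aggregate")
  if (!all(c("SR", "SH", "ED") %in% colnames(m)))
    stop("quadrat triples must have columns SR, SH, ED")
  colMeans(m[, c("SR", "SH", "ED"), drop = FALSE])
}

#' Plot-level diversity indices from a survey
#'
#' Runs the full index pipeline over a quadrat survey: per-quadrat
#' proportions, SR/SH/ED per quadrat, then the quadrat mean per plot.
#'
#' @param survey a `plot_survey` (see [read_survey()]).
#' @return data.frame with one row per plot: `plot_id`, `x`, `y`, `SR`,
#'   `SH`, `ED`.
#' @export
plot_indices <- function(survey) {
  plots <- survey_plots(survey)
  rows <- lapply(plots$plot_id, function(pid) {
    sub <- survey[survey$plot_id == pid, , drop = FALSE]
    tri <- t(vapply(split(sub, sub$quadrat_id), function(q)
      quadrat_indices(q$cover, q$area_m2[1]), numeric(3)))
    aggregate_plot(tri)
  })
  cbind(plots[, c("plot_id", "x", "y")],
        as.data.frame(do.call(rbind, rows)))
}
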