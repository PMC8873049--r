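#' Mean absolute error and root mean square error
#'
#' `MAE = mean(|pred - obs|)`, `RMSE = sqrt(mean((pred - obs)^2))`. By
#' Jensen's inequality `MAE <= RMSE`; the function asserts this on every
#' call.
#'
#' @param pred,obs equal-length numeric vectors, `m >= 1`.
#' @return named vector `c(MAE, RMSE)`.
#' @export
error_metrics <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs differ in length")
  if (!length(pred)) stop("empty evaluation")
  if (anyNA(pred) || anyNA(obs)) stop("NA in evaluation vectors")
  e <- pred - obs
  mae <- mean(abs(e))
  rmse <- sqrt(mean(e^2))
  stopifnot(mae <= rmse + 1e-12)
  c(MAE = mae, RMSE = rmse)
}

#' Correlation table between diversity indices and explanatory variables
#'
#' Pairwise Pearson correlations of each index column against each feature
#' column, with two-sided p-values from the t distribution on `m - 2`
#' degrees of freedom and the usual significance stars (`*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001). Constant columns give `NA`.
#'
#' @param indices data.frame of index values (e.g. `SR`, `SH`, `ED`).
#' @param features data.frame of explanatory variables (same rows).
#' @return data.frame: `variable`, then per index `r_<index>`,
#'   `p_<index>`, `stars_<index>`; rows ordered by decreasing |r| of the
#'   first index.
#' @export
pearson_table <- function(indices, features) {
  indices <- as.data.frame(indices)
  features <- as.data.frame(features)
  m <- nrow(indices)
  if (m != nrow(features)) stop("indices and features differ in rows")
  if (m < 3) stop("need at least 3 complete rows")
  out <- data.frame(variable = names(features))
  for (ix in names(indices)) {
    r <- vapply(names(features), function(fn) {
      if (stats::sd(features[[fn]]) == 0 || stats::sd(indices[[ix]]) == 0)
        return(NA_real_)
      stats::cor(indices[[ix]], features[[fn]])
    }, numeric(1))
    tstat <- r * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = m - 2)
    stars <- ifelse(is.na(p), "",
             ifelse(p < 0.001, "***",
             ifelse(p < 0.01, "**",
             ifelse(p < 0.05, "*", ""))))
    out[[paste0("r_", ix)]] <- r
    out[[paste0("p_", ix)]] <- p
    out[[paste0("stars_", ix)]] <- stars
  }
  first <- paste0("r_", names(indices)[1])
  out <- out[order(-abs(out[[first]])), ]
  rownames(out) <- NULL
  out
}

#' Repeated random-holdout comparison of the mapping methods
#'
#' The evaluation protocol of the comparative study: in each repeat, a
#' random `train_fraction` of the plots (plot-level, never quadrat-level,
#' so quadrats of one plot cannot straddle the split) trains every method;
#' the held-out plots score it by MAE and RMSE. HASM variants are scored by
#' reading the fused surface at the validation plot cells, so validation
#' observations never enter the learner fit nor the HASM constraint set.
#' Each base learner is fitted once per repeat and index and shared by its
#' plain and HASM variants.
#'
#' @param plot_table data.frame with `plot_id`, `x`, `y`, the index columns,
#'   and one column per feature.
#' @param stack [band_stack()] of the feature layers.
#' @param methods subset of [method_ids()].
#' @param indices index columns to evaluate (default `SR`, `SH`, `ED`).
#' @param config a [study_config()]; repeat `r` uses seed `config$seed + r - 1`.
#' @return `method_report`: data.frame with one row per repeat x method x
#'   index (`repeat_`, `method`, `index`, `MAE`, `RMSE`, `n_val`) and
#'   attribute `summary` (mean MAE/RMSE per method x index).
#' @export
repeated_holdout <- function(plot_table, stack, methods = method_ids(),
                             indices = c("SR", "SH", "ED"),
                             config = study_config()) {
  stopifnot(all(methods %in% method_ids()),
            all(indices %in% names(plot_table)))
  features <- intersect(stack_names(stack), names(plot_table))
  if (!length(features)) stop("no feature columns shared with the stack")
  n <- nrow(plot_table)
  n_train <- round(config$train_fraction * n)
  if (n_train >= n) stop("validation set is empty")
  base_needed <- unique(vapply(methods, base_learner_of, character(1)))
  rows <- list()
  for (r in seq_len(config$repeats)) {
    seed_r <- config$seed + r - 1L
    set.seed(seed_r)
    tr_idx <- sort(sample.int(n, n_train))
    va_idx <- setdiff(seq_len(n), tr_idx)
    for (ix in indices) {
      train <- cbind(plot_table[tr_idx, c("plot_id", "x", "y", features)],
                     obs = plot_table[[ix]][tr_idx])
      val <- plot_table[va_idx, , drop = FALSE]
      obs_val <- plot_table[[ix]][va_idx]
      for (bl in base_needed) {
        model <- fit_base_learner(bl, train, features, config, seed_r)
        driver <- predict_raster(model, stack)
        rc <- xy_to_cell(driver, val$x, val$y)
        pred_plain <- driver$values[cbind(rc$row, rc$col)]
        if (bl %in% methods)
          rows[[length(rows) + 1L]] <-
            report_row(r, bl, ix, pred_plain, obs_val, seed_r)
        hm <- paste0("hasm_", bl)
        if (hm %in% methods) {
          fused <- hasm_fuse(driver, train, hasm = config$hasm,
                             mode = config$fusion_mode,
                             clip_at = config$clip_at)
          pred_f <- fused$values[cbind(rc$row, rc$col)]
          rows[[length(rows) + 1L]] <-
            report_row(r, hm, ix, pred_f, obs_val, seed_r)
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  summary <- stats::aggregate(cbind(MAE, RMSE) ~ method + index, report, mean)
  structure(report, summary = summary,
            class = c("method_report", "data.frame"))
}

report_row <- function(r, method, index, pred, obs, seed) {
  em <- error_metrics(pred, obs)
  data.frame(repeat_ = r, method = method, index = index,
             MAE = em[["MAE"]], RMSE = em[["RMSE"]],
             n_val = length(obs), seed = seed)
}

#' @export
print.method_report <- function(x, digits = 2, ...) {
  s <- attr(x, "summary")
  cat(sprintf("method_report: %d repeats, %d methods, %d indices\n",
              max(x$repeat_), length(unique(x$method)),
              length(unique(x$index))))
  wide <- stats::reshape(s, idvar = "method", timevar = "index",
                         direction = "wide")
  print(format(wide, digits = digits, nsmall = digits), row.names = FALSE)
  invisible(x)
}

#' Mean errors per method and index
#' @param report a `method_report`.
#' @return data.frame `method`, `index`, `MAE`, `RMSE` (means over repeats).
#' @export
report_summary <- function(report) attr(report, "summary")
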