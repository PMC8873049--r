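#' Read and write single-band rasters (ESRI ASCII grid)
#'
#' Plain-text raster I/O in the ArcInfo ASCII grid dialect: a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of cell values, north row first.
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces double-precision values exactly.
#'
#' @param path file path.
#' @return `read_raster` returns a [grid_surface()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && tolower(parts[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
          "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[key]])) stop("ASCII grid header missing '", key, "'")
  body <- paste(lines[(i + 1L):length(lines)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, expected %d x %d",
                 length(vals), nr, nc))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  grid_surface(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner)
}

#' @rdname read_raster
#' @param surface a [grid_surface()].
#' @param nodata sentinel written for `NA` cells.
#' @export
write_raster <- function(surface, path, nodata = -9999) {
  stopifnot(inherits(surface, "grid_surface"))
  v <- surface$values
  g <- geometry_of(surface)
  hdr <- c(sprintf("ncols %d", g$ncol),
           sprintf("nrows %d", g$nrow),
           sprintf("xllcorner %.17g", g$xll),
           sprintf("yllcorner %.17g", g$yll),
           sprintf("cellsize %.17g", g$cellsize),
           sprintf("NODATA_value %.17g", nodata))
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a quadrat survey table
#'
#' Reads the species-cover survey CSV with columns `plot_id`, `quadrat_id`,
#' `x`, `y`, `area_m2`, `species`, `cover`. Rows with negative or missing
#' cover are dropped and reported; duplicated (plot, quadrat, species)
#' records are an error.
#'
#' @param path CSV file path.
#' @return A `plot_survey`: data.frame of validated records with attribute
#'   `validation` (data.frame of dropped rows and reasons).
#' @examples
#' sv <- read_survey(system.file("extdata", "example_survey_synthetic.csv",
#'                               package = "psdmap"))
#' head(plot_indices(sv))
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_plot_survey(df)
}

#' @rdname read_survey
#' @param df a data.frame of survey records (same columns as the CSV).
#' @export
as_plot_survey <- function(df) {
  required <- c("plot_id", "quadrat_id", "x", "y", "area_m2", "species",
                "cover")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("survey is missing column(s): ", paste(missing, collapse = ", "))
  df$cover <- as.numeric(df$cover)
  drop_neg <- !is.na(df$cover) & df$cover < 0
  drop_na <- is.na(df$cover)
  report <- data.frame(
    row = c(which(drop_neg), which(drop_na)),
    reason = c(rep("negative cover", sum(drop_neg)),
               rep("missing cover", sum(drop_na))))
  if (nrow(report)) {
    warning(nrow(report), " survey row(s) dropped (see validation report)")
    df <- df[!(drop_neg | drop_na), , drop = FALSE]
  }
  key <- paste(df$plot_id, df$quadrat_id, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    dupes <- unique(key[duplicated(key)])
    stop("duplicate (plot_id, quadrat_id, species) record(s): ",
         paste(gsub("\r", "/", utils::head(dupes, 5)), collapse = "; "))
  }
  rownames(df) <- NULL
  structure(df, validation = report, class = c("plot_survey", "data.frame"))
}

#' Plot locations of a survey
#' @param survey a `plot_survey`.
#' @return data.frame with one row per plot: `plot_id`, `x`, `y`, `area_m2`.
#' @export
survey_plots <- function(survey) {
  u <- unique(data.frame(plot_id = survey$plot_id, x = survey$x,
                         y = survey$y, area_m2 = survey$area_m2))
  if (anyDuplicated(u$plot_id))
    stop("plot(s) with inconsistent coordinates or area: ",
         paste(unique(u$plot_id[duplicated(u$plot_id)]), collapse = ", "))
  rownames(u) <- NULL
  u
}
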