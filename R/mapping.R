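#' @include AllClasses.R brillouin.R raman.R
NULL

.featureOrder <- c("nu_soft", "nu_hard", "I_soft", "I_hard",
                   "M_soft", "M_hard", "M_avg",
                   "mineral_to_matrix", "ch_moment", "heme_moment")

#' Compute per-pixel features over a whole map
#'
#' Runs [extractBrillouinFeatures()] and [extractRamanFeatures()] on every
#' pixel of a [SpectralMap-class] and assembles the results into a
#' [FeatureMap-class]: one rows-by-cols matrix per feature, with `NA`
#' marking pixels where a feature could not be computed (absent modality or
#' flagged missing feature). Pixel processing order does not affect the
#' result.
#'
#' @param map a [SpectralMap-class] with at least one usable pixel.
#' @param config an [AnalysisConfig-class].
#' @return A [FeatureMap-class] with features `nu_soft`, `nu_hard`,
#'   `I_soft`, `I_hard`, `M_soft`, `M_hard`, `M_avg`, `mineral_to_matrix`,
#'   `ch_moment`, `heme_moment`.
#' @export
mapFeatures <- function(map, config = analysisConfig()) {
  stopifnot(is(map, "SpectralMap"), is(config, "AnalysisConfig"))
  d <- mapDim(map)
  feats <- lapply(.featureOrder, function(f)
    matrix(NA_real_, nrow = d[1], ncol = d[2]))
  names(feats) <- .featureOrder
  usable <- FALSE
  for (i in seq_len(d[1]) - 1L) {
    for (j in seq_len(d[2]) - 1L) {
      sb <- getSpectrum(map, i, j, "brillouin")
      if (!is.null(sb)) {
        usable <- TRUE
        bf <- extractBrillouinFeatures(sb, config)
        for (f in names(bf)) feats[[f]][i + 1L, j + 1L] <- bf[[f]]
      }
      sr <- getSpectrum(map, i, j, "raman")
      if (!is.null(sr)) {
        usable <- TRUE
        rf <- extractRamanFeatures(sr, config)$features
        for (f in names(rf)) feats[[f]][i + 1L, j + 1L] <- rf[[f]]
      }
    }
  }
  if (!usable)
    stop("no usable pixels in the map")
  new("FeatureMap", features = feats, step = map@step, origin = map@origin)
}

#' Define a rectangular region of interest
#'
#' Axis-aligned rectangle in 0-based pixel indices, inclusive of the `lo`
#' edges and exclusive of the `hi` edges (so `roi("a", 0, 4, 0, 4)` covers a
#' 4 x 4 block).
#'
#' @param id ROI label.
#' @param rowLo,rowHi,colLo,colHi pixel index bounds (lo inclusive, hi
#'   exclusive).
#' @return A one-row data.frame with columns `id`, `row_lo`, `row_hi`,
#'   `col_lo`, `col_hi`.
#' @export
roi <- function(id, rowLo, rowHi, colLo, colHi) {
  stopifnot(rowLo >= 0, colLo >= 0, rowHi > rowLo, colHi > colLo)
  data.frame(id = as.character(id), row_lo = as.integer(rowLo),
             row_hi = as.integer(rowHi), col_lo = as.integer(colLo),
             col_hi = as.integer(colHi), stringsAsFactors = FALSE)
}

.roiCells <- function(fmap, r) {
  d <- mapDim(fmap)
  rows <- seq(max(r$row_lo, 0L), min(r$row_hi, d[1]) - 1L)
  cols <- seq(max(r$col_lo, 0L), min(r$col_hi, d[2]) - 1L)
  if (r$row_lo >= d[1] || r$col_lo >= d[2] ||
      length(rows) == 0L || length(cols) == 0L)
    stop("ROI '", r$id, "' does not intersect the grid")
  list(rows = rows + 1L, cols = cols + 1L)
}

#' Per-feature statistics over a region of interest
#'
#' For every feature of a [FeatureMap-class], summarises the unmasked pixels
#' falling inside the ROI rectangle: count, mean, standard deviation,
#' standard error of the mean (SD / sqrt(n)), quartiles, and a histogram with
#' `config@histogramBins` equal-width bins over the observed range. Features
#' with no unmasked pixel in the ROI are omitted with a warning.
#'
#' @param fmap a [FeatureMap-class].
#' @param r a one-row ROI data.frame (see [roi()]).
#' @param config an [AnalysisConfig-class].
#' @return A list with elements `id`, `n` (pixels in the rectangle) and
#'   `features`: a named list, each entry holding `n`, `mean`, `sd`, `sem`,
#'   `quartiles` (0/25/50/75/100%), and `histogram` (`breaks`, `counts`).
#' @export
roiStatistics <- function(fmap, r, config = analysisConfig()) {
  stopifnot(is(fmap, "FeatureMap"))
  cells <- .roiCells(fmap, r)
  out <- list()
  for (f in featureNames(fmap)) {
    vals <- fmap@features[[f]][cells$rows, cells$cols]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      warning("feature '", f, "' fully masked in ROI '", r$id, "'; omitted")
      next
    }
    n <- length(vals)
    sd <- if (n > 1L) stats::sd(vals) else 0
    rng <- range(vals)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = config@histogramBins + 1L)
    h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
    out[[f]] <- list(n = n, mean = mean(vals), sd = sd, sem = sd / sqrt(n),
                     quartiles = stats::quantile(vals),
                     histogram = list(breaks = h$breaks, counts = h$counts))
  }
  list(id = r$id, n = length(cells$rows) * length(cells$cols),
       features = out)
}

#' Percent change between two means
#'
#' Signed relative change `100 * (comparison - reference) / reference`. The
#' attribute `"rounded"` carries the signed value rounded to the nearest
#' integer percent, the convention used when reporting comparisons.
#'
#' @param referenceMean reference value (nonzero).
#' @param comparisonMean comparison value.
#' @return Signed percent change with a `"rounded"` attribute.
#' @examples
#' percentChange(22.40, 34.20)  # about +53%
#' @export
percentChange <- function(referenceMean, comparisonMean) {
  stopifnot(is.finite(referenceMean), is.finite(comparisonMean))
  if (referenceMean == 0)
    stop("reference mean must be nonzero")
  p <- 100 * (comparisonMean - referenceMean) / referenceMean
  structure(p, rounded = round(p))
}

#' Compare two ROI summaries feature by feature
#'
#' Tabulates, for each requested feature, the two means with their standard
#' errors and the percent change from `a` to `b`. Features missing from
#' either summary are omitted with a warning.
#'
#' @param a,b ROI summaries from [roiStatistics()]; `a` is the reference.
#' @param features features to compare, in the requested row order; defaults
#'   to all features present in both summaries.
#' @return A data.frame with columns `feature`, `mean_a`, `sem_a`, `mean_b`,
#'   `sem_b`, `pct_change`, `pct_change_rounded`.
#' @export
compareROIs <- function(a, b, features = NULL) {
  if (is.null(features))
    features <- intersect(names(a$features), names(b$features))
  rows <- list()
  for (f in features) {
    if (is.null(a$features[[f]]) || is.null(b$features[[f]])) {
      warning("feature '", f, "' missing from a summary; row omitted")
      next
    }
    fa <- a$features[[f]]
    fb <- b$features[[f]]
    p <- percentChange(fa$mean, fb$mean)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, mean_a = fa$mean, sem_a = fa$sem,
      mean_b = fb$mean, sem_b = fb$sem,
      pct_change = as.numeric(p),
      pct_change_rounded = attr(p, "rounded"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read ROI definitions from a delimited file
#'
#' Expects columns `id`, `row_lo`, `row_hi`, `col_lo`, `col_hi` (tab- or
#' comma-separated, `#` comments allowed).
#'
#' @param path file path.
#' @return A data.frame of ROIs, one per row.
#' @export
readROIs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "row_lo", "row_hi", "col_lo", "col_hi")
  if (!all(need %in% names(df)))
    stop("ROI file must have columns: ", paste(need, collapse = ", "))
  df
}
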