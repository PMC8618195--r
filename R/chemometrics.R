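#' @include AllClasses.R raman.R
NULL

#' Assemble the fingerprint-region matrix for PCA
#'
#' Preprocesses the Raman spectrum of every pixel (baseline removal and
#' reference normalisation via [extractRamanFeatures()] preprocessing),
#' crops it to the fingerprint range (limits inclusive) and stacks the usable
#' pixels into a [SpectralMatrix-class], one row per pixel, labeled by ROI.
#' Pixels without a Raman spectrum or with a failed normalisation are dropped
#' and reported via a message.
#'
#' @param maps a named list of [SpectralMap-class] objects, one per ROI (the
#'   names become the ROI labels), or a single map (labeled `"map"`).
#' @param config an [AnalysisConfig-class].
#' @return A [SpectralMatrix-class]; error when fewer than 2 usable pixels
#'   remain.
#' @seealso [runPCA()]
#' @export
buildSpectralMatrix <- function(maps, config = analysisConfig()) {
  if (is(maps, "SpectralMap")) maps <- list(map = maps)
  stopifnot(is.list(maps), length(maps) > 0L,
            all(vapply(maps, is, logical(1), "SpectralMap")))
  if (is.null(names(maps)) || any(names(maps) == ""))
    stop("maps must be named by ROI")
  rows <- list()
  labels <- list()
  wn <- NULL
  dropped <- 0L
  for (roi in names(maps)) {
    m <- maps[[roi]]
    if (length(m@ramanAxis) == 0L) next
    keep <- .bandChannels(m@ramanAxis, config@fingerprintRange)
    if (is.null(wn)) {
      wn <- m@ramanAxis[keep]
    } else if (!isTRUE(all.equal(wn, m@ramanAxis[keep]))) {
      stop("inconsistent Raman axes across maps")
    }
    d <- mapDim(m)
    for (i in seq_len(d[1]) - 1L) {
      for (j in seq_len(d[2]) - 1L) {
        s <- getSpectrum(m, i, j, "raman")
        if (is.null(s)) { dropped <- dropped + 1L; next }
        flat <- removeBaseline(s, config@baselineOrder, config@baselineIters)
        norm <- tryCatch(
          normalizeToReference(flat, config@refWavenumber, config@refWindow),
          bramsMissingFeature = function(e) NULL)
        if (is.null(norm)) { dropped <- dropped + 1L; next }
        rows[[length(rows) + 1L]] <- norm@intensity[keep]
        labels[[length(labels) + 1L]] <-
          data.frame(roi = roi, x = j, y = i, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) < 2L)
    stop("fewer than 2 usable pixels for the spectral matrix")
  if (dropped > 0L)
    message(dropped, " pixel(s) dropped (missing or unusable Raman spectrum)")
  new("SpectralMatrix",
      data = do.call(rbind, rows),
      wavenumbers = wn,
      labels = do.call(rbind, labels))
}

#' Principal component analysis of a spectral matrix
#'
#' Column-mean centering (unit-variance scaling only when
#' `config@autoscale`), then singular value decomposition via
#' [stats::prcomp()]. A deterministic sign convention is applied: each
#' component is flipped, if needed, so that its largest-magnitude loading
#' weight is positive, making loadings reproducible across platforms.
#' Explained variance percentages are relative to the total column variance
#' of the (centred, possibly scaled) matrix, so retaining all components
#' always accounts for 100%.
#'
#' @param x a [SpectralMatrix-class].
#' @param nComponents number of components to retain; truncated with a
#'   warning when the matrix rank is lower.
#' @param config an [AnalysisConfig-class] (only `autoscale` is used).
#' @return A [PCAResult-class].
#' @examples
#' set.seed(1)
#' m <- new("SpectralMatrix",
#'          data = cbind(rnorm(50, sd = 3), rnorm(50, sd = 1)),
#'          wavenumbers = c(1000, 1100),
#'          labels = data.frame(roi = "a", x = seq_len(50), y = 0))
#' runPCA(m, 2)
#' @export
runPCA <- function(x, nComponents = 3L, config = analysisConfig()) {
  stopifnot(is(x, "SpectralMatrix"), nComponents >= 1L)
  maxk <- min(nrow(x@data) - 1L, ncol(x@data))
  if (nComponents > maxk)
    stop("nComponents must be <= min(rows - 1, columns)")
  pc <- stats::prcomp(x@data, center = TRUE, scale. = config@autoscale)
  ev <- pc$sdev^2
  total <- sum(ev)
  ## rank relative to the data's own magnitude, so a constant matrix
  ## (zero variance everywhere) is rank 0, not numerical noise
  ref <- mean(x@data^2)
  rank <- if (ref == 0 || total <= ref * 1e-20) 0L
          else sum(ev > total * 1e-12)
  k <- nComponents
  if (rank < k) {
    warning("matrix rank ", rank, " below requested ", k, " component(s)")
    if (rank >= 1L) k <- rank
  }
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  if (rank == 0L) {
    ev[] <- 0
    total <- 0
  }
  ## sign convention: largest-magnitude weight of each loading is positive
  for (c in seq_len(k)) {
    w <- rot[, c]
    if (w[which.max(abs(w))] < 0) {
      rot[, c] <- -w
      sco[, c] <- -sco[, c]
    }
  }
  expl <- if (total > 0) 100 * ev[seq_len(k)] / total else rep(0, k)
  dimnames(sco) <- list(NULL, paste0("PC", seq_len(k)))
  loadings <- t(rot)
  dimnames(loadings) <- list(paste0("PC", seq_len(k)), NULL)
  scale <- if (isTRUE(config@autoscale)) pc$scale
           else rep(1, ncol(x@data))
  new("PCAResult",
      loadings = loadings, scores = sco,
      explainedVariancePct = expl,
      cumulativeVariancePct = cumsum(expl),
      meanSpectrum = as.numeric(pc$center),
      scale = as.numeric(scale),
      wavenumbers = x@wavenumbers,
      labels = x@labels)
}

#' Standardized group separation along each component
#'
#' For every principal component and every group label, compares the group's
#' score mean against the pooled remainder: reports both means, the pooled
#' (within-groups) standard deviation along that component, and the
#' standardized mean separation |mean difference| / pooled SD. A component is
#' flagged as dividing a group from the rest when the standardized
#' separation exceeds the configured threshold.
#'
#' @param x a [PCAResult-class].
#' @param labels group labels, one per observation; defaults to the ROI
#'   labels carried by the result.
#' @param config an [AnalysisConfig-class] (`separationThreshold`).
#' @return A data.frame with columns `component`, `group`, `group_mean`,
#'   `rest_mean`, `pooled_sd`, `separation`, `divides`.
#' @export
groupSeparation <- function(x, labels = NULL, config = analysisConfig()) {
  stopifnot(is(x, "PCAResult"))
  if (is.null(labels)) labels <- x@labels$roi
  labels <- as.character(labels)
  if (length(labels) != nrow(x@scores))
    stop("one label per observation required")
  groups <- unique(labels)
  if (length(groups) < 2L)
    stop("at least two distinct groups required")
  out <- list()
  for (c in seq_len(ncol(x@scores))) {
    sc <- x@scores[, c]
    for (g in groups) {
      a <- sc[labels == g]
      b <- sc[labels != g]
      va <- if (length(a) > 1L) stats::var(a) else 0
      vb <- if (length(b) > 1L) stats::var(b) else 0
      pooled <- sqrt(((length(a) - 1L) * va + (length(b) - 1L) * vb) /
                       max(length(a) + length(b) - 2L, 1L))
      sep <- if (pooled > 0) abs(mean(a) - mean(b)) / pooled
             else if (isTRUE(all.equal(mean(a), mean(b)))) 0
             else Inf
      out[[length(out) + 1L]] <- data.frame(
        component = paste0("PC", c), group = g,
        group_mean = mean(a), rest_mean = mean(b),
        pooled_sd = pooled, separation = sep,
        divides = sep > config@separationThreshold,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
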