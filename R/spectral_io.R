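#' @include AllClasses.R constructors.R mapping.R
NULL

## Delimited-text plumbing: TAB default, comma accepted, '#' comments.
.readDelim <- function(path, header = TRUE) {
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))]
  sep <- if (length(first) > 0L && grepl(",", first[1], fixed = TRUE)) ","
         else ""
  utils::read.table(path, header = header, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, blank.lines.skip = TRUE)
}

.fmtNum <- function(x) {
  # 6 significant digits on write, below all stated tolerances
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

#' Read a spectrum from two-column delimited text
#'
#' The format is two columns (axis, intensity), TAB or comma separated, with
#' optional `#`-prefixed header lines. Recognised header metadata:
#' `# modality: brillouin|raman` and `# position: x y` (micrometres). A
#' non-monotone axis or a negative intensity is a format error; the latter
#' names the offending line.
#'
#' @param path file path.
#' @param modality fallback modality when the header carries none.
#' @return A validated [Spectrum-class].
#' @seealso [writeSpectrum()]
#' @export
readSpectrum <- function(path, modality = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(trimws(lines), "#")]
  meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*:", key), hdr, value = TRUE)
    if (length(m) == 0L) return(NULL)
    trimws(sub(sprintf("^#\\s*%s\\s*:", key), "", m[1]))
  }
  mod <- meta("modality")
  if (is.null(mod)) mod <- modality
  if (is.null(mod))
    stop("modality not in file header; pass it explicitly")
  pos <- meta("position")
  pos <- if (is.null(pos)) c(NA_real_, NA_real_)
         else as.numeric(strsplit(pos, "[,[:space:]]+")[[1]][1:2])
  body <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  if (length(body) == 0L)
    stop("format error: no data rows in ", path)
  sep <- if (grepl(",", lines[body[1]], fixed = TRUE)) "[,[:space:]]+"
         else "[[:space:]]+"
  parts <- strsplit(trimws(lines[body]), sep)
  if (any(lengths(parts) < 2L))
    stop("format error: expected two columns (axis, intensity)")
  axis <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  inten <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (anyNA(axis) || anyNA(inten))
    stop("format error: non-numeric value in ", path)
  if (any(diff(axis) <= 0))
    stop("format error: axis not strictly increasing in ", path)
  bad <- which(inten < 0)
  if (length(bad) > 0L)
    stop("format error: negative intensity at line ", body[bad[1]],
         " of ", path)
  spectrum(axis, inten, mod, position = pos)
}

#' Write a spectrum as two-column delimited text
#'
#' Writes `#` header lines carrying the modality (and position when known)
#' followed by TAB-separated (axis, intensity) rows at 6 significant digits.
#' `readSpectrum(writeSpectrum(s))` reproduces the values to that precision.
#'
#' @param x a [Spectrum-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(x, path) {
  stopifnot(is(x, "Spectrum"))
  hdr <- sprintf("# modality: %s", x@modality)
  if (!anyNA(x@position))
    hdr <- c(hdr, sprintf("# position: %.6g %.6g",
                          x@position[1], x@position[2]))
  rows <- paste(.fmtNum(x@axis), .fmtNum(x@intensity), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

.writeSidecar <- function(map, path) {
  yaml::write_yaml(list(step = map@step,
                        origin = as.numeric(map@origin),
                        nrow = map@nrow, ncol = map@ncol), path)
}

.readSidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  yaml::read_yaml(path)
}

#' Write a spectral map
#'
#' Two on-disk dialects share a YAML metadata sidecar (grid step, origin,
#' shape):
#' \describe{
#'   \item{`"long"`}{one delimited table with columns `x`, `y`, `modality`,
#'     `axis_value`, `intensity` (one row per channel), sidecar at
#'     `<path>.meta.yaml`. Convenient for small fixtures.}
#'   \item{`"dir"`}{a directory holding `index.tsv` (columns `x`, `y`,
#'     `brillouin_file`, `raman_file`; `NA` marks an absent modality),
#'     per-pixel spectrum files, and `metadata.yaml`. Mirrors instrument
#'     output.}
#' }
#' `x`/`y` are 0-based pixel column/row indices; stage positions follow from
#' `origin + index * step`.
#'
#' @param map a [SpectralMap-class].
#' @param path output file (`"long"`) or directory (`"dir"`).
#' @param format `"long"` or `"dir"`.
#' @return `path`, invisibly.
#' @seealso [readMap()]
#' @export
writeMap <- function(map, path, format = c("long", "dir")) {
  stopifnot(is(map, "SpectralMap"))
  format <- match.arg(format)
  if (format == "long") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# brams spectral map (long format)", con)
    writeLines(paste("x", "y", "modality", "axis_value", "intensity",
                     sep = "\t"), con)
    for (m in c("brillouin", "raman")) {
      mat <- slot(map, m)
      if (ncol(mat) == 0L) next
      axis <- if (m == "brillouin") map@brillouinAxis else map@ramanAxis
      for (i in seq_len(map@nrow) - 1L) {
        for (j in seq_len(map@ncol) - 1L) {
          v <- mat[i * map@ncol + j + 1L, ]
          if (anyNA(v)) next
          writeLines(paste(j, i, m, .fmtNum(axis), .fmtNum(v), sep = "\t"),
                     con)
        }
      }
    }
    .writeSidecar(map, paste0(path, ".meta.yaml"))
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    idx <- data.frame(x = integer(), y = integer(),
                      brillouin_file = character(),
                      raman_file = character(), stringsAsFactors = FALSE)
    for (i in seq_len(map@nrow) - 1L) {
      for (j in seq_len(map@ncol) - 1L) {
        files <- c(brillouin = NA_character_, raman = NA_character_)
        for (m in c("brillouin", "raman")) {
          s <- getSpectrum(map, i, j, m)
          if (is.null(s)) next
          fn <- sprintf("px_%03d_%03d_%s.txt", i, j, m)
          writeSpectrum(s, file.path(path, fn))
          files[[m]] <- fn
        }
        idx <- rbind(idx, data.frame(x = j, y = i,
                                     brillouin_file = files[["brillouin"]],
                                     raman_file = files[["raman"]],
                                     stringsAsFactors = FALSE))
      }
    }
    utils::write.table(idx, file.path(path, "index.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .writeSidecar(map, file.path(path, "metadata.yaml"))
  }
  invisible(path)
}

.assembleMap <- function(pixels, meta, coords = NULL) {
  ## pixels: list of list(x, y, modality, axis, intensity); coords optionally
  ## lists every grid point (for the directory index, where a pixel can be
  ## present with no spectrum at all)
  xs <- vapply(pixels, `[[`, numeric(1), "x")
  ys <- vapply(pixels, `[[`, numeric(1), "y")
  if (!is.null(coords)) {
    xs <- c(xs, coords$x)
    ys <- c(ys, coords$y)
  }
  nrow <- max(ys) + 1L
  ncol <- max(xs) + 1L
  if (!is.null(meta$nrow)) nrow <- max(nrow, meta$nrow)
  if (!is.null(meta$ncol)) ncol <- max(ncol, meta$ncol)
  seen <- unique(paste(ys, xs))
  want <- as.vector(outer(seq_len(nrow) - 1L, seq_len(ncol) - 1L, paste))
  missing <- setdiff(want, seen)
  if (length(missing) > 0L) {
    rc <- do.call(rbind, strsplit(missing, " "))
    stop("ragged grid: missing pixel(s) at (x, y) = ",
         paste(sprintf("(%s, %s)", rc[, 2], rc[, 1]), collapse = ", "))
  }
  axes <- list(brillouin = NULL, raman = NULL)
  mats <- list(brillouin = NULL, raman = NULL)
  for (p in pixels) {
    m <- p$modality
    if (is.null(axes[[m]])) {
      axes[[m]] <- p$axis
      mats[[m]] <- matrix(NA_real_, nrow = nrow * ncol,
                          ncol = length(p$axis))
    } else if (length(p$axis) != length(axes[[m]]) ||
               max(abs(p$axis - axes[[m]])) > 1e-9 * max(abs(axes[[m]]))) {
      stop("inconsistent ", m, " axes within the map (pixel x=", p$x,
           ", y=", p$y, ")")
    }
    mats[[m]][p$y * ncol + p$x + 1L, ] <- p$intensity
  }
  spectralMap(nrow, ncol,
              brillouinAxis = axes$brillouin, brillouin = mats$brillouin,
              ramanAxis = axes$raman, raman = mats$raman,
              step = if (is.null(meta$step)) 3 else meta$step,
              origin = if (is.null(meta$origin)) c(0, 0)
                       else as.numeric(meta$origin))
}

#' Read a spectral map
#'
#' Accepts either on-disk dialect written by [writeMap()]: a long-format
#' delimited table (with its `<path>.meta.yaml` sidecar) or a directory with
#' an `index.tsv`, per-pixel spectrum files and `metadata.yaml`. A pixel with
#' a missing modality is recorded as absent, not zero. A grid with an absent
#' pixel is a ragged-grid error naming the missing `(x, y)`; spectra of one
#' modality with differing axes are an inconsistent-axes error.
#'
#' @param path long-format file or map directory.
#' @return A validated [SpectralMap-class].
#' @export
readMap <- function(path) {
  if (dir.exists(path)) {
    meta <- .readSidecar(file.path(path, "metadata.yaml"))
    idx <- .readDelim(file.path(path, "index.tsv"))
    need <- c("x", "y", "brillouin_file", "raman_file")
    if (!all(need %in% names(idx)))
      stop("index.tsv must have columns: ", paste(need, collapse = ", "))
    pixels <- list()
    for (k in seq_len(nrow(idx))) {
      for (m in c("brillouin", "raman")) {
        fn <- idx[[paste0(m, "_file")]][k]
        if (is.na(fn) || fn == "NA" || fn == "") next
        s <- readSpectrum(file.path(path, fn), modality = m)
        pixels[[length(pixels) + 1L]] <-
          list(x = idx$x[k], y = idx$y[k], modality = m,
               axis = s@axis, intensity = s@intensity)
      }
    }
    if (length(pixels) == 0L)
      stop("map contains no spectra")
    ## the index enumerates every grid point, spectra or not
    .assembleMap(pixels, meta, coords = idx[, c("x", "y")])
  } else {
    meta <- .readSidecar(paste0(path, ".meta.yaml"))
    if (is.null(meta)) meta <- list()
    df <- .readDelim(path)
    need <- c("x", "y", "modality", "axis_value", "intensity")
    if (!all(need %in% names(df)))
      stop("long-format map must have columns: ",
           paste(need, collapse = ", "))
    key <- paste(df$x, df$y, df$modality)
    pixels <- lapply(split(seq_len(nrow(df)), key), function(rows) {
      o <- rows[order(df$axis_value[rows])]
      list(x = df$x[o[1]], y = df$y[o[1]], modality = df$modality[o[1]],
           axis = df$axis_value[o], intensity = df$intensity[o])
    })
    .assembleMap(unname(pixels), meta)
  }
}

#' Write per-pixel features as a delimited table
#'
#' One row per pixel with columns `x`, `y` (0-based pixel indices),
#' `nu_soft`, `nu_hard`, `I_soft`, `I_hard`, `M_soft`, `M_hard`, `M_avg`,
#' `mineral_to_matrix`, `ch_moment`, `heme_moment`. Masked cells are written
#' as empty fields, never zeros.
#'
#' @param fmap a [FeatureMap-class] (or a named list of feature matrices of
#'   one shape, for partial feature sets).
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readFeaturesTable()]
#' @export
writeFeaturesTable <- function(fmap, path) {
  feats <- if (is(fmap, "FeatureMap")) fmap@features else fmap
  dims <- unique(lapply(feats, dim))
  if (length(dims) != 1L)
    stop("feature maps must share one grid shape")
  d <- dims[[1]]
  cols <- intersect(.featureOrder, names(feats))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("x", "y", cols), collapse = "\t"), con)
  for (i in seq_len(d[1]) - 1L) {
    for (j in seq_len(d[2]) - 1L) {
      v <- vapply(cols, function(f) feats[[f]][i + 1L, j + 1L], numeric(1))
      txt <- ifelse(is.na(v), "", sprintf("%.6g", v))
      writeLines(paste(c(j, i, txt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a per-pixel features table
#'
#' Inverse of [writeFeaturesTable()]; empty cells come back as `NA`.
#'
#' @param path file path.
#' @param step,origin grid metadata to attach (not stored in the table).
#' @return A [FeatureMap-class].
#' @export
readFeaturesTable <- function(path, step = 3, origin = c(0, 0)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  nrow <- max(df$y) + 1L
  ncol <- max(df$x) + 1L
  cols <- setdiff(names(df), c("x", "y"))
  feats <- lapply(cols, function(f) {
    m <- matrix(NA_real_, nrow = nrow, ncol = ncol)
    m[cbind(df$y + 1L, df$x + 1L)] <- df[[f]]
    m
  })
  names(feats) <- cols
  new("FeatureMap", features = feats, step = step,
      origin = as.numeric(origin))
}

#' Read / write an AnalysisConfig as YAML
#'
#' Round-trips every slot of [AnalysisConfig-class] through a YAML file, the
#' same structured-text format used for map sidecars and the `--config` flag
#' of the command-line front-end. Keys missing from the file keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return `readConfig` an [AnalysisConfig-class]; `writeConfig` the path,
#'   invisibly.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysisConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysisConfig, vals)
}

#' @rdname readConfig
#' @param config an [AnalysisConfig-class].
#' @export
writeConfig <- function(config, path) {
  stopifnot(is(config, "AnalysisConfig"))
  vals <- lapply(slotNames(config), function(s) {
    v <- slot(config, s)
    if (is.integer(v)) as.integer(v) else v
  })
  names(vals) <- slotNames(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}
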