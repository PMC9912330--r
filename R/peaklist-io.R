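#' Read a peak list
#'
#' Supports two dialects. \strong{sparky}: whitespace-separated columns
#' \code{Assignment w1 w2 [Data Height]}, where for 1H-15N HSQC lists
#' w1 is the 15N shift and w2 the 1H shift by convention (override with
#' \code{axisOrder = "HN"} for lists written the other way around).
#' Sparky assignments drop the proton atom name on reading
#' (\code{"R96N-H"} becomes label \code{"R96"};
#' \code{"W119NE1-HE1"} keeps its side-chain tag as \code{"W119NE1"}).
#' \strong{csv}: self-describing, with header
#' \code{label,delta_H_ppm,delta_N_ppm,intensity}.
#'
#' Malformed rows raise an error naming the offending line; duplicate
#' labels raise an error. An empty data section yields an empty peak
#' list, not an error — no row is ever silently dropped.
#'
#' @param path file to read
#' @param dialect \code{"sparky"} or \code{"csv"}
#' @param axisOrder for the sparky dialect: \code{"NH"} (default,
#'   w1 = 15N) or \code{"HN"} (w1 = 1H)
#' @return a peak-list data.frame with columns \code{label},
#'   \code{deltaH}, \code{deltaN}, \code{intensity} (NA when absent)
#' @export
readPeakList <- function(path, dialect = c("sparky", "csv"),
                         axisOrder = c("NH", "HN")) {
  dialect <- match.arg(dialect)
  axisOrder <- match.arg(axisOrder)
  if (!file.exists(path)) stop("peak list not found: ", path)
  pl <- if (dialect == "sparky") readSparkyList(path, axisOrder)
        else readCsvList(path)
  if (anyDuplicated(pl$label))
    stop("duplicate label in ", path, ": ",
         pl$label[duplicated(pl$label)][1])
  pl
}

readSparkyList <- function(path, axisOrder) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("Assignment", ln, fixed = TRUE)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 3)
      stop("malformed row at line ", i, " of ", path, ": ", lines[i])
    w1 <- suppressWarnings(as.numeric(tok[2]))
    w2 <- suppressWarnings(as.numeric(tok[3]))
    if (is.na(w1) || is.na(w2))
      stop("non-numeric chemical shift at line ", i, " of ", path,
           ": ", lines[i])
    int <- if (length(tok) >= 4) {
      v <- suppressWarnings(as.numeric(tok[4]))
      if (is.na(v))
        stop("non-numeric intensity at line ", i, " of ", path)
      v
    } else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      label = sparkyLabel(tok[1]),
      deltaH = if (axisOrder == "NH") w2 else w1,
      deltaN = if (axisOrder == "NH") w1 else w2,
      intensity = int, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(emptyPeakList())
  do.call(rbind, out)
}

# "R96N-H" -> "R96"; "W119NE1-HE1" -> "W119NE1"; plain labels untouched
sparkyLabel <- function(assignment) {
  lab <- sub("-[^-]*$", "", assignment)
  sub("(?<=[0-9])N$", "", lab, perl = TRUE)
}

# backbone "R96" -> "R96N-H"; side chain "W119NE1" -> "W119NE1-HE1"
sparkyAssignment <- function(label) {
  tag <- sub("^[A-Za-z]+[0-9]+", "", label)
  if (!nzchar(tag)) return(paste0(label, "N-H"))
  hat <- if (startsWith(tag, "N")) sub("^N", "H", tag) else "H"
  paste0(label, "-", hat)
}

readCsvList <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  req <- c("label", "delta_H_ppm", "delta_N_ppm")
  if (!all(req %in% names(raw)))
    stop("csv peak list ", path, " must have header columns: ",
         paste(req, collapse = ", "))
  if (nrow(raw) == 0L) return(emptyPeakList())
  dH <- suppressWarnings(as.numeric(raw$delta_H_ppm))
  dN <- suppressWarnings(as.numeric(raw$delta_N_ppm))
  bad <- which(is.na(dH) | is.na(dN))
  if (length(bad))
    stop("non-numeric chemical shift at line ", bad[1] + 1L,
         " of ", path)
  int <- if ("intensity" %in% names(raw)) {
    v <- suppressWarnings(as.numeric(raw$intensity))
    v[!nzchar(trimws(ifelse(is.na(raw$intensity), "", raw$intensity)))] <- NA
    v
  } else rep(NA_real_, nrow(raw))
  data.frame(label = raw$label, deltaH = dH, deltaN = dN,
             intensity = int, stringsAsFactors = FALSE)
}

emptyPeakList <- function() {
  data.frame(label = character(), deltaH = numeric(), deltaN = numeric(),
             intensity = numeric(), stringsAsFactors = FALSE)
}

#' Write a peak list
#'
#' Inverse of [readPeakList()]: shifts are written with six decimals so
#' a round trip reproduces the input to well under 1e-5 ppm. An empty
#' peak list yields a valid header-only file.
#'
#' @param peaks peak-list data.frame (\code{label}, \code{deltaH},
#'   \code{deltaN}, optional \code{intensity})
#' @param path output file
#' @param dialect \code{"sparky"} or \code{"csv"}
#' @return \code{path}, invisibly
#' @export
writePeakList <- function(peaks, path, dialect = c("sparky", "csv")) {
  dialect <- match.arg(dialect)
  ok <- validatePeakList(peaks)
  if (!isTRUE(ok)) stop(ok)
  if (!"intensity" %in% names(peaks)) peaks$intensity <- NA_real_
  if (dialect == "sparky") {
    hdr <- sprintf("%17s %10s %10s %12s", "Assignment", "w1", "w2",
                   "Data Height")
    rows <- character(nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      rows[i] <- sprintf("%17s %10.6f %10.6f %12s",
                         sparkyAssignment(peaks$label[i]),
                         peaks$deltaN[i], peaks$deltaH[i],
                         if (is.na(peaks$intensity[i])) "" else
                           sprintf("%.6g", peaks$intensity[i]))
    }
    writeLines(c(hdr, "", rows), path)
  } else {
    df <- data.frame(label = peaks$label,
                     delta_H_ppm = sprintf("%.6f", peaks$deltaH),
                     delta_N_ppm = sprintf("%.6f", peaks$deltaN),
                     intensity = ifelse(is.na(peaks$intensity), "",
                                        sprintf("%.6g", peaks$intensity)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a titration series from a manifest
#'
#' The manifest lists one row per titration step with columns
#' \code{step}, \code{peaklist_path} (relative to the manifest) and
#' \code{I_TSP}; either a CSV file with that header or a YAML file with
#' a \code{steps} list of mappings with those keys. Steps are sorted by
#' index; step 0 (the free-protein reference) must be present, and
#' every step needs an \code{I_TSP} value.
#'
#' @param manifestPath path to the manifest (.csv, .yaml or .yml)
#' @param dialect peak-list dialect; by default inferred per file from
#'   its extension (.csv is csv, anything else sparky)
#' @return a [TitrationSeries]
#' @export
readSeries <- function(manifestPath, dialect = NULL) {
  if (!file.exists(manifestPath))
    stop("manifest not found: ", manifestPath)
  ext <- tolower(tools::file_ext(manifestPath))
  man <- if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(manifestPath)
    if (is.null(y$steps)) stop("YAML manifest must have a 'steps' list")
    do.call(rbind, lapply(y$steps, function(s) {
      data.frame(step = if (is.null(s$step)) NA else s$step,
                 peaklist_path = if (is.null(s$peaklist_path)) NA_character_
                                 else s$peaklist_path,
                 I_TSP = if (is.null(s$I_TSP)) NA_real_ else s$I_TSP,
                 stringsAsFactors = FALSE)
    }))
  } else {
    utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  }
  req <- c("step", "peaklist_path", "I_TSP")
  if (!all(req %in% names(man)))
    stop("manifest must provide: ", paste(req, collapse = ", "))
  if (any(is.na(man$step)) || any(is.na(man$peaklist_path)))
    stop("manifest has rows with missing step or peaklist_path")
  if (any(is.na(man$I_TSP)))
    stop("missing I_TSP for step(s): ",
         paste(man$step[is.na(man$I_TSP)], collapse = ", "))
  man <- man[order(man$step), , drop = FALSE]
  if (anyDuplicated(man$step)) stop("duplicate step indices in manifest")
  if (man$step[1] != 0)
    stop("manifest lacks step 0 (no free-protein reference)")
  base <- dirname(manifestPath)
  peakLists <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$peaklist_path[i]
    if (!file.exists(p)) p <- file.path(base, man$peaklist_path[i])
    if (!file.exists(p))
      stop("peak list referenced by manifest not found: ",
           man$peaklist_path[i])
    d <- if (is.null(dialect)) {
      if (tolower(tools::file_ext(p)) == "csv") "csv" else "sparky"
    } else dialect
    readPeakList(p, d)
  })
  TitrationSeries(step = man$step, peakLists = peakLists,
                  iTSP = man$I_TSP,
                  metadata = list(manifest = normalizePath(manifestPath)))
}

#' Write a titration series to a directory
#'
#' One peak-list file per step plus a \code{manifest.csv}; a synthetic
#' series' ground truth, when present in the metadata, is written to a
#' separate \code{ground_truth.yaml} sidecar so the analysis inputs
#' stay free of it.
#'
#' @param series a [TitrationSeries]
#' @param dir output directory (created if needed)
#' @param dialect peak-list dialect for the per-step files
#' @return the manifest path, invisibly
#' @export
writeSeries <- function(series, dir, dialect = c("sparky", "csv")) {
  dialect <- match.arg(dialect)
  validObject(series)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (dialect == "csv") "csv" else "list"
  files <- sprintf("step%02d.%s", series@step, ext)
  for (i in seq_along(series@step))
    writePeakList(series@peakLists[[i]], file.path(dir, files[i]), dialect)
  man <- data.frame(step = series@step, peaklist_path = files,
                    I_TSP = series@iTSP)
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE, quote = FALSE)
  gt <- series@metadata$groundTruth
  if (!is.null(gt)) {
    gt$ddMaxWeighted <- as.list(gt$ddMaxWeighted)
    yaml::write_yaml(gt, file.path(dir, "ground_truth.yaml"))
  }
  invisible(manPath)
}
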