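#' Parse a residue label into number and side-chain tag
#'
#' Labels follow the "one/three-letter code + sequence number +
#' optional side-chain tag" convention, e.g. \code{"R96"},
#' \code{"Trp119"}, \code{"W119NE1"}.
#'
#' @param label character vector of labels
#' @return data.frame with \code{label}, \code{number} (NA when
#'   unparseable) and \code{tag} (empty for backbone amides)
#' @export
parseResidueLabel <- function(label) {
  m <- regmatches(label, regexec("^[A-Za-z]{1,3}([0-9]+)(.*)$", label))
  num <- vapply(m, function(x) if (length(x)) as.integer(x[2])
                else NA_integer_, integer(1))
  tag <- vapply(m, function(x) if (length(x)) x[3] else "", character(1))
  data.frame(label = label, number = num, tag = tag,
             stringsAsFactors = FALSE)
}

#' Group significant residues into binding-site patches
#'
#' Contiguous runs of significant backbone residues (consecutive
#' members at most \code{maxGap} apart in sequence) form patches; runs
#' of a single residue are reported as singletons. Side-chain signals
#' (e.g. Trp NHe) are reported separately, attributed to their residue
#' number, and do not enter the backbone grouping. Labels whose residue
#' number cannot be parsed go to the singleton bucket with a warning.
#'
#' @param csp a [CSPTable-class]
#' @param maxGap largest sequence gap within one patch (default 1,
#'   i.e. strictly consecutive residues)
#' @return a [PatchReport-class]
#' @examples
#' fx <- makeFixtureHfyn(seed = 1)
#' findPatches(buildCspTable(fx$series))
#' @export
findPatches <- function(csp, maxGap = 1) {
  labs <- significantLabels(csp)
  if (!length(labs))
    return(new("PatchReport",
               patches = data.frame(start = integer(), end = integer(),
                                    n = integer()),
               members = list(), singletons = character(),
               sideChainHits = character()))
  parsed <- parseResidueLabel(labs)
  bad <- is.na(parsed$number)
  if (any(bad))
    warning("unparseable label(s) moved to singletons: ",
            paste(labs[bad], collapse = ", "))
  side <- !bad & nzchar(parsed$tag)
  bb <- parsed[!bad & !side, , drop = FALSE]
  bb <- bb[order(bb$number), , drop = FALSE]

  starts <- integer(); ends <- integer(); members <- list()
  singles <- labs[bad]
  if (nrow(bb)) {
    runStart <- 1L
    breaks <- c(which(diff(bb$number) > maxGap), nrow(bb))
    for (b in breaks) {
      run <- bb[runStart:b, , drop = FALSE]
      if (nrow(run) >= 2) {
        starts <- c(starts, run$number[1])
        ends <- c(ends, run$number[nrow(run)])
        members <- c(members, list(run$label))
      } else {
        singles <- c(singles, run$label)
      }
      runStart <- b + 1L
    }
  }
  new("PatchReport",
      patches = data.frame(start = starts, end = ends,
                           n = lengths(members)),
      members = members, singletons = singles,
      sideChainHits = parsed$label[side])
}

#' Map saturated CSPs onto a PDB structure
#'
#' Writes a copy of the input PDB in which the temperature-factor
#' column of every ATOM record carries the residue's saturated CSP
#' (ddMax in ppm times \code{scale}, clamped to [0, 999.99] to fit the
#' fixed-width field); residues absent from the CSP table get the
#' sentinel -1.00. Nothing but the B-factor column is touched, so the
#' output differs from the input only in those six characters per ATOM
#' line. Side-chain labels are attributed to their residue number; when
#' both a backbone and a side-chain signal report the same residue the
#' larger ddMax wins by default.
#'
#' @param pdbIn input PDB file
#' @param csp a [CSPTable-class]
#' @param pdbOut output path
#' @param chain restrict to one chain identifier (default: all chains)
#' @param scale multiplier applied to ddMax before writing (default
#'   100, preserving two decimals of ppm precision)
#' @param sideChain \code{"max"} (default) or \code{"backbone"}: how a
#'   side-chain signal combines with the backbone value of its residue
#' @return invisibly, a character vector of labels whose residue was
#'   not found in the structure (also raised as a warning)
#' @export
writeStructureMap <- function(pdbIn, csp, pdbOut, chain = NULL,
                              scale = 100, sideChain = c("max",
                                                         "backbone")) {
  sideChain <- match.arg(sideChain)
  if (!file.exists(pdbIn)) stop("PDB file not found: ", pdbIn)
  parsed <- parseResidueLabel(csp@label)
  val <- setNames(rep(NA_real_, 0), character())
  bmap <- new.env(parent = emptyenv())
  for (i in seq_along(csp@label)) {
    num <- parsed$number[i]
    if (is.na(num) || is.na(csp@ddMax[i])) next
    key <- as.character(num)
    isSide <- nzchar(parsed$tag[i])
    if (isSide && sideChain == "backbone" &&
        !is.null(bmap[[key]])) next
    cur <- bmap[[key]]
    bmap[[key]] <- if (is.null(cur)) csp@ddMax[i]
                   else max(cur, csp@ddMax[i])
  }

  lines <- readLines(pdbIn)
  seen <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!startsWith(ln, "ATOM")) next
    if (nchar(ln) < 66)
      stop("malformed ATOM record at line ", i, " of ", pdbIn)
    if (!is.null(chain) && substr(ln, 22, 22) != chain) next
    resSeq <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
    if (is.na(resSeq))
      stop("malformed residue number at line ", i, " of ", pdbIn)
    key <- as.character(resSeq)
    v <- bmap[[key]]
    b <- if (is.null(v)) -1 else min(max(v * scale, 0), 999.99)
    if (!is.null(v)) seen <- c(seen, key)
    lines[i] <- paste0(substr(ln, 1, 60), sprintf("%6.2f", b),
                       substr(ln, 67, nchar(ln)))
  }
  writeLines(lines, pdbOut)
  mapped <- ls(bmap)
  missing <- setdiff(mapped, unique(seen))
  missingLabs <- csp@label[as.character(parsed$number) %in% missing]
  if (length(missingLabs))
    warning("residue(s) in CSP table absent from structure: ",
            paste(missingLabs, collapse = ", "))
  invisible(missingLabs)
}
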