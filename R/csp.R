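#' Isotope-weighted chemical shift perturbation
#'
#' Combines the 1H and 15N shift differences of one amide into a single
#' CSP in proton-ppm units:
#' \deqn{\Delta\delta = \sqrt{(\delta_H - \delta_{H0})^2 +
#'   (w_N (\delta_N - \delta_{N0}))^2}}
#' The 15N axis is compressed by \code{nWeight} (default 0.14, the
#' standard amide weighting reflecting the relative 15N shift
#' dispersion) so that both nuclei contribute on a comparable scale.
#'
#' @param deltaH0,deltaN0 free-protein shifts (ppm)
#' @param deltaH,deltaN shifts in the perturbed spectrum (ppm)
#' @param nWeight 15N scaling factor (> 0)
#' @return the CSP in ppm (vectorized over its arguments)
#' @examples
#' computeCsp(8.2, 119, 8.3, 119.5)  # sqrt(0.1^2 + (0.14 * 0.5)^2)
#' @export
computeCsp <- function(deltaH0, deltaN0, deltaH, deltaN, nWeight = 0.14) {
  if (nWeight <= 0) stop("nWeight must be > 0")
  if (any(!is.finite(c(deltaH0, deltaN0, deltaH, deltaN))))
    stop("chemical shifts must be finite")
  sqrt((deltaH - deltaH0)^2 + (nWeight * (deltaN - deltaN0))^2)
}

#' Track peaks across a titration series
#'
#' Joins the per-step peak lists into per-residue trajectories. In
#' \code{by_label} mode peaks are matched by exact label identity; in
#' \code{nearest} mode each step-k position is linked to the step-(k+1)
#' peak minimizing the weighted distance (same weighting as
#' [computeCsp()]), links beyond the axis tolerances are rejected, and
#' a tie between two candidates (within 1e-6 ppm weighted distance) is
#' flagged as ambiguous rather than guessed. Residues whose peak lies
#' within the overlap tolerance of another peak at any step are
#' flagged, since their CSPs are unreliable.
#'
#' @param series a [TitrationSeries]
#' @param matchMode \code{"by_label"} or \code{"nearest"}
#' @param tolH,tolN matching/overlap tolerances (ppm) on the 1H and 15N
#'   axes
#' @param nWeight 15N weighting for the nearest-match distance
#' @return a list with \code{label} (from the step-0 reference),
#'   matrices \code{deltaH} and \code{deltaN} (residues x steps, NA
#'   where no link was made), \code{overlap} and \code{ambiguous}
#'   logical vectors
#' @export
trackPeaks <- function(series, matchMode = c("by_label", "nearest"),
                       tolH = 0.02, tolN = 0.2, nWeight = 0.14) {
  matchMode <- match.arg(matchMode)
  validObject(series)
  n <- nSteps(series)
  if (series@step[1] != 0) stop("step 0 (free-protein reference) required")
  ref <- series@peakLists[[1]]
  labs <- ref$label
  nres <- length(labs)
  dH <- matrix(NA_real_, nres, n, dimnames = list(labs, series@step))
  dN <- matrix(NA_real_, nres, n, dimnames = list(labs, series@step))
  dH[, 1] <- ref$deltaH
  dN[, 1] <- ref$deltaN
  ambiguous <- setNames(rep(FALSE, nres), labs)

  if (matchMode == "by_label") {
    for (j in seq_len(n - 1) + 1) {
      pl <- series@peakLists[[j]]
      idx <- match(labs, pl$label)
      dH[, j] <- pl$deltaH[idx]
      dN[, j] <- pl$deltaN[idx]
    }
  } else {
    for (j in seq_len(n - 1) + 1) {
      pl <- series@peakLists[[j]]
      for (i in seq_len(nres)) {
        h0 <- dH[i, j - 1]; n0 <- dN[i, j - 1]
        if (is.na(h0)) next
        dh <- pl$deltaH - h0; dn <- pl$deltaN - n0
        within <- abs(dh) <= tolH & abs(dn) <= tolN
        if (!any(within)) next
        d <- sqrt(dh^2 + (nWeight * dn)^2)
        d[!within] <- Inf
        o <- order(d)
        if (length(o) > 1 && is.finite(d[o[2]]) &&
            d[o[2]] - d[o[1]] < 1e-6) {
          ambiguous[i] <- TRUE
          next
        }
        dH[i, j] <- pl$deltaH[o[1]]
        dN[i, j] <- pl$deltaN[o[1]]
      }
    }
  }

  overlap <- setNames(rep(FALSE, nres), labs)
  for (j in seq_len(n)) {
    pl <- series@peakLists[[j]]
    m <- nrow(pl)
    if (m < 2) next
    close <- abs(outer(pl$deltaH, pl$deltaH, "-")) <= tolH &
             abs(outer(pl$deltaN, pl$deltaN, "-")) <= tolN
    diag(close) <- FALSE
    crowded <- pl$label[rowSums(close) > 0]
    overlap[labs %in% crowded] <- TRUE
  }

  list(label = labs, deltaH = dH, deltaN = dN, overlap = overlap,
       ambiguous = ambiguous)
}

#' Trajectory linearity score
#'
#' Under two-state fast exchange a titrating peak moves along a straight
#' line between its free and bound positions, so deviation from
#' collinearity diagnoses additional states or exchange-regime effects.
#' Fits a total-least-squares line through the (deltaH,
#' nWeight * deltaN) points of one trajectory and returns the maximum
#' perpendicular deviation in ppm (0 for a perfectly two-state
#' trajectory).
#'
#' @param deltaH,deltaN trajectory coordinates (ppm), >= 3 finite points
#' @param nWeight 15N weighting
#' @return maximum perpendicular distance from the best line (ppm)
#' @export
linearityCheck <- function(deltaH, deltaN, nWeight = 0.14) {
  keep <- is.finite(deltaH) & is.finite(deltaN)
  x <- deltaH[keep]
  y <- nWeight * deltaN[keep]
  if (length(x) < 3)
    stop("linearity check needs at least 3 points")
  m <- cbind(x - mean(x), y - mean(y))
  if (all(abs(m) < .Machine$double.eps)) return(0)
  sv <- svd(m)
  # perpendicular deviations are the projections on the minor axis
  max(abs(m %*% sv$v[, 2]))
}

#' Corrected-standard-deviation significance cutoff
#'
#' The saturated CSPs of non-interacting residues scatter about zero,
#' while binding-site residues form large outliers. The cutoff is the
#' standard deviation of the null scatter, estimated robustly by
#' iterated outlier exclusion: compute the standard deviation of the
#' retained values (about zero by default, since CSP magnitudes have a
#' null centred on zero), drop values exceeding
#' \code{exclusionFactor} times it, and repeat until no value is
#' dropped. Values strictly greater than the final sigma_c are
#' significant.
#'
#' @param values non-negative saturated CSPs (ppm), length >= 3
#' @param exclusionFactor outlier multiplier for the iteration
#'   (default 3)
#' @param about \code{"zero"} (default) or \code{"mean"}: centre of the
#'   standard deviation
#' @return a [SignificanceResult-class] object
#' @examples
#' r <- significanceThreshold(c(rep(0.01, 10), 1))
#' sigmaC(r)   # 0.01 after the 1.0 outlier is excluded
#' @export
significanceThreshold <- function(values, exclusionFactor = 3,
                                  about = c("zero", "mean")) {
  about <- match.arg(about)
  vals <- values[!is.na(values)]
  if (length(vals) < 3)
    stop("need at least 3 values to estimate sigma_c")
  if (any(vals < 0)) stop("CSP values must be non-negative")
  keep <- !is.na(values)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    v <- values[keep]
    s <- if (about == "zero") sqrt(mean(v^2))
         else sqrt(mean((v - mean(v))^2))
    drop <- keep & !is.na(values) & values > exclusionFactor * s
    if (!any(drop)) break
    keep <- keep & !drop
    if (sum(keep) < 1L) break
  }
  new("SignificanceResult", sigmaC = s,
      excluded = which(!keep & !is.na(values)),
      iterations = iterations,
      significant = !is.na(values) & values > s)
}

#' Build the per-residue CSP table of a titration series
#'
#' Composes the analysis of one series: track peaks across steps,
#' compute the weighted CSP of every residue at every step relative to
#' the free-protein reference, take the CSP at the designated saturated
#' step as ddMax, score trajectory linearity, and select significant
#' residues with [significanceThreshold()]. Also reports the
#' saturation diagnostic, the largest change in CSP between the last
#' two spectra — small values confirm the titration was carried to
#' saturation.
#'
#' @param series a [TitrationSeries]
#' @param saturatedStep step index whose CSP defines ddMax (default:
#'   the last step)
#' @param matchMode,tolH,tolN passed to [trackPeaks()]
#' @param nWeight 15N weighting
#' @param exclusionFactor,about passed to [significanceThreshold()]
#' @return a [CSPTable-class] object
#' @examples
#' fx <- makeFixtureHfyn(seed = 1)
#' csp <- buildCspTable(fx$series)
#' csp
#' @export
buildCspTable <- function(series, saturatedStep = NULL,
                          matchMode = c("by_label", "nearest"),
                          tolH = 0.02, tolN = 0.2, nWeight = 0.14,
                          exclusionFactor = 3, about = c("zero", "mean")) {
  matchMode <- match.arg(matchMode)
  about <- match.arg(about)
  tr <- trackPeaks(series, matchMode, tolH = tolH, tolN = tolN,
                   nWeight = nWeight)
  nres <- length(tr$label)
  n <- nSteps(series)
  dd <- matrix(NA_real_, nres, n,
               dimnames = list(tr$label, series@step))
  for (j in seq_len(n))
    dd[, j] <- computeCsp(tr$deltaH[, 1], tr$deltaN[, 1],
                          tr$deltaH[, j], tr$deltaN[, j], nWeight)
  if (is.null(saturatedStep)) saturatedStep <- series@step[n]
  satCol <- match(saturatedStep, series@step)
  if (is.na(satCol)) stop("saturatedStep ", saturatedStep,
                          " not in the series")
  ddmax <- dd[, satCol]
  lin <- vapply(seq_len(nres), function(i) {
    ok <- is.finite(tr$deltaH[i, ]) & is.finite(tr$deltaN[i, ])
    if (sum(ok) < 3) return(NA_real_)
    linearityCheck(tr$deltaH[i, ], tr$deltaN[i, ], nWeight)
  }, numeric(1))
  sig <- significanceThreshold(ddmax, exclusionFactor, about)
  satDiag <- if (n >= 2)
    max(abs(dd[, n] - dd[, n - 1]), na.rm = TRUE) else NA_real_
  new("CSPTable", label = tr$label, dd = dd, ddMax = ddmax,
      linearity = lin, overlap = unname(tr$overlap),
      significant = sig@significant, sigmaC = sig@sigmaC,
      sigmaIterations = sig@iterations,
      sigmaExcluded = tr$label[sig@excluded],
      saturatedStep = as.integer(saturatedStep),
      saturationDiagnostic = satDiag, nWeight = nWeight)
}

#' Flatten a CSP table to a data.frame
#'
#' One row per residue with per-step CSP columns
#' (\code{dd_step<index>}), ddMax, linearity, and the overlap and
#' significance flags — the layout used by the pipeline's CSV export.
#'
#' @param x a \code{CSPTable}
#' @param row.names,optional,... ignored (S3 compatibility)
#' @return a data.frame
#' @export
as.data.frame.CSPTable <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  dd <- x@dd
  colnames(dd) <- paste0("dd_step", colnames(dd))
  data.frame(label = x@label, dd, dd_max = x@ddMax,
             linearity = x@linearity, overlap = x@overlap,
             significant = x@significant, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
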