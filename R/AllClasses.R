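#' @import methods
NULL

#' Microfluidic chip and titration-schedule parameters
#'
#' Describes the mixing hardware and the two stock solutions of a
#' displacement-mixing titration: a circuit of fixed working volume is
#' loaded with a protein-only solution (a), and at each step a small
#' volume of the protein--ligand solution (b) is injected, displacing an
#' equal volume of the fully mixed circuit content. Both solutions carry
#' the protein at the same concentration, so only ligand and the TSP
#' internal standard change across the series.
#'
#' @slot circuitVolume working volume of the mixing circuit (microlitres)
#' @slot injectionVolumeMean mean injected volume per step (microlitres)
#' @slot injectionVolumeSd standard deviation of the injected volume
#'   (microlitres); draws are truncated to (0, circuitVolume)
#' @slot nSteps number of injections (the series has nSteps + 1 spectra,
#'   the first being the protein-only reference)
#' @slot proteinConc total protein concentration, identical in both
#'   solutions (micromolar)
#' @slot ligandConcB total ligand concentration in solution b (micromolar);
#'   the saturating ligand-to-protein ratio is ligandConcB / proteinConc
#' @slot tspConcA,tspConcB TSP concentration in solutions a and b
#'   (arbitrary units); they must differ by at least one order of
#'   magnitude so the TSP 1D intensity resolves the mixing ratio
#'
#' @export
setClass("ChipParams", representation(
  circuitVolume = "numeric",
  injectionVolumeMean = "numeric",
  injectionVolumeSd = "numeric",
  nSteps = "integer",
  proteinConc = "numeric",
  ligandConcB = "numeric",
  tspConcA = "numeric",
  tspConcB = "numeric"
))

setValidity("ChipParams", function(object) {
  msg <- character()
  if (object@circuitVolume <= 0) msg <- c(msg, "circuitVolume must be > 0")
  if (object@injectionVolumeMean <= 0)
    msg <- c(msg, "injectionVolumeMean must be > 0")
  if (object@injectionVolumeMean >= object@circuitVolume)
    msg <- c(msg, "injectionVolumeMean must be smaller than circuitVolume")
  if (object@injectionVolumeSd < 0)
    msg <- c(msg, "injectionVolumeSd must be >= 0")
  if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
  if (object@proteinConc <= 0) msg <- c(msg, "proteinConc must be > 0")
  if (object@ligandConcB < 0) msg <- c(msg, "ligandConcB must be >= 0")
  if (object@tspConcA <= 0 || object@tspConcB <= 0)
    msg <- c(msg, "TSP concentrations must be > 0")
  ratio <- object@tspConcB / object@tspConcA
  if (ratio < 10 && ratio > 1 / 10)
    msg <- c(msg, "TSP concentrations must differ by at least one order of magnitude")
  if (length(msg)) msg else TRUE
})

#' Construct chip parameters
#'
#' @param circuitVolume working volume of the mixing circuit (uL)
#' @param injectionVolumeMean mean injected volume per step (uL)
#' @param injectionVolumeSd sd of the injected volume (uL)
#' @param nSteps number of injections
#' @param proteinConc protein concentration in both solutions (uM)
#' @param ligandConcB ligand concentration in solution b (uM)
#' @param tspConcA,tspConcB TSP concentrations (a.u.) in solutions a and b
#' @return a validated \code{ChipParams} object
#' @examples
#' ChipParams(nSteps = 10, proteinConc = 1000, ligandConcB = 5000)
#' @export
ChipParams <- function(circuitVolume = 10, injectionVolumeMean = 2,
                       injectionVolumeSd = 0.25, nSteps = 10L,
                       proteinConc = 1000, ligandConcB = 5000,
                       tspConcA = 10, tspConcB = 0.5) {
  new("ChipParams", circuitVolume = circuitVolume,
      injectionVolumeMean = injectionVolumeMean,
      injectionVolumeSd = injectionVolumeSd, nSteps = as.integer(nSteps),
      proteinConc = proteinConc, ligandConcB = ligandConcB,
      tspConcA = tspConcA, tspConcB = tspConcB)
}

#' Observation-noise model for synthetic titrations
#'
#' @slot shiftNoiseH 1H chemical-shift noise sd (ppm)
#' @slot shiftNoiseN 15N chemical-shift noise sd (ppm)
#' @slot intensityRelNoise relative (multiplicative) intensity noise
#' @slot seed RNG seed for reproducible series
#' @export
setClass("NoiseModel", representation(
  shiftNoiseH = "numeric",
  shiftNoiseN = "numeric",
  intensityRelNoise = "numeric",
  seed = "integer"
))

setValidity("NoiseModel", function(object) {
  if (object@shiftNoiseH < 0 || object@shiftNoiseN < 0 ||
      object@intensityRelNoise < 0)
    "noise standard deviations must be >= 0" else TRUE
})

#' Construct a noise model
#'
#' Defaults emulate a shift precision of about 0.002 ppm in 1H and
#' 0.02 ppm in 15N (of the order of a sub-10 Hz apparent resolution at
#' 14.1 T) and a 1 percent relative intensity noise on the
#' high-signal-to-noise TSP singlet.
#'
#' @param shiftNoiseH 1H shift noise sd (ppm)
#' @param shiftNoiseN 15N shift noise sd (ppm)
#' @param intensityRelNoise relative intensity noise (fraction)
#' @param seed integer RNG seed
#' @return a validated \code{NoiseModel}
#' @examples
#' NoiseModel(seed = 7)
#' noiselessModel()
#' @export
NoiseModel <- function(shiftNoiseH = 0.002, shiftNoiseN = 0.02,
                       intensityRelNoise = 0.01, seed = 1L) {
  new("NoiseModel", shiftNoiseH = shiftNoiseH, shiftNoiseN = shiftNoiseN,
      intensityRelNoise = intensityRelNoise, seed = as.integer(seed))
}

#' @rdname NoiseModel
#' @export
noiselessModel <- function(seed = 1L) {
  NoiseModel(shiftNoiseH = 0, shiftNoiseN = 0, intensityRelNoise = 0,
             seed = seed)
}

#' Per-step composition of the mixing circuit
#'
#' The displacement-mixing recursion applied to the chip parameters:
#' one row per titration step (step 0 is the untouched protein-only
#' solution), with the circuit ligand concentration, TSP concentration,
#' normalized ligand concentration alpha = [L]/[P], and the volume
#' injected at that step.
#'
#' @slot schedule data.frame with columns \code{step}, \code{ligandConc}
#'   (uM), \code{tspConc} (a.u.), \code{alpha}, \code{injectedVolume} (uL)
#' @slot proteinConc protein concentration (uM), constant across steps
#' @export
setClass("MixingSchedule", representation(
  schedule = "data.frame",
  proteinConc = "numeric"
))

setValidity("MixingSchedule", function(object) {
  s <- object@schedule
  req <- c("step", "ligandConc", "tspConc", "alpha", "injectedVolume")
  if (!all(req %in% names(s)))
    return(paste("schedule must have columns:", paste(req, collapse = ", ")))
  msg <- character()
  if (nrow(s) < 1L) msg <- c(msg, "schedule must have at least one step")
  if (is.unsorted(s$step, strictly = TRUE))
    msg <- c(msg, "step indices must be strictly increasing")
  if (any(diff(s$ligandConc) < -1e-9))
    msg <- c(msg, "ligand concentration must be non-decreasing")
  if (any(abs(s$alpha - s$ligandConc / object@proteinConc) > 1e-9))
    msg <- c(msg, "alpha must equal ligandConc / proteinConc")
  if (s$injectedVolume[1] != 0)
    msg <- c(msg, "step 0 must have zero injected volume")
  if (length(msg)) msg else TRUE
})

#' An ordered titration series of peak lists
#'
#' One peak list per titration step plus the per-step TSP 1D intensity
#' that reports the mixing ratio. Step 0 is the protein-only reference
#' spectrum. Peak lists are data.frames with columns \code{label},
#' \code{deltaH} (ppm), \code{deltaN} (ppm) and optionally
#' \code{intensity}.
#'
#' @slot step integer step indices, strictly increasing
#' @slot peakLists list of peak-list data.frames, one per step
#' @slot iTSP numeric TSP 1D intensity per step (a.u.)
#' @slot metadata free-form list (ground truth for synthetic series,
#'   provenance, etc.)
#' @export
setClass("TitrationSeries", representation(
  step = "integer",
  peakLists = "list",
  iTSP = "numeric",
  metadata = "list"
))

setValidity("TitrationSeries", function(object) {
  msg <- character()
  n <- length(object@step)
  if (length(object@peakLists) != n)
    msg <- c(msg, "one peak list per step required")
  if (length(object@iTSP) != n)
    msg <- c(msg, "one TSP intensity per step required")
  if (n && is.unsorted(object@step, strictly = TRUE))
    msg <- c(msg, "step indices must be strictly increasing")
  if (any(!is.finite(object@iTSP)))
    msg <- c(msg, "TSP intensities must be finite")
  for (pl in object@peakLists) {
    bad <- validatePeakList(pl)
    if (!isTRUE(bad)) { msg <- c(msg, bad); break }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a titration series
#'
#' @param step integer step indices (0-based; step 0 is the free-protein
#'   reference)
#' @param peakLists list of peak-list data.frames
#' @param iTSP per-step TSP intensities
#' @param metadata optional list of metadata
#' @return a validated \code{TitrationSeries}
#' @export
TitrationSeries <- function(step, peakLists, iTSP, metadata = list()) {
  new("TitrationSeries", step = as.integer(step), peakLists = peakLists,
      iTSP = as.numeric(iTSP), metadata = metadata)
}

# internal: check one peak list data.frame
validatePeakList <- function(pl) {
  if (!is.data.frame(pl))
    return("each peak list must be a data.frame")
  if (!all(c("label", "deltaH", "deltaN") %in% names(pl)))
    return("peak lists need columns label, deltaH, deltaN")
  if (nrow(pl) == 0L) return(TRUE)
  if (any(!nzchar(pl$label))) return("peak labels must be non-empty")
  if (any(!is.finite(pl$deltaH)) || any(!is.finite(pl$deltaN)))
    return("chemical shifts must be finite")
  if (anyDuplicated(pl$label))
    return(sprintf("duplicate peak label: %s",
                   pl$label[duplicated(pl$label)][1]))
  TRUE
}

#' Per-residue chemical shift perturbation table
#'
#' @slot label residue labels (rownames of \code{dd})
#' @slot dd matrix of CSPs (ppm), residues x steps; column j is the
#'   isotope-weighted shift difference between step j and step 0
#' @slot ddMax CSP at the designated saturated step (ppm)
#' @slot linearity maximum perpendicular deviation (ppm) of each
#'   residue's peak trajectory from its total-least-squares line
#' @slot overlap TRUE where the residue's peak lies within the overlap
#'   tolerance of another peak at any step
#' @slot significant TRUE where ddMax exceeds the corrected standard
#'   deviation cutoff
#' @slot sigmaC the corrected standard deviation cutoff (ppm)
#' @slot sigmaIterations iterations of the exclusion loop
#' @slot sigmaExcluded labels removed as outliers during the iteration
#' @slot saturatedStep step index used for ddMax
#' @slot saturationDiagnostic max over residues of |dd(last) -
#'   dd(second last)| (ppm); small values indicate saturation
#' @slot nWeight the 15N scaling used in the weighted CSP
#' @export
setClass("CSPTable", representation(
  label = "character",
  dd = "matrix",
  ddMax = "numeric",
  linearity = "numeric",
  overlap = "logical",
  significant = "logical",
  sigmaC = "numeric",
  sigmaIterations = "integer",
  sigmaExcluded = "character",
  saturatedStep = "integer",
  saturationDiagnostic = "numeric",
  nWeight = "numeric"
))

setValidity("CSPTable", function(object) {
  n <- length(object@label)
  msg <- character()
  if (nrow(object@dd) != n) msg <- c(msg, "dd must have one row per label")
  if (length(object@ddMax) != n || length(object@overlap) != n ||
      length(object@significant) != n || length(object@linearity) != n)
    msg <- c(msg, "per-residue slots must match label length")
  if (any(object@dd < -1e-12, na.rm = TRUE))
    msg <- c(msg, "CSPs must be non-negative")
  if (ncol(object@dd) > 0 && any(abs(object@dd[, 1]) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "CSP at step 0 must be zero")
  if (length(object@sigmaC) == 1 && object@sigmaC < 0)
    msg <- c(msg, "sigmaC must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of the iterative corrected-standard-deviation cutoff
#'
#' @slot sigmaC final corrected standard deviation (ppm)
#' @slot excluded indices (into the input vector) removed as outliers
#' @slot iterations number of passes until the retained set was stable
#' @slot significant logical, TRUE where the input value strictly
#'   exceeds sigmaC
#' @export
setClass("SignificanceResult", representation(
  sigmaC = "numeric",
  excluded = "integer",
  iterations = "integer",
  significant = "logical"
))

#' Global two-state binding fit result
#'
#' @slot betaD dimensionless dissociation constant K_D / [P]
#' @slot kD dissociation constant (uM)
#' @slot calSlope,calIntercept calibration mapping alpha =
#'   calSlope * I_TSP + calIntercept
#' @slot proteinConc protein concentration used to scale betaD (uM)
#' @slot covariance covariance matrix over (log betaD, calSlope,
#'   calIntercept)
#' @slot ci95 matrix of 95 percent confidence intervals, one row per
#'   reported parameter (betaD, kD, calSlope, calIntercept)
#' @slot residuals data.frame with one row per (residue, step):
#'   observed and fitted fractional shift and their difference
#' @slot alpha fitted normalized ligand concentration per step
#' @slot labelsUsed residues entering the fit
#' @slot converged logical
#' @slot dof residual degrees of freedom
#' @slot sigmaResid residual standard deviation
#' @slot message optimizer diagnostic message
#' @export
setClass("BindingFitResult", representation(
  betaD = "numeric",
  kD = "numeric",
  calSlope = "numeric",
  calIntercept = "numeric",
  proteinConc = "numeric",
  covariance = "matrix",
  ci95 = "matrix",
  residuals = "data.frame",
  alpha = "numeric",
  labelsUsed = "character",
  converged = "logical",
  dof = "integer",
  sigmaResid = "numeric",
  message = "character"
))

setValidity("BindingFitResult", function(object) {
  msg <- character()
  if (object@converged && object@kD <= 0)
    msg <- c(msg, "converged fits must have kD > 0")
  if (nrow(object@ci95) > 0) {
    lo <- object@ci95[, "lower"]; hi <- object@ci95[, "upper"]
    est <- object@ci95[, "estimate"]
    if (any(lo > est + 1e-12, na.rm = TRUE) ||
        any(hi < est - 1e-12, na.rm = TRUE))
      msg <- c(msg, "confidence intervals must bracket the estimate")
  }
  if (length(msg)) msg else TRUE
})

#' Binding-site patch report
#'
#' @slot patches data.frame with columns \code{start}, \code{end},
#'   \code{n}; one row per contiguous run of significant backbone
#'   residues, sorted and non-overlapping
#' @slot members list of member label vectors, parallel to patches
#' @slot singletons labels of significant residues not in any multi-residue
#'   patch representation (unparseable labels land here with a warning)
#' @slot sideChainHits significant side-chain labels (e.g. Trp NHe),
#'   reported separately but attributed to their residue number
#' @export
setClass("PatchReport", representation(
  patches = "data.frame",
  members = "list",
  singletons = "character",
  sideChainHits = "character"
))

setValidity("PatchReport", function(object) {
  p <- object@patches
  if (nrow(p) == 0L) return(TRUE)
  msg <- character()
  if (any(p$end < p$start)) msg <- c(msg, "patch end must be >= start")
  if (nrow(p) > 1 && any(p$start[-1] <= p$end[-nrow(p)]))
    msg <- c(msg, "patches must be sorted and non-overlapping")
  if (length(object@members) != nrow(p))
    msg <- c(msg, "one member set per patch required")
  if (length(msg)) msg else TRUE
})
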