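#' Number of titration steps in an object
#' @param x a \code{TitrationSeries} or \code{MixingSchedule}
#' @return integer count of steps (including the protein-only reference)
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' TSP internal-standard intensities
#' @param x a \code{TitrationSeries}
#' @return numeric vector of per-step 1D TSP intensities (a.u.)
#' @export
setGeneric("iTSP", function(x) standardGeneric("iTSP"))

#' Extract one peak list
#' @param x a \code{TitrationSeries}
#' @param i step position (1-based within the series)
#' @return a peak-list data.frame
#' @export
setGeneric("peakList", function(x, i) standardGeneric("peakList"))

#' Per-step normalized ligand concentration
#' @param x a \code{MixingSchedule} or \code{BindingFitResult}
#' @return numeric vector of alpha = [L]/[P] values
#' @export
setGeneric("alphaValues", function(x) standardGeneric("alphaValues"))

#' Saturated-step chemical shift perturbations
#' @param x a \code{CSPTable}
#' @return named numeric vector of ddMax values (ppm)
#' @export
setGeneric("ddMax", function(x) standardGeneric("ddMax"))

#' Corrected-standard-deviation significance cutoff
#' @param x a \code{CSPTable} or \code{SignificanceResult}
#' @return sigma_c (ppm)
#' @export
setGeneric("sigmaC", function(x) standardGeneric("sigmaC"))

#' Labels of residues above the significance cutoff
#' @param x a \code{CSPTable}
#' @return character vector of significant labels
#' @export
setGeneric("significantLabels", function(x) standardGeneric("significantLabels"))

#' Labels flagged for spectral overlap
#' @param x a \code{CSPTable}
#' @return character vector of overlap-flagged labels
#' @export
setGeneric("overlapLabels", function(x) standardGeneric("overlapLabels"))

#' Dimensionless dissociation constant
#' @param x a \code{BindingFitResult}
#' @return beta_D = K_D / [P]
#' @export
setGeneric("betaD", function(x) standardGeneric("betaD"))

#' Dissociation constant in micromolar
#' @param x a \code{BindingFitResult}
#' @return K_D (uM)
#' @export
setGeneric("kD", function(x) standardGeneric("kD"))

#' Binding-site patches
#' @param x a \code{PatchReport}
#' @return data.frame of patch boundaries
#' @export
setGeneric("patches", function(x) standardGeneric("patches"))
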