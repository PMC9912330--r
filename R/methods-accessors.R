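#' @rdname nSteps
#' @export
setMethod("nSteps", "TitrationSeries", function(x) length(x@step))

#' @rdname nSteps
#' @export
setMethod("nSteps", "MixingSchedule", function(x) nrow(x@schedule))

#' @rdname iTSP
#' @export
setMethod("iTSP", "TitrationSeries", function(x) x@iTSP)

#' @rdname peakList
#' @export
setMethod("peakList", "TitrationSeries", function(x, i) {
  stopifnot(i >= 1L, i <= length(x@peakLists))
  x@peakLists[[i]]
})

#' @rdname alphaValues
#' @export
setMethod("alphaValues", "MixingSchedule", function(x) x@schedule$alpha)

#' @rdname alphaValues
#' @export
setMethod("alphaValues", "BindingFitResult", function(x) x@alpha)

#' @rdname ddMax
#' @export
setMethod("ddMax", "CSPTable", function(x) setNames(x@ddMax, x@label))

#' @rdname sigmaC
#' @export
setMethod("sigmaC", "CSPTable", function(x) x@sigmaC)

#' @rdname sigmaC
#' @export
setMethod("sigmaC", "SignificanceResult", function(x) x@sigmaC)

#' @rdname significantLabels
#' @export
setMethod("significantLabels", "CSPTable", function(x) x@label[x@significant])

#' @rdname overlapLabels
#' @export
setMethod("overlapLabels", "CSPTable", function(x) x@label[x@overlap])

#' @rdname betaD
#' @export
setMethod("betaD", "BindingFitResult", function(x) x@betaD)

#' @rdname kD
#' @export
setMethod("kD", "BindingFitResult", function(x) x@kD)

#' @rdname patches
#' @export
setMethod("patches", "PatchReport", function(x) x@patches)

setMethod("show", "ChipParams", function(object) {
  cat("ChipParams:", object@nSteps, "injections of",
      sprintf("%.3g +/- %.3g uL", object@injectionVolumeMean,
              object@injectionVolumeSd),
      "into a", sprintf("%.3g uL circuit\n", object@circuitVolume))
  cat(sprintf("  [P] = %.4g uM (both solutions); [L]_b = %.4g uM (alpha_max = %.3g)\n",
              object@proteinConc, object@ligandConcB,
              object@ligandConcB / object@proteinConc))
  cat(sprintf("  TSP: %.3g (a) vs %.3g (b) a.u.\n",
              object@tspConcA, object@tspConcB))
})

setMethod("show", "MixingSchedule", function(object) {
  s <- object@schedule
  cat("MixingSchedule with", nrow(s), "steps ([P] =",
      object@proteinConc, "uM)\n")
  cat(sprintf("  alpha: %.4g -> %.4g\n", s$alpha[1], s$alpha[nrow(s)]))
  print(utils::head(s, 4))
  if (nrow(s) > 4) cat("  ...", nrow(s) - 4, "more steps\n")
})

setMethod("show", "TitrationSeries", function(object) {
  cat("TitrationSeries with", nSteps(object), "steps\n")
  npk <- vapply(object@peakLists, nrow, integer(1))
  cat(sprintf("  peaks per step: %s\n",
              paste(range(npk), collapse = "-")))
  cat(sprintf("  I_TSP: %.4g -> %.4g a.u.\n",
              object@iTSP[1], object@iTSP[length(object@iTSP)]))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "CSPTable", function(object) {
  cat("CSPTable:", length(object@label), "residues x",
      ncol(object@dd), "steps\n")
  cat(sprintf("  sigma_c = %.4g ppm (%d iteration%s); %d significant, %d overlap-flagged\n",
              object@sigmaC, object@sigmaIterations,
              if (object@sigmaIterations == 1L) "" else "s",
              sum(object@significant), sum(object@overlap)))
  cat(sprintf("  saturation diagnostic: %.4g ppm (saturated step %d)\n",
              object@saturationDiagnostic, object@saturatedStep))
})

setMethod("show", "SignificanceResult", function(object) {
  cat(sprintf("SignificanceResult: sigma_c = %.4g ppm after %d iteration%s; %d values excluded, %d significant\n",
              object@sigmaC, object@iterations,
              if (object@iterations == 1L) "" else "s",
              length(object@excluded), sum(object@significant)))
})

setMethod("show", "BindingFitResult", function(object) {
  cat("BindingFitResult",
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  ci <- object@ci95
  cat(sprintf("  K_D = %.4g uM  95%% CI [%.4g, %.4g]\n",
              object@kD, ci["kD", "lower"], ci["kD", "upper"]))
  cat(sprintf("  beta_D = %.4g; calibration alpha = %.4g * I_TSP + %.4g\n",
              object@betaD, object@calSlope, object@calIntercept))
  cat(sprintf("  %d residues, %d points, residual sd %.3g, dof %d\n",
              length(object@labelsUsed), nrow(object@residuals),
              object@sigmaResid, object@dof))
})

setMethod("show", "PatchReport", function(object) {
  cat("PatchReport:", nrow(object@patches), "patches\n")
  if (nrow(object@patches)) {
    for (i in seq_len(nrow(object@patches)))
      cat(sprintf("  %d-%d: %s\n", object@patches$start[i],
                  object@patches$end[i],
                  paste(object@members[[i]], collapse = ", ")))
  }
  if (length(object@singletons))
    cat("  singletons:", paste(object@singletons, collapse = ", "), "\n")
  if (length(object@sideChainHits))
    cat("  side-chain hits:", paste(object@sideChainHits, collapse = ", "), "\n")
})
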