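# Fyn-SH3-like reference sequence used by the synthetic fixture.
# Positions 82-142; the two prolines (134, 140) have no backbone amide,
# leaving 59 observable NH signals. Residue identities at the positions
# that matter for the binding-site layout (R96, E98, D100, G117,
# W119/W120, Y132, Y135, Y137) follow the hFynSH3 convention; the rest
# is a plausible SH3 fill. This is a synthetic mimic, not deposited
# experimental data.
.hfynSeq <- c(
  "82" = "T", "83" = "G", "84" = "V", "85" = "T", "86" = "L", "87" = "F",
  "88" = "V", "89" = "A", "90" = "L", "91" = "Y", "92" = "D", "93" = "Y",
  "94" = "E", "95" = "A", "96" = "R", "97" = "T", "98" = "E", "99" = "D",
  "100" = "D", "101" = "L", "102" = "S", "103" = "F", "104" = "H",
  "105" = "K", "106" = "G", "107" = "E", "108" = "K", "109" = "F",
  "110" = "Q", "111" = "I", "112" = "L", "113" = "N", "114" = "S",
  "115" = "S", "116" = "E", "117" = "G", "118" = "D", "119" = "W",
  "120" = "W", "121" = "E", "122" = "A", "123" = "R", "124" = "S",
  "125" = "L", "126" = "T", "127" = "T", "128" = "G", "129" = "E",
  "130" = "T", "131" = "G", "132" = "Y", "133" = "I", "134" = "P",
  "135" = "Y", "136" = "S", "137" = "Y", "138" = "V", "139" = "A",
  "140" = "P", "141" = "V", "142" = "D")

# residue numbers of the three ground-truth binding patches
.hfynPatchResidues <- c(96:100, 117:120, 135:137)

#' Synthetic hFynSH3-mimic titration fixture
#'
#' Builds a complete synthetic titration modelled on an SH3
#' domain--peptide interaction: 59 assigned backbone amide signals
#' (SH3 positions 82-142, prolines absent), of which exactly the 12
#' residues in the three binding patches 96-100, 117-120 and 135-137
#' carry large saturated perturbations (weighted ddMax drawn uniformly
#' from 0.12-0.20 ppm, typical of a peptide contact surface and far
#' above the noise floor); all other residues have zero true
#' perturbation. The titration is an 11-point displacement-mixing
#' series (protein-only reference plus 10 injections of nominally 2 uL
#' into a 10 uL circuit) with a five-fold ligand excess in the
#' saturating solution.
#'
#' @param seed integer seed; fixes peak positions, injected volumes and
#'   all noise draws (the same seed always yields an identical series)
#' @param kD ground-truth dissociation constant (uM)
#' @param proteinConc protein concentration (uM); with the default,
#'   beta_D = kD/1000 sits well inside the fittable regime
#' @param noise a [NoiseModel]; defaults to the standard noise model
#'   seeded by \code{seed}; pass \code{noiselessModel(seed)} for exact
#'   data
#' @param exactVolumes inject exactly 2 uL each step (TRUE) or draw
#'   volumes with the nominal 0.25 uL sd (FALSE, default)
#' @param overlapPair place the Y132 peak within the default overlap
#'   tolerance of E98 (the spectral-overlap scenario); off by default
#' @return a list with elements \code{series} (a [TitrationSeries]),
#'   \code{protein} (the [proteinDef()] used), \code{chip}
#'   ([ChipParams]), \code{schedule} ([MixingSchedule]) and
#'   \code{groundTruth} (kD, betaD, proteinConc, per-step alpha,
#'   perturbed labels and weighted ddMax)
#' @examples
#' fx <- makeFixtureHfyn(seed = 1)
#' fx$series
#' @export
makeFixtureHfyn <- function(seed = 1L, kD = 48, proteinConc = 1000,
                            noise = NoiseModel(seed = seed),
                            exactVolumes = FALSE, overlapPair = FALSE) {
  seed <- as.integer(seed)
  resno <- as.integer(names(.hfynSeq))
  keep <- .hfynSeq != "P"
  resno <- resno[keep]
  aa <- .hfynSeq[keep]
  labels <- paste0(aa, resno)
  nres <- length(labels)

  protein <- withSeed(seed + 1000L, {
    dH0 <- stats::rnorm(nres, 8.3, 0.45)
    dN0 <- stats::rnorm(nres, 119, 4)
    ddH <- numeric(nres)
    ddN <- numeric(nres)
    hit <- resno %in% .hfynPatchResidues
    mag <- stats::runif(sum(hit), 0.12, 0.20)   # weighted ddMax (ppm)
    ang <- stats::runif(sum(hit), 0.25, 1.32)   # split between H and N
    sgnH <- sample(c(-1, 1), sum(hit), replace = TRUE)
    sgnN <- sample(c(-1, 1), sum(hit), replace = TRUE)
    ddH[hit] <- sgnH * mag * cos(ang)
    ddN[hit] <- sgnN * mag * sin(ang) / 0.14
    if (overlapPair) {
      i98 <- match("E98", labels)
      i132 <- match("Y132", labels)
      dH0[i132] <- dH0[i98] + 0.005
      dN0[i132] <- dN0[i98] + 0.05
    }
    proteinDef(labels, dH0, dN0, ddH, ddN)
  })

  chip <- ChipParams(circuitVolume = 10, injectionVolumeMean = 2,
                     injectionVolumeSd = if (exactVolumes) 0 else 0.25,
                     nSteps = 10L, proteinConc = proteinConc,
                     ligandConcB = 5 * proteinConc,
                     tspConcA = 10, tspConcB = 0.5)
  schedule <- simulateMixingSchedule(chip, noise)
  betaD <- kD / proteinConc
  series <- generatePeakLists(protein, schedule, betaD, noise)
  gt <- series@metadata$groundTruth
  gt$patchResidues <- .hfynPatchResidues
  list(series = series, protein = protein, chip = chip,
       schedule = schedule, groundTruth = gt)
}
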