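#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so simulation helpers are reproducible
#' without clobbering the session stream.
#' @noRd
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate the displacement-mixing schedule of a microfluidic titration
#'
#' Single-compartment model of the chip circuit: at each titration step
#' a volume v (drawn from Normal(mean, sd) truncated to (0, V)) of the
#' protein--ligand solution b is injected into the fully mixed circuit
#' of working volume V, displacing an equal volume out of the chip.
#' Every solute concentration updates as
#' \code{c <- (c * (V - v) + c_b * v) / V}; the protein concentration is
#' identical in both solutions and therefore constant throughout. Step 0
#' is the untouched protein-only solution a. For constant v the ligand
#' load follows the closed form \code{1 - (1 - v/V)^n} of its recursion.
#'
#' @param chip a [ChipParams] object
#' @param noise a [NoiseModel]; only the injection-volume randomness is
#'   used here (set \code{injectionVolumeSd = 0} in \code{chip} for an
#'   exact schedule), seeded by \code{noise@seed}
#' @return a [MixingSchedule] with one row per spectrum (nSteps + 1)
#' @examples
#' sched <- simulateMixingSchedule(
#'   ChipParams(injectionVolumeSd = 0), noiselessModel())
#' alphaValues(sched)
#' @export
simulateMixingSchedule <- function(chip, noise = NoiseModel()) {
  validObject(chip)
  validObject(noise)
  V <- chip@circuitVolume
  n <- chip@nSteps
  vols <- withSeed(noise@seed, drawInjectionVolumes(
    n, chip@injectionVolumeMean, chip@injectionVolumeSd, V))
  lig <- numeric(n + 1)
  tsp <- numeric(n + 1)
  lig[1] <- 0
  tsp[1] <- chip@tspConcA
  for (k in seq_len(n)) {
    v <- vols[k]
    lig[k + 1] <- (lig[k] * (V - v) + chip@ligandConcB * v) / V
    tsp[k + 1] <- (tsp[k] * (V - v) + chip@tspConcB * v) / V
  }
  sched <- data.frame(
    step = 0:n,
    ligandConc = lig,
    tspConc = tsp,
    alpha = lig / chip@proteinConc,
    injectedVolume = c(0, vols))
  new("MixingSchedule", schedule = sched, proteinConc = chip@proteinConc)
}

# truncated-normal injection volumes; rejection sampling is cheap at
# these sds and keeps the draw exactly Normal within (0, V)
drawInjectionVolumes <- function(n, mean, sd, V) {
  if (sd == 0) return(rep(mean, n))
  vols <- numeric(n)
  for (k in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > 0 && v < V) break
    }
    vols[k] <- v
  }
  vols
}

#' Define the simulated protein
#'
#' A protein definition is a data.frame with one row per observable
#' amide signal: \code{label} (unique residue identifier, e.g.
#' \code{"R96"}, optionally carrying a side-chain tag such as
#' \code{"W119NE1"}), free-state shifts \code{deltaH0}/\code{deltaN0}
#' (ppm), and the saturated perturbations \code{ddMaxH}/\code{ddMaxN}
#' (ppm), zero for residues that do not respond to ligand.
#'
#' @param label character residue labels (unique, non-empty)
#' @param deltaH0,deltaN0 free-protein chemical shifts (ppm)
#' @param ddMaxH,ddMaxN saturated chemical-shift changes (ppm)
#' @return a validated protein-definition data.frame
#' @export
proteinDef <- function(label, deltaH0, deltaN0, ddMaxH = 0, ddMaxN = 0) {
  pd <- data.frame(label = as.character(label), deltaH0 = deltaH0,
                   deltaN0 = deltaN0, ddMaxH = ddMaxH, ddMaxN = ddMaxN,
                   stringsAsFactors = FALSE)
  if (any(!nzchar(pd$label))) stop("labels must be non-empty")
  if (anyDuplicated(pd$label)) stop("labels must be unique")
  if (any(!is.finite(as.matrix(pd[-1])))) stop("shift fields must be finite")
  pd
}

#' Generate synthetic HSQC peak lists for a titration
#'
#' At each step of the schedule every residue's peak sits at the
#' population-weighted average position of its free and bound states
#' (two-state fast exchange): \code{delta = delta_free + f(alpha,
#' beta_D) * ddMax}, componentwise in 1H and 15N, so each noiseless
#' trajectory is exactly collinear. Gaussian shift noise and relative
#' intensity noise are then added, and the per-step TSP 1D intensity is
#' \code{calibrationGain * tspConc * (1 + noise)}.
#'
#' @param protein a [proteinDef()] data.frame
#' @param schedule a [MixingSchedule]
#' @param betaD ground-truth dimensionless dissociation constant (> 0)
#' @param noise a [NoiseModel]
#' @param calibrationGain TSP intensity per concentration unit (a.u.);
#'   arbitrary, since the downstream fit estimates the calibration
#' @param peakIntensity nominal cross-peak height (a.u.)
#' @return a [TitrationSeries]; \code{metadata$groundTruth} records the
#'   generating parameters (betaD, kD, proteinConc, alpha and f per
#'   step, perturbed labels and their weighted ddMax)
#' @export
generatePeakLists <- function(protein, schedule, betaD, noise = NoiseModel(),
                              calibrationGain = 1, peakIntensity = 1e5) {
  if (betaD <= 0) stop("betaD must be > 0")
  validObject(schedule)
  sch <- schedule@schedule
  nstep <- nrow(sch)
  nres <- nrow(protein)
  f <- fractionalShift(sch$alpha, betaD)
  withSeed(noise@seed, {
    peakLists <- vector("list", nstep)
    for (j in seq_len(nstep)) {
      dH <- protein$deltaH0 + f[j] * protein$ddMaxH +
        stats::rnorm(nres, 0, noise@shiftNoiseH)
      dN <- protein$deltaN0 + f[j] * protein$ddMaxN +
        stats::rnorm(nres, 0, noise@shiftNoiseN)
      int <- peakIntensity *
        (1 + stats::rnorm(nres, 0, noise@intensityRelNoise))
      peakLists[[j]] <- data.frame(label = protein$label, deltaH = dH,
                                   deltaN = dN, intensity = int,
                                   stringsAsFactors = FALSE)
    }
    itsp <- calibrationGain * sch$tspConc *
      (1 + stats::rnorm(nstep, 0, noise@intensityRelNoise))
    TitrationSeries(
      step = sch$step, peakLists = peakLists, iTSP = itsp,
      metadata = list(groundTruth = list(
        betaD = betaD,
        kD = betaD * schedule@proteinConc,
        proteinConc = schedule@proteinConc,
        alpha = sch$alpha,
        f = f,
        calibrationGain = calibrationGain,
        perturbedLabels = protein$label[
          protein$ddMaxH != 0 | protein$ddMaxN != 0],
        ddMaxWeighted = setNames(
          sqrt(protein$ddMaxH^2 + (0.14 * protein$ddMaxN)^2),
          protein$label))))
  })
}
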