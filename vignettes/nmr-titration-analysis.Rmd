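---
title: "Quantifying protein–ligand binding from HSQC titration series"
author: "nmrtitr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein–ligand binding from HSQC titration series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrtitr)
```

## The measurement

A protein-observed NMR titration follows the ¹H–¹⁵N HSQC spectrum of a
labelled protein while the ligand-to-protein molar ratio α = [L]/[P]
is stepped up. When binding kinetics are fast on the chemical-shift
time scale, every amide cross-peak sits at the population-weighted
average of its free and bound positions, so each peak moves along a
straight line between the two endpoints and its displacement is a
direct, per-residue readout of the bound fraction. `nmrtitr`
implements the analysis half of an automated microfluidic version of
this experiment: the mixing hardware produces a series of peak lists
plus a 1D intensity of an internal standard (TSP), and the package
turns those into a dissociation constant, a set of significant
residues, and a binding-site map.

## Two-state model in dimensionless form

With the dimensionless dissociation constant β_D = K_D/[P], mass
action for a single site gives the bound fraction as the physical root
of a quadratic:

$$ f(\alpha, \beta_D) \;=\; \frac{(\alpha + 1 + \beta_D) -
   \sqrt{(\alpha + 1 + \beta_D)^2 - 4\alpha}}{2}. $$

`fractionalShift()` evaluates the algebraically equivalent conjugate
form $2\alpha / (s + \sqrt{s^2 - 4\alpha})$ with $s = \alpha + 1 +
\beta_D$. The textbook form subtracts two nearly equal numbers when
$f$ is small and loses all precision; the conjugate form is accurate
for β_D down to 10⁻⁸ and below, which the test suite verifies against
an independent numerical solution of the mass-action equilibrium
(`uniroot` on $\beta_D f = (1-f)(\alpha-f)$) over a 200 × 200 grid.

## Chemical shift perturbations and significance

Per residue and step, the two shift differences combine into one CSP
in proton-ppm units,

$$ \Delta\delta = \sqrt{\Delta\delta_H^2 + (0.14\,\Delta\delta_N)^2}, $$

with the conventional amide ¹⁵N weight 0.14 (configurable). The CSP at
the final (saturated) step, Δδ_max, summarizes each residue.
Significant residues are selected by the corrected standard deviation
σ_c: the standard deviation of all Δδ_max about zero is computed,
values above 3σ are excluded, and the procedure iterates to a fixed
point; residues with Δδ_max strictly greater than the final σ_c are
significant. The "about zero" centring reflects that CSP magnitudes of
non-interacting residues scatter about zero; centring about the mean
and the exclusion multiplier are exposed as options. A brute-force
test enumerates every possible exclusion order on small inputs and
confirms the iteration's fixed point is order-independent.

Saturation is not assumed: `buildCspTable()` reports the largest
change in CSP between the last two spectra as a diagnostic, and the
saturated step is configurable rather than automatically gated.

## TSP calibration and the global fit

In the microfluidic experiment the ligand concentration is not set by
hand; it results from displacement mixing and is read off the
intensity of the TSP internal standard, which differs by an order of
magnitude between the two stock solutions. Because both α and the TSP
concentration are affine in the mixing fraction, α is an affine
function of the measured intensity, α = slope · I_TSP + intercept.
The calibration is estimated inside the fit rather than fixed
beforehand: `globalFit()` minimizes, over all significant non-overlapped
residues i and steps j,

$$ \sum_{i,j} \left[ \frac{\Delta\delta_{ij}}{\Delta\delta_{\max,i}}
   - \frac{f(\alpha_j, \beta_D)}{f(\alpha_{sat}, \beta_D)} \right]^2 $$

by Levenberg–Marquardt over (log β_D, slope, intercept). Two choices
here deserve comment.

**Self-consistent normalization.** The data are normalized by the
*observed* saturated-step CSP, so the model is divided by its own
value at that step. If the final point has truly saturated the
protein the divisor is 1 and the term reduces to the plain isotherm;
if not, dividing keeps model and data on the same scale. Omitting the
divisor biases K_D severely whenever the last step falls short of
saturation — under the package's default schedule (α_max = 5, final
α ≈ 4.46, f ≈ 0.986) the noiseless fit would return ≈ 20 μM for a
true 48 μM. With the divisor the noiseless fit recovers K_D, slope
and intercept to better than 10⁻⁶ relative, which the acceptance
suite checks.

**Positivity and the region α < 0.** β_D is fitted as log β_D, which
enforces positivity without constraints. During optimization the
calibration can transiently map the ligand-free intensity to a
slightly negative α; the fit therefore extends f linearly for α < 0
with its slope at the origin, $\alpha/(1+\beta_D)$. A hard clamp at
zero instead creates a flat, gradient-free region in which the
optimizer can park a grossly unphysical calibration (the step-0
spectrum then no longer constrains the intercept at all); the smooth
continuation lets the reference spectrum pull the calibration back.

Initialization takes the calibration from nominal endpoint α values
and β_D from a 20-point log-grid profile scan; the optimum has been
spot-checked against a dense profile-likelihood scan.

**Confidence intervals.** The default interval is the t-interval
formed on log β_D (the actual free parameter) from the
covariance matrix σ̂²(JᵀJ)⁻¹ and transformed, which respects
positivity and the right-skew of the estimate; K_D intervals are the
β_D interval scaled by [P], and calibration parameters get plain
symmetric t-intervals. A residue-cluster bootstrap is available as an
option (`ciMethod = "bootstrap"`): all points of one residue share its
step-0 reference and its normalizer, so the residue — not the single
point — is the exchangeable unit.

Overlap-flagged residues are excluded from the fit by default, since a
neighbouring peak within the tolerance corrupts the measured CSP; a
user exclusion list is honoured on top.

## Binding-site patches and structure mapping

`findPatches()` groups significant backbone residues into runs whose
consecutive members are at most `maxGap` apart in sequence (default 1,
strictly consecutive, which is the strictest reading of a contiguous
patch); single-residue runs are reported as singletons, and side-chain
signals such as a tryptophan NHε are listed separately, attributed to
their residue number. `writeStructureMap()` writes Δδ_max × 100 into
the temperature-factor column of a user-supplied PDB file (two
decimals survive the fixed-width field; unassigned residues get the
sentinel −1.00) and touches nothing else — the output is byte-identical
to the input outside those six columns, so downstream tools see an
otherwise untouched structure. When a side-chain and a backbone signal
report the same residue the larger value wins by default.

## What the synthetic generator emulates

`simulateMixingSchedule()` is a single-compartment model of the chip:
each injection of volume v (Normal with mean 2 μL and sd 0.25 μL,
truncated to (0, V)) into the fully mixed circuit of working volume
V = 10 μL displaces an equal volume, so every solute follows
c ← (c(V−v) + c_b v)/V and, for constant v, the ligand load follows
the closed form 1 − (1 − v/V)ⁿ. Such hardware does not by itself
distinguish plug-flow from mixed displacement; the single-compartment
recursion is the simplest model consistent with displacement of the
previously mixed solution, and the analysis is insulated from the
choice because the TSP intensity — not the nominal schedule — carries
the concentration information into the fit.

`generatePeakLists()` places every peak at δ_free + f·Δδ_max
componentwise (hence exactly collinear trajectories without noise) and
adds Gaussian shift noise, relative intensity noise, and a TSP
intensity proportional to the TSP concentration. Defaults: shift noise
0.002 ppm (¹H) and 0.02 ppm (¹⁵N), of the order of a sub-10 Hz
apparent resolution at 14.1 T; relative intensity noise 0.01, a
conservative figure for a concentrated reference singlet in a 1D
spectrum.

`makeFixtureHfyn()` builds a complete SH3-mimic study: 59 backbone
amides at positions 82–142 of a Fyn-SH3-like sequence (the two
prolines carry no amide), with exactly the 12 residues of the three
patches 96–100, 117–120 and 135–137 perturbed. Their weighted Δδ_max
are drawn uniformly from 0.12–0.20 ppm — typical saturated amide CSPs
at a peptide interface — and all other residues have zero true
perturbation; the protein concentration defaults to 1000 μM so
β_D = K_D/[P] sits well inside the fittable regime, with the true
K_D (default 48 μM) recorded in a ground-truth sidecar. What the
generator does *not* emulate: lineshapes, intensity loss from exchange
broadening, intermediate/slow exchange, assignment errors, baseline
and phasing artifacts, and genuinely small-but-nonzero perturbations
of distal residues. Passing tests therefore demonstrate correctness
of the analysis chain under the stated statistical model, not
robustness to every pathology of real spectra.

## Identifiability at the default schedule

A property worth understanding before trusting any single noisy run:
the default displacement schedule places only one spectrum on the
rising limb of the isotherm (α ≈ 1; the remaining steps sit at
α ≥ 1.8 where f is nearly saturated). With the calibration slope and
intercept free, the likelihood then has a shallow valley coupling
β_D to the calibration, and at the default noise level the package's
own acceptance suite measures a median |K_D error| of roughly a
quarter of K_D across seeds, with interval coverage in the low 80s of
percent — the fit is exact on noiseless data (the same suite recovers
48 μM to 0.1%) and unbiased in the median, but a single run at this
noise is not a 10%-accurate measurement. This is a property of the
experimental design, not of the estimator: supplying the true α
values (`alphaKnown`) cuts the error to a few percent, and schedules
with several points below α ≈ 1, a known α_max, or lower shift noise
tighten it accordingly. Users planning real titrations should front-
load injection volumes so that several steps sample the rising limb.

## Numerical and degenerate-input policy

- Conjugate-root evaluation of f; discriminant clamped at zero against
  roundoff (it is analytically non-negative).
- σ_c on identically zero inputs returns 0 with nothing significant
  (the cutoff is strictly greater-than); fewer than three values is an
  error, not a guess.
- Nearest-neighbour peak linking rejects links beyond the axis
  tolerances and refuses to guess between two candidates within
  10⁻⁶ ppm weighted distance (the trajectory is marked ambiguous).
- Trajectory linearity needs at least three points; the score is the
  maximum perpendicular deviation from the total-least-squares line
  (degenerate all-identical trajectories score 0).
- A significant residue with zero saturated CSP cannot be normalized
  and is dropped from the fit with a warning; fewer than four steps or
  an empty significant set abort the fit with a clear error.
- Pipeline reruns are byte-identical apart from the log timestamp;
  every run directory archives its resolved configuration and seed.

## Problem sizes used in the test suite

Unit and acceptance tests run on the 59-residue, 11-step fixture
(single fits take well under a second); the statistical-recovery check
uses 50 independent seeds, the oracle-equivalence check a 200 × 200
(α, β_D) grid, and the exclusion-order enumeration lists of up to 8
values. These sizes make the full suite complete in well under a
minute while still exercising every code path at realistic scale.
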