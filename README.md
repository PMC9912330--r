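# nmrtitr

Quantitative analysis of protein-observed NMR titrations, built for
the output of automated microfluidic mixing platforms: series of
¹H–¹⁵N HSQC peak lists acquired at increasing ligand-to-protein ratio,
with a TSP internal-standard 1D intensity reporting the mixing state
of each step. The package takes peak lists in and returns a
dissociation constant with confidence intervals, the set of
significantly perturbed residues, and the binding-site patches they
form on the sequence and structure.

It is aimed at structural biologists and biophysicists running (or
simulating) chemical-shift-perturbation titrations who want the whole
chain — peak-list parsing, CSP computation, significance selection,
global isotherm fitting, site mapping — scripted, tested, and
reproducible.

## The model

Under two-state fast exchange, each amide's chemical shift
perturbation Δδ = √(Δδ_H² + (0.14 Δδ_N)²) is proportional to the
bound protein fraction. In dimensionless variables α = [L]/[P] and
β_D = K_D/[P], mass action gives the bound fraction

    f(α, β_D) = ((α + 1 + β_D) − sqrt((α + 1 + β_D)² − 4α)) / 2,

evaluated internally in its numerically stable conjugate form. In the
microfluidic experiment α is not pipetted but inferred from the TSP
intensity through the affine calibration α = slope·I_TSP + intercept.
The global fit minimizes

    Σᵢⱼ [ Δδᵢⱼ/Δδ_max,i − f(αⱼ, β_D)/f(α_sat, β_D) ]²

over (log β_D, slope, intercept) by Levenberg–Marquardt, pooling all
significant residues; significance uses the iterative
corrected-standard-deviation cutoff σ_c (exclude > 3σ, iterate,
select Δδ_max > σ_c). Dividing the model by its saturated-step value
mirrors the normalization of the data and keeps K_D unbiased when the
final step has not fully saturated the protein.

## Worked example

Everything below runs without any external data: the synthetic module
generates a complete SH3-domain-mimic titration (59 assigned amides,
11 displacement-mixing steps, ground-truth K_D = 48 μM at
[P] = 1000 μM) with realistic shift and intensity noise.

```r
library(nmrtitr)

fx  <- makeFixtureHfyn(seed = 1, kD = 48, proteinConc = 1000)
csp <- buildCspTable(fx$series)
csp
#> CSPTable: 59 residues x 11 steps
#>   sigma_c = 0.07577 ppm (1 iteration); 12 significant, 8 overlap-flagged
#>   saturation diagnostic: 0.01085 ppm (saturated step 10)

fit <- globalFit(csp, fx$series, proteinConc = 1000)
fit
#> BindingFitResult (converged)
#>   K_D = 64.88 uM  95% CI [43.21, 97.41]
#>   beta_D = 0.06488; calibration alpha = -0.5625 * I_TSP + 5.628
#>   11 residues, 121 points, residual sd 0.0192, dof 118

findPatches(csp)
#> PatchReport: 3 patches
#>   96-100: R96, T97, E98, D99, D100
#>   117-120: G117, D118, W119, W120
#>   135-137: Y135, S136, Y137
```

Reading the output: 12 of 59 amides exceed the σ_c significance
cutoff (0.076 ppm) and they group into three contiguous sequence
patches — the binding surface. The saturation diagnostic (largest CSP
change between the last two spectra, 0.011 ppm) confirms the
titration reached saturation. The global fit pools the 11 significant
non-overlapped residues (one is dropped for spectral overlap) and
returns K_D with a 95% interval that covers the generating 48 μM; on
noiseless data the same fit returns 48.000 μM. Single noisy runs
under this schedule scatter substantially around the truth because
only one titration step samples the rising limb of the isotherm — see
the vignette's identifiability section before designing a real
schedule.

Real data enter through `readSeries("manifest.csv")`, a manifest of
per-step Sparky or CSV peak lists plus TSP intensities;
`runPipeline()` (or the `inst/scripts/nmrtitr` command-line wrapper)
chains analyze → fit → map and archives every result, the resolved
configuration and the seed in an output directory. With a PDB file
configured, `writeStructureMap()` writes Δδ_max into the
temperature-factor column for structure coloring.

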