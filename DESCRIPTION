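Package: nmrtitr
Title: Automated Analysis of Protein-Ligand NMR Titration Series
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative analysis of protein-observed NMR
    titrations acquired as series of 2D HSQC peak lists, as produced by
    automated microfluidic mixing platforms. Computes isotope-weighted
    chemical shift perturbations (CSPs), tracks peaks across titration
    steps, tests two-state fast-exchange trajectory linearity, selects
    significant residues by the iterative corrected-standard-deviation
    cutoff, fits the dimensionless two-state binding isotherm globally
    against an internal-standard (TSP) intensity calibration to obtain
    the dissociation constant K_D with 95% confidence intervals, and
    maps significant perturbations onto contiguous binding-site patches
    and PDB structures. A synthetic-data module emulates displacement
    mixing of a microfluidic circuit and two-state fast-exchange peak
    movement so the entire pipeline is testable without spectrometer
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
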