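#' Assemble and validate a pipeline configuration
#'
#' Collects every option of the end-to-end analysis in one validated
#' list; [runPipeline()] accepts either this object or a YAML file with
#' the same fields. Validation happens before any stage runs, so a
#' broken configuration fails fast.
#'
#' @param manifest path to the titration-series manifest (required)
#' @param outputDir directory for all run outputs (required; created)
#' @param proteinConc protein concentration in uM (required for the fit)
#' @param pdb optional PDB file for structure mapping
#' @param chain optional chain identifier within the PDB
#' @param nWeight,tolH,tolN,matchMode,saturatedStep,exclusionFactor,about
#'   analysis options, see [buildCspTable()]
#' @param exclude,ciMethod,alphaMaxNominal fit options, see
#'   [globalFit()]
#' @param maxGap patch-grouping option, see [findPatches()]
#' @param seed RNG seed (used by the bootstrap CI, if selected)
#' @return a validated configuration list of class \code{runConfig}
#' @export
runConfig <- function(manifest, outputDir, proteinConc, pdb = NULL,
                      chain = NULL, nWeight = 0.14, tolH = 0.02,
                      tolN = 0.2, matchMode = "by_label",
                      saturatedStep = NULL, exclusionFactor = 3,
                      about = "zero", exclude = character(),
                      ciMethod = "covariance", alphaMaxNominal = 5,
                      maxGap = 1, seed = 1L) {
  if (missing(manifest) || is.null(manifest))
    stop("config error: 'manifest' is required")
  if (missing(outputDir) || is.null(outputDir))
    stop("config error: 'outputDir' is required")
  if (missing(proteinConc) || is.null(proteinConc))
    stop("config error: 'proteinConc' is required")
  if (!is.numeric(proteinConc) || proteinConc <= 0)
    stop("config error: 'proteinConc' must be a positive number (uM)")
  if (!matchMode %in% c("by_label", "nearest"))
    stop("config error: matchMode must be by_label or nearest")
  if (!ciMethod %in% c("covariance", "bootstrap"))
    stop("config error: ciMethod must be covariance or bootstrap")
  cfg <- list(manifest = manifest, outputDir = outputDir,
              proteinConc = proteinConc, pdb = pdb, chain = chain,
              nWeight = nWeight, tolH = tolH, tolN = tolN,
              matchMode = matchMode, saturatedStep = saturatedStep,
              exclusionFactor = exclusionFactor, about = about,
              exclude = exclude, ciMethod = ciMethod,
              alphaMaxNominal = alphaMaxNominal, maxGap = maxGap,
              seed = as.integer(seed))
  class(cfg) <- "runConfig"
  cfg
}

stageCall <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s stage] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full titration analysis pipeline
#'
#' Executes analyze (CSP table), fit (global K_D fit) and map (patches
#' and, when a PDB is configured, structure coloring) on one titration
#' series, writing every result plus the resolved configuration and a
#' log into the output directory. Apart from the timestamp line in the
#' log, a rerun with the same configuration reproduces the outputs
#' byte for byte. Partial outputs are retained when a later stage
#' fails, and the error message names the failing stage.
#'
#' Output files: \code{csp_table.csv}, \code{fit_report.json},
#' \code{patch_report.json}, \code{structure_map.pdb} (optional),
#' \code{config.yaml}, \code{run.log}.
#'
#' @param config a [runConfig()] object, a list of its fields, or the
#'   path to a YAML file holding them
#' @return invisibly, a list with the output directory, the
#'   [CSPTable-class], the [BindingFitResult-class] and the
#'   [PatchReport-class]
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!inherits(config, "runConfig"))
    config <- do.call(runConfig, config)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outputDir, f)

  cfgOut <- config
  class(cfgOut) <- NULL
  cfgOut <- cfgOut[!vapply(cfgOut, is.null, logical(1))]
  yaml::write_yaml(cfgOut, out("config.yaml"))

  log <- c(sprintf("nmrtitr %s",
                   as.character(utils::packageVersion("nmrtitr"))),
           sprintf("R %s", as.character(getRversion())),
           sprintf("seed %d", config$seed),
           sprintf("started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))

  series <- stageCall("read", readSeries(config$manifest))
  csp <- stageCall("analyze", buildCspTable(
    series, saturatedStep = config$saturatedStep,
    matchMode = config$matchMode, tolH = config$tolH,
    tolN = config$tolN, nWeight = config$nWeight,
    exclusionFactor = config$exclusionFactor, about = config$about))
  utils::write.csv(as.data.frame(csp), out("csp_table.csv"),
                   row.names = FALSE)
  log <- c(log, sprintf("analyze: %d residues, sigma_c = %.6g ppm, %d significant",
                        length(csp@label), csp@sigmaC,
                        sum(csp@significant)))

  fit <- stageCall("fit", globalFit(
    csp, series, proteinConc = config$proteinConc,
    exclude = config$exclude, ciMethod = config$ciMethod,
    alphaMaxNominal = config$alphaMaxNominal,
    bootSeed = config$seed))
  report <- list(
    converged = fit@converged,
    K_D_uM = fit@kD,
    K_D_ci95 = as.list(fit@ci95["kD", c("lower", "upper")]),
    beta_D = fit@betaD,
    cal_slope = fit@calSlope,
    cal_intercept = fit@calIntercept,
    protein_conc_uM = fit@proteinConc,
    residues_used = fit@labelsUsed,
    sigma_c_ppm = csp@sigmaC,
    saturation_diagnostic_ppm = csp@saturationDiagnostic,
    residual_sd = fit@sigmaResid,
    dof = fit@dof,
    alpha_per_step = fit@alpha)
  jsonlite::write_json(report, out("fit_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(fit@residuals, out("fit_residuals.csv"),
                   row.names = FALSE)
  log <- c(log, sprintf("fit: K_D = %.6g uM [%.6g, %.6g], converged = %s",
                        fit@kD, fit@ci95["kD", "lower"],
                        fit@ci95["kD", "upper"], fit@converged))

  pr <- stageCall("map", findPatches(csp, maxGap = config$maxGap))
  patchReport <- list(
    patches = lapply(seq_len(nrow(pr@patches)), function(i)
      list(start = pr@patches$start[i], end = pr@patches$end[i],
           members = pr@members[[i]])),
    singletons = pr@singletons,
    side_chain_hits = pr@sideChainHits)
  jsonlite::write_json(patchReport, out("patch_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- c(log, sprintf("map: %d patches", nrow(pr@patches)))

  if (!is.null(config$pdb)) {
    stageCall("map", writeStructureMap(config$pdb, csp,
                                       out("structure_map.pdb"),
                                       chain = config$chain))
    log <- c(log, "map: structure_map.pdb written")
  }
  if (!fit@converged) log <- c(log, "WARNING: fit did not converge")
  writeLines(log, out("run.log"))
  invisible(list(outputDir = config$outputDir, csp = csp, fit = fit,
                 patches = pr))
}
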