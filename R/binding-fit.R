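#' Global two-state binding fit of a titration series
#'
#' Fits all significant, non-overlapping residues' fractional shifts
#' jointly to the dimensionless two-state isotherm, with the
#' dissociation constant and the TSP-intensity calibration as the free
#' parameters. Each observation is the CSP of residue i at step j
#' normalized by that residue's saturated-step CSP; the model value is
#' \deqn{\hat y_{ij} = f(\alpha_j, \beta_D) / f(\alpha_{sat}, \beta_D)}
#' with \eqn{\alpha_j = slope \cdot I_{TSP,j} + intercept} and f from
#' [fractionalShift()]. Dividing by the model value at the saturated
#' step mirrors the normalization applied to the data, so the fit is
#' unbiased even when the final titration point has not fully reached
#' saturation; at true saturation the divisor is 1 and the model
#' reduces to the plain isotherm. Minimization is by
#' Levenberg--Marquardt (\code{minpack.lm}) over (log beta_D, slope,
#' intercept); the log parameterization enforces beta_D > 0 without
#' constraint machinery.
#'
#' Overlap-flagged residues are excluded by default (their CSPs are
#' corrupted by the neighbouring peak); a user exclusion list is
#' honoured on top. Residues with zero saturated CSP cannot be
#' normalized and are dropped with a warning.
#'
#' @param csp a [CSPTable-class] from [buildCspTable()]
#' @param series the [TitrationSeries] the table was built from (source
#'   of the per-step TSP intensities)
#' @param proteinConc total protein concentration (uM), used to scale
#'   beta_D to K_D
#' @param exclude labels to exclude in addition to overlap-flagged ones
#' @param includeOverlap keep overlap-flagged residues (default FALSE)
#' @param alphaKnown optional vector of known alpha values per step;
#'   when supplied the calibration is not fitted and only beta_D is free
#' @param alphaMaxNominal nominal ligand excess of the saturating
#'   solution, used only to initialize the calibration
#' @param fitScale also fit a shared amplitude scale (off by default;
#'   useful only for strongly under-saturated series)
#' @param ciMethod \code{"covariance"} (t-interval from the covariance
#'   matrix) or \code{"bootstrap"} (residual bootstrap percentile
#'   interval)
#' @param nBoot bootstrap replicates when \code{ciMethod = "bootstrap"}
#' @param bootSeed RNG seed for the bootstrap
#' @return a [BindingFitResult-class]
#' @examples
#' fx <- makeFixtureHfyn(seed = 1)
#' csp <- buildCspTable(fx$series)
#' fit <- globalFit(csp, fx$series, proteinConc = 1000)
#' kD(fit)
#' @export
globalFit <- function(csp, series, proteinConc, exclude = character(),
                      includeOverlap = FALSE, alphaKnown = NULL,
                      alphaMaxNominal = 5, fitScale = FALSE,
                      ciMethod = c("covariance", "bootstrap"),
                      nBoot = 200, bootSeed = 1L) {
  ciMethod <- match.arg(ciMethod)
  if (proteinConc <= 0) stop("proteinConc must be > 0")
  n <- nSteps(series)
  if (n < 4) stop("need at least 4 titration steps for 3 free parameters")
  use <- csp@significant
  if (!includeOverlap) use <- use & !csp@overlap
  use <- use & !(csp@label %in% exclude)
  zero <- use & (is.na(csp@ddMax) | csp@ddMax <= 0)
  if (any(zero)) {
    warning("dropping residue(s) with zero saturated CSP: ",
            paste(csp@label[zero], collapse = ", "))
    use <- use & !zero
  }
  if (!any(use))
    stop("no significant residues left to fit after exclusions")
  labs <- csp@label[use]
  satCol <- match(csp@saturatedStep, series@step)

  obs <- list()
  for (i in which(use)) {
    y <- csp@dd[i, ] / csp@ddMax[i]
    ok <- is.finite(y)
    obs[[length(obs) + 1L]] <- data.frame(
      label = csp@label[i], step = series@step[ok],
      col = which(ok), iTSP = series@iTSP[ok], observed = y[ok],
      stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, obs)
  iTSP <- series@iTSP

  # isotherm with a smooth linear continuation for alpha < 0 (slope of
  # f at the origin); during optimization the calibration may transiently
  # map the ligand-free intensity to a slightly negative alpha, and the
  # continuation lets the step-0 data pull it back instead of leaving a
  # flat clamped region the optimizer can hide in
  fExt <- function(alpha, b) {
    ifelse(alpha >= 0, fractionalShift(pmax(alpha, 0), b),
           alpha / (1 + b))
  }
  predict_frac <- function(betaDv, slope, intercept, scale = 1) {
    alpha <- if (is.null(alphaKnown))
      alphaFromTsp(iTSP, slope, intercept)
    else pmax(alphaKnown, 0)
    fall <- fExt(alpha, betaDv)
    fsat <- fall[satCol]
    if (!is.finite(fsat) || fsat <= 0) return(rep(NA_real_, nrow(obs)))
    scale * fall[obs$col] / fsat
  }

  calFree <- is.null(alphaKnown)
  resid_fn <- function(p) {
    b <- exp(p[1])
    sl <- if (calFree) p[2] else NA_real_
    ic <- if (calFree) p[3] else NA_real_
    sc <- if (fitScale) exp(p[length(p)]) else 1
    pr <- predict_frac(b, sl, ic, sc)
    if (any(!is.finite(pr))) return(rep(1e6, nrow(obs)))
    obs$observed - pr
  }

  # initialization: calibration from nominal endpoint alphas, then a
  # log-grid profile scan over beta_D
  if (calFree) {
    dI <- iTSP[satCol] - iTSP[1]
    if (dI == 0) stop("degenerate calibration: TSP intensity constant")
    slope0 <- alphaMaxNominal / dI
    int0 <- -slope0 * iTSP[1]
  }
  grid <- 10^seq(-3, 1.3, length.out = 20)
  rss <- vapply(grid, function(b) {
    r <- if (calFree) {
      pr <- predict_frac(b, slope0, int0)
      obs$observed - pr
    } else obs$observed - predict_frac(b, NA, NA)
    sum(r^2)
  }, numeric(1))
  beta0 <- grid[which.min(rss)]
  p0 <- log(beta0)
  if (calFree) p0 <- c(p0, slope0, int0)
  if (fitScale) p0 <- c(p0, 0)

  fit <- minpack.lm::nls.lm(p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14,
                              ptol = 1e-14))
  p <- fit$par
  betaHat <- exp(p[1])
  slopeHat <- if (calFree) p[2] else NA_real_
  intHat <- if (calFree) p[3] else NA_real_
  scaleHat <- if (fitScale) exp(p[length(p)]) else 1
  converged <- fit$info %in% 1:3
  res <- resid_fn(p)
  npar <- length(p)
  dof <- nrow(obs) - npar
  rssHat <- sum(res^2)
  sigma2 <- if (dof > 0) rssHat / dof else NA_real_

  J <- numJacobian(resid_fn, p)
  JtJ <- crossprod(J)
  cov <- tryCatch(sigma2 * solve(JtJ), error = function(e) {
    matrix(NA_real_, npar, npar)
  })
  pnames <- c("logBetaD", if (calFree) c("calSlope", "calIntercept"),
              if (fitScale) "logScale")
  dimnames(cov) <- list(pnames, pnames)

  alphaHat <- if (calFree) pmax(alphaFromTsp(iTSP, slopeHat, intHat), 0)
              else pmax(alphaKnown, 0)
  fitted <- predict_frac(betaHat, slopeHat, intHat, scaleHat)
  residuals <- data.frame(label = obs$label, step = obs$step,
                          iTSP = obs$iTSP, observed = obs$observed,
                          fitted = fitted,
                          residual = obs$observed - fitted,
                          stringsAsFactors = FALSE)

  ci <- if (ciMethod == "covariance") {
    ciFromCovariance(betaHat, slopeHat, intHat, proteinConc, cov, dof,
                     0.95, calFree)
  } else {
    ciFromBootstrap(resid_fn, p, obs, predict_frac, betaHat, slopeHat,
                    intHat, scaleHat, proteinConc, calFree, fitScale,
                    nBoot, bootSeed)
  }

  new("BindingFitResult", betaD = betaHat, kD = betaHat * proteinConc,
      calSlope = slopeHat, calIntercept = intHat,
      proteinConc = proteinConc, covariance = cov, ci95 = ci,
      residuals = residuals, alpha = alphaHat, labelsUsed = labs,
      converged = converged, dof = as.integer(dof),
      sigmaResid = sqrt(max(sigma2, 0)), message = fit$message)
}

# central-difference jacobian of a residual function
numJacobian <- function(fn, p, eps = 1e-6) {
  f0 <- fn(p)
  J <- matrix(0, length(f0), length(p))
  for (k in seq_along(p)) {
    h <- eps * max(1, abs(p[k]))
    pp <- p; pp[k] <- p[k] + h
    pm <- p; pm[k] <- p[k] - h
    J[, k] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  -J  # fn returns observed - fitted; jacobian of the model
}

ciFromCovariance <- function(betaHat, slopeHat, intHat, proteinConc,
                             cov, dof, level, calFree) {
  tq <- if (dof > 0) stats::qt(1 - (1 - level) / 2, dof) else NA_real_
  seLog <- sqrt(cov["logBetaD", "logBetaD"])
  # the free parameter is log beta_D: form the t-interval there and
  # transform, which respects positivity and the estimate's skew
  lo <- betaHat * exp(-tq * seLog)
  hi <- betaHat * exp(tq * seLog)
  mk <- function(est, se) c(estimate = est, lower = est - tq * se,
                            upper = est + tq * se)
  rows <- list(
    betaD = c(estimate = betaHat, lower = lo, upper = hi),
    kD = c(estimate = betaHat, lower = lo, upper = hi) * proteinConc)
  if (calFree) {
    rows$calSlope <- mk(slopeHat, sqrt(cov["calSlope", "calSlope"]))
    rows$calIntercept <- mk(intHat,
                            sqrt(cov["calIntercept", "calIntercept"]))
  }
  do.call(rbind, rows)
}

ciFromBootstrap <- function(resid_fn, p, obs, predict_frac, betaHat,
                            slopeHat, intHat, scaleHat, proteinConc,
                            calFree, fitScale, nBoot, bootSeed) {
  # cluster bootstrap over residues: the errors of one residue share
  # its step-0 reference and its saturated-step normalizer, so the
  # residue is the exchangeable unit, not the single point
  labs <- unique(obs$label)
  rows <- split(seq_len(nrow(obs)), obs$label)
  boots <- withSeed(bootSeed, {
    vapply(seq_len(nBoot), function(b) {
      pick <- sample(labs, length(labs), replace = TRUE)
      idx <- unlist(rows[pick], use.names = FALSE)
      fnb <- function(q) {
        bb <- exp(q[1])
        sl <- if (calFree) q[2] else NA_real_
        ic <- if (calFree) q[3] else NA_real_
        sc <- if (fitScale) exp(q[length(q)]) else 1
        pr <- predict_frac(bb, sl, ic, sc)
        if (any(!is.finite(pr))) return(rep(1e6, length(idx)))
        obs$observed[idx] - pr[idx]
      }
      fb <- minpack.lm::nls.lm(p, fn = fnb)
      exp(fb$par[1])
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  rows <- list(
    betaD = c(estimate = betaHat, lower = min(qs[1], betaHat),
              upper = max(qs[2], betaHat)),
    kD = c(estimate = betaHat * proteinConc,
           lower = min(qs[1], betaHat) * proteinConc,
           upper = max(qs[2], betaHat) * proteinConc))
  if (calFree) {
    rows$calSlope <- c(estimate = slopeHat, lower = NA, upper = NA)
    rows$calIntercept <- c(estimate = intHat, lower = NA, upper = NA)
  }
  do.call(rbind, rows)
}

#' Confidence intervals of a binding fit
#'
#' Recomputes per-parameter intervals from the stored covariance matrix
#' at an arbitrary confidence level: estimate plus/minus the
#' t-quantile(level, dof) times the standard error, with dof the
#' residual degrees of freedom of the fit. The K_D interval is the
#' beta_D interval scaled by the protein concentration.
#'
#' @param fit a converged [BindingFitResult-class]
#' @param level confidence level in [0, 1) (0.95 reproduces the stored
#'   \code{ci95}; 0 collapses the interval onto the estimate)
#' @return matrix with one row per parameter and columns
#'   \code{estimate}, \code{lower}, \code{upper}
#' @export
confidenceIntervals <- function(fit, level = 0.95) {
  if (!fit@converged) stop("fit did not converge; intervals unavailable")
  if (any(!is.finite(fit@covariance)))
    stop("covariance is singular or unavailable; cannot form intervals")
  calFree <- "calSlope" %in% rownames(fit@covariance)
  ciFromCovariance(fit@betaD, fit@calSlope, fit@calIntercept,
                   fit@proteinConc, fit@covariance, fit@dof, level,
                   calFree)
}
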