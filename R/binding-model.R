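#' Fractional chemical shift of a two-state binding equilibrium
#'
#' For a protein P binding a ligand L with dissociation constant K_D
#' under fast exchange, the observed CSP of every reporter is
#' proportional to the bound fraction. In dimensionless form, with
#' alpha = [L]/[P] the ligand-to-protein molar ratio and
#' beta_D = K_D/[P], the bound fraction is the physical root of the
#' mass-action quadratic:
#' \deqn{f = \frac{(\alpha + 1 + \beta_D) -
#'   \sqrt{(\alpha + 1 + \beta_D)^2 - 4\alpha}}{2}}
#' Evaluated in the conjugate form \eqn{2\alpha / (s + \sqrt{s^2 -
#' 4\alpha})} with \eqn{s = \alpha + 1 + \beta_D}, which avoids the
#' catastrophic cancellation of the textbook form when f is small and
#' is stable for beta_D down to 1e-8 and beyond.
#'
#' @param alpha normalized ligand concentration [L]/[P], >= 0
#'   (vectorized)
#' @param betaD dimensionless dissociation constant K_D/[P], > 0
#' @return the bound protein fraction, in [0, 1]
#' @examples
#' fractionalShift(1, 1)          # (3 - sqrt(5)) / 2
#' fractionalShift(c(0, 2), 1e-8) # 0 and (stoichiometric) 1
#' @export
fractionalShift <- function(alpha, betaD) {
  if (any(alpha < 0)) stop("alpha must be >= 0")
  if (any(betaD <= 0)) stop("betaD must be > 0")
  s <- alpha + 1 + betaD
  disc <- s * s - 4 * alpha
  # disc = (alpha - 1 - betaD)^2 + 4*betaD >= 0 analytically; clamp
  # away roundoff so sqrt never sees a tiny negative
  2 * alpha / (s + sqrt(pmax(disc, 0)))
}

#' Normalized ligand concentration from the TSP intensity
#'
#' The two stock solutions carry TSP at concentrations an order of
#' magnitude apart, so the TSP 1D intensity is an affine reporter of
#' the mixing ratio and hence of alpha = [L]/[P]:
#' alpha = slope * I_TSP + intercept.
#'
#' @param iTSP measured TSP intensity (a.u.), vectorized
#' @param slope,intercept calibration coefficients
#' @return alpha values
#' @seealso [alphaCalFromEndpoints()] to build the calibration from the
#'   endpoint intensities
#' @export
alphaFromTsp <- function(iTSP, slope, intercept) {
  slope * iTSP + intercept
}

#' Calibration coefficients from endpoint TSP intensities
#'
#' Endpoint parameterization of the same affine law: with I_A the TSP
#' intensity of the ligand-free solution, I_B that of the
#' ligand-saturated solution and alpha_max the normalized ligand
#' concentration of the saturated solution,
#' alpha = alpha_max * (I_TSP - I_A) / (I_B - I_A).
#'
#' @param iA TSP intensity of the ligand-free solution (a.u.)
#' @param iB TSP intensity of the ligand-saturated solution (a.u.)
#' @param alphaMax normalized ligand concentration of the saturated
#'   solution (must exceed 1 so that solution b can saturate binding)
#' @return list with \code{slope} and \code{intercept} such that
#'   \code{alphaFromTsp(iA, slope, intercept) == 0} and
#'   \code{alphaFromTsp(iB, slope, intercept) == alphaMax}
#' @examples
#' cal <- alphaCalFromEndpoints(iA = 10, iB = 0.5, alphaMax = 5)
#' alphaFromTsp(c(10, 5.25, 0.5), cal$slope, cal$intercept)
#' @export
alphaCalFromEndpoints <- function(iA, iB, alphaMax) {
  if (iA == iB) stop("degenerate calibration: I_A equals I_B")
  slope <- alphaMax / (iB - iA)
  list(slope = slope, intercept = -slope * iA)
}
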