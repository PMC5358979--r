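#' Langmuir isotherm fit of the bent fraction versus enzyme concentration
#'
#' Nonlinear least squares of `fraction = F / (F + K_d)`, the 1:1 binding
#' isotherm without ligand depletion. Valid for surface-immobilized substrate
#' at ~0.1 nM, far below the dissociation constant.
#'
#' @param conc Enzyme concentrations F, nM (>= 5, spanning the K_d).
#' @param fraction_bent Bent-population fraction at each concentration (from
#'   [fit_mixture()] on the per-molecule FRET histograms).
#' @param S Substrate concentration, nM (recorded, not used by the fit).
#' @return An `isotherm_fit`: list with `mode = "langmuir_fraction"`, `K_d_nM`,
#'   `K_d_se`, `residuals`, `points`, and the underlying `nls` fit.
#' @examples
#' f <- c(0.11, 0.2, 0.33, 0.5, 0.67, 0.83, 0.91)
#' conc <- c(0.5, 1, 2, 4, 8, 20, 40)
#' fit_langmuir(conc, f)$K_d_nM
#' @export
fit_langmuir <- function(conc, fraction_bent, S = 0.1) {
  if (length(conc) < 5) stop("need >= 5 concentrations")
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (diff(range(fraction_bent)) < 0.2)
    stop("no curvature in the isotherm data; concentrations do not span K_d")
  start <- list(K_d = conc[which.min(abs(fraction_bent - 0.5))])
  fit <- minpack.lm::nlsLM(fraction_bent ~ conc / (conc + K_d), start = start,
                           lower = c(K_d = 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  structure(list(mode = "langmuir_fraction",
                 K_d_nM = cf["K_d", "Estimate"],
                 K_d_se = cf["K_d", "Std. Error"],
                 residuals = stats::residuals(fit),
                 points = data.frame(conc_nM = conc,
                                     fraction_bent = fraction_bent),
                 S = S, fit = fit),
            class = "isotherm_fit")
}

#' Quadratic (tight-binding) isotherm of ensemble FRET versus enzyme
#'
#' Bulk titrations at substrate concentrations comparable to the dissociation
#' constant need the exact bimolecular closed form. For S + F <-> SF at
#' equilibrium the observed FRET is
#' `E = E0 + (Ef - E0) * ((S + F + K_d) - sqrt((S + F + K_d)^2 - 4 S F)) / (2 S)`,
#' where `E0` and `Ef` are the FRET endpoints of free and bound substrate.
#'
#' @param conc Enzyme concentrations F, nM (> 0, >= 5 points).
#' @param E Observed ensemble FRET at each concentration.
#' @param S Total substrate concentration, nM (known).
#' @return An `isotherm_fit` with `mode = "quadratic_E"`, `K_d_nM`, `E0`, `Ef`.
#' @examples
#' qroot <- function(F, S, Kd, E0, Ef)
#'   E0 + (Ef - E0) * ((S + F + Kd) - sqrt((S + F + Kd)^2 - 4 * S * F)) / (2 * S)
#' E <- qroot(c(1, 2, 4, 8, 16, 32), 0.5, 4, 0.27, 0.54)
#' fit_quadratic_isotherm(c(1, 2, 4, 8, 16, 32), E, S = 0.5)$K_d_nM
#' @export
fit_quadratic_isotherm <- function(conc, E, S) {
  if (any(conc <= 0)) stop("enzyme concentrations must be > 0")
  if (length(conc) < 5) stop("need >= 5 points")
  qroot <- function(F, S, K_d, E0, Ef) {
    b <- S + F + K_d
    E0 + (Ef - E0) * (b - sqrt(pmax(b^2 - 4 * S * F, 0))) / (2 * S)
  }
  start <- list(E0 = E[which.min(conc)], Ef = E[which.max(conc)],
                K_d = stats::median(conc))
  fit <- minpack.lm::nlsLM(E ~ qroot(conc, S, K_d, E0, Ef), start = start,
                           lower = c(E0 = -0.2, Ef = -0.2, K_d = 1e-9),
                           upper = c(E0 = 1.2, Ef = 1.2, K_d = Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  structure(list(mode = "quadratic_E",
                 K_d_nM = cf["K_d", "Estimate"],
                 K_d_se = cf["K_d", "Std. Error"],
                 E0 = cf["E0", "Estimate"], Ef = cf["Ef", "Estimate"],
                 residuals = stats::residuals(fit),
                 points = data.frame(conc_nM = conc, E = E),
                 S = S, fit = fit),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("%s isotherm: K_d = %.3g +/- %.2g nM\n",
              x$mode, x$K_d_nM, x$K_d_se))
  invisible(x)
}
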