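# Membrane hydrodynamics and engagement stoichiometry.

.kB <- 1.380649e-23  # J/K
.euler <- 0.5772156649015329

# Petrov-Schwille interpolation coefficients
.ps <- c(c1 = 0.73761, b1 = 2.74819, c2 = 0.52119, b2 = 0.61465)

# reduced radius: ratio of aqueous to membrane drag length scales
.reducedRadius <- function(radius, params)
  2 * radius * params@aqueousViscosity /
    (params@membraneViscosity * params@membraneThickness)

#' Lateral diffusion coefficient of a cylindrical membrane inclusion
#'
#' Evaluates the extended Saffman-Delbrueck relation for the lateral
#' diffusion coefficient of a cylindrical inclusion of given radius in a
#' membrane of 2-D viscosity \code{membraneViscosity * membraneThickness},
#' bounded symmetrically by an aqueous phase. The Petrov-Schwille
#' interpolation in the reduced radius
#' \code{eps = 2 R mu_w / (mu_m h)} is used, which reduces to the classical
#' logarithmic Saffman-Delbrueck form
#' \code{kT/(4 pi mu_m h) (ln(2/eps) - gamma)} as \code{eps -> 0} and
#' remains valid for inclusions much larger than the Saffman-Delbrueck
#' length (eps >> 1), where D falls off as 1/R.
#'
#' @param radius inclusion radius in metres (vectorized).
#' @param params an \linkS4class{SDParams}.
#' @param classical if TRUE, evaluate the classical small-radius form
#'   instead of the interpolation.
#' @return diffusion coefficient(s) in um^2/s.
#' @examples
#' sdDiffusion(2e-9)    # ~0.39 um^2/s: rhodopsin-dimer scale
#' sdDiffusion(90e-9)   # ~0.078 um^2/s: cluster-raft scale
#' @export
sdDiffusion <- function(radius, params = SDParams(), classical = FALSE) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("radius must be strictly positive (metres)")
  validObject(params)
  eps <- .reducedRadius(radius, params)
  pref <- .kB * params@temperature /
    (4 * pi * params@membraneViscosity * params@membraneThickness)
  L <- log(2 / eps)
  if (classical) return(pref * (L - .euler) * 1e12)
  num <- L - .euler + 4 * eps / pi - (eps^2 / 2) * L
  den <- 1 - (eps^3 / pi) * L +
    .ps["c1"] * eps^.ps["b1"] / (1 + .ps["c2"] * eps^.ps["b2"])
  as.numeric(pref * num / den * 1e12)  # m^2/s -> um^2/s
}

#' Invert the extended Saffman-Delbrueck relation
#'
#' Recovers the inclusion radius from a diffusion coefficient by monotone
#' root-finding on a logarithmic radius scale. \code{sdDiffusion} is
#' strictly decreasing in radius, so the root is unique within the bracket.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param params an \linkS4class{SDParams}.
#' @param radiusBracket search interval in metres.
#' @return radius in metres (relative tolerance ~1e-9 or better).
#' @export
invertSD <- function(D, params = SDParams(), radiusBracket = c(1e-10, 1e-5)) {
  dHi <- sdDiffusion(radiusBracket[1], params)
  dLo <- sdDiffusion(radiusBracket[2], params)
  if (D >= dHi || D <= dLo)
    stop(sprintf(
      "D = %g um^2/s is outside the attainable range (%g, %g) for radii in [%g, %g] m",
      D, dLo, dHi, radiusBracket[1], radiusBracket[2]))
  f <- function(lr) sdDiffusion(exp(lr), params) - D
  r <- stats::uniroot(f, lower = log(radiusBracket[1]),
                      upper = log(radiusBracket[2]), tol = 1e-13)
  exp(r$root)
}

#' Fraction of rhodopsin sequestered in photoactivated receptor-Gt complexes
#'
#' Stoichiometric saturation model: each transducin (Gt) engages
#' \code{rhodopsinsPerComplex} photoactivated rhodopsins (2:1 complex by
#' default), and the membrane holds one Gt per \code{rhodopsinsPerGt}
#' rhodopsins. Complex formation is limited by whichever species runs out:
#' complexes per rhodopsin = min(1/rhodopsinsPerGt,
#' isoFraction/rhodopsinsPerComplex). The sequestered fraction is
#' piecewise-linear in the photoisomerized fraction and saturates at
#' \code{\link{saturationIsomerization}}.
#'
#' @param isoFraction fraction of rhodopsin photoisomerized, in [0, 1]
#'   (vectorized).
#' @param stoich a \linkS4class{StoichiometryParams}.
#' @return fraction of total rhodopsin sequestered in complexes.
#' @export
gtEngagement <- function(isoFraction, stoich = StoichiometryParams()) {
  if (any(isoFraction < 0) || any(isoFraction > 1))
    stop("isoFraction must lie in [0, 1]")
  validObject(stoich)
  complexesPerRh <- pmin(1 / stoich@rhodopsinsPerGt,
                         isoFraction / stoich@rhodopsinsPerComplex)
  stoich@rhodopsinsPerComplex * complexesPerRh
}

#' Photoisomerized fraction at which Gt engagement saturates
#'
#' The engagement model saturates once every Gt is complexed, i.e. at
#' isoFraction = rhodopsinsPerComplex / rhodopsinsPerGt (0.20 for the
#' 10:1 rhodopsin:Gt ratio and 2:1 complex).
#'
#' @param stoich a \linkS4class{StoichiometryParams}.
#' @return saturating photoisomerized fraction.
#' @export
saturationIsomerization <- function(stoich = StoichiometryParams()) {
  validObject(stoich)
  stoich@rhodopsinsPerComplex / stoich@rhodopsinsPerGt
}
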