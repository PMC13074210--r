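#' FRET indicators of a burst or population
#'
#' Bundles the intensity-based FRET efficiency `E`, the intensity-weighted
#' mean donor lifetime `tauF` (ns), the donor-only lifetime `tauD0` (ns) and
#' the derived lifetime-based efficiency `Etau = 1 - tauF/tauD0`. For any
#' physical species mixture `E >= Etau`; the gap carries the variance of the
#' efficiency distribution (see [varianceFromIndicators]).
#'
#' @param E intensity-based FRET efficiency in \[0,1\].
#' @param tauF intensity-weighted mean donor lifetime, ns.
#' @param tauD0 donor-only lifetime, ns.
#' @return data.frame with columns E, tauF, tauD0, Etau.
#' @export
fretIndicators <- function(E, tauF, tauD0) {
  stopifnot(tauD0 > 0)
  if (any(tauF < 0 | tauF > tauD0 * (1 + 1e-9)))
    warning("tauF outside (0, tauD0]")
  data.frame(E = E, tauF = tauF, tauD0 = tauD0, Etau = 1 - tauF / tauD0)
}

#' Static FRET-line
#'
#' The locus of single-species populations in the (tauF, E) plane, ideal
#' (linker-free) form \eqn{E = 1 - \tau/\tau_{D0}}. Passes through
#' (tauD0, 0) and (0, 1).
#'
#' @param tauD0 donor-only lifetime, ns.
#' @param n number of curve points.
#' @return data.frame with columns tauF (ns) and E.
#' @export
staticFretLine <- function(tauD0, n = 201) {
  stopifnot(tauD0 > 0)
  tau <- seq(0, tauD0, length.out = n)
  data.frame(tauF = tau, E = 1 - tau / tauD0)
}

## moments of the lifetime distribution for a binary mixture at fraction x
.binaryMoments <- function(x, E1, E2, tauD0) {
  t1 <- tauD0 * (1 - E1); t2 <- tauD0 * (1 - E2)
  m1 <- x * t1 + (1 - x) * t2
  m2 <- x * t1^2 + (1 - x) * t2^2
  list(tauF = m2 / m1, E = x * E1 + (1 - x) * E2)
}

#' Dynamic FRET-line for a binary exchange
#'
#' Traces all mixing ratios \eqn{x^{(1)} \in [0,1]} between two species in
#' the (tauF, E) plane. The mean efficiency is the species-fraction average
#' while the intensity-weighted lifetime is the ratio of the second to the
#' first moment of the lifetime distribution,
#' \eqn{\langle\tau\rangle_F = (x\tau_1^2 + (1-x)\tau_2^2) /
#' (x\tau_1 + (1-x)\tau_2)}. The endpoints lie on the static line; in the
#' moment coordinates `(m1, m2) = (1-E, (1-E)(1-Etau))` the curve is an
#' exact straight line.
#'
#' @param E1,E2 limiting FRET efficiencies (distinct, in \[0,1)).
#' @param tauD0 donor-only lifetime, ns.
#' @param x grid of species-1 fractions (default 201 points on \[0,1\]).
#' @return data.frame with columns x, E, tauF, Etau, ds, m1, m2.
#' @export
dynamicFretLine <- function(E1, E2, tauD0, x = seq(0, 1, length.out = 201)) {
  if (E1 == E2) stop("E1 and E2 must differ")
  if (any(c(E1, E2) < 0) || any(c(E1, E2) >= 1))
    stop("efficiencies must lie in [0, 1)")
  m <- .binaryMoments(x, E1, E2, tauD0)
  Etau <- 1 - m$tauF / tauD0
  data.frame(x = x, E = m$E, tauF = m$tauF, Etau = Etau,
             ds = dynamicShift(x, E1, E2),
             m1 = 1 - m$E, m2 = (1 - m$E) * (1 - Etau))
}

#' Dynamic shift of a binary mixture
#'
#' Displacement of the mixed population from the static FRET-line,
#' \deqn{ds(x) = \frac{1}{2}\,\frac{(E_2-E_1)^2\, x(1-x)}
#'   {x(1-E_1) + (1-x)(1-E_2)},}
#' identically equal to \eqn{(E - E_\tau)/2}, half the vertical offset of
#' the population above the static line. Vanishes at x = 0 and x = 1.
#'
#' @param x species-1 fraction(s) in \[0,1\].
#' @param E1,E2 limiting efficiencies (in \[0,1)).
#' @return dynamic shift value(s), dimensionless.
#' @export
dynamicShift <- function(x, E1, E2) {
  if (any(c(E1, E2) >= 1)) stop("E1, E2 must be < 1")
  if (any(x < 0 | x > 1)) stop("x must lie in [0,1]")
  0.5 * (E2 - E1)^2 * x * (1 - x) / (x * (1 - E1) + (1 - x) * (1 - E2))
}

#' Maximum dynamic shift and its species fraction
#'
#' Closed forms
#' \eqn{ds_{max} = \frac{1}{2}(\sqrt{1-E_1} - \sqrt{1-E_2})^2} attained at
#' \eqn{x^{(1)}_{max} = \sqrt{1-E_2}/(\sqrt{1-E_1} + \sqrt{1-E_2})}.
#'
#' @param E1,E2 limiting efficiencies (in \[0,1)).
#' @return list with elements `dsMax` and `xMax`.
#' @export
maxDynamicShift <- function(E1, E2) {
  if (any(c(E1, E2) < 0) || any(c(E1, E2) >= 1))
    stop("efficiencies must lie in [0, 1)")
  s1 <- sqrt(1 - E1); s2 <- sqrt(1 - E2)
  list(dsMax = 0.5 * (s1 - s2)^2, xMax = s2 / (s1 + s2))
}

#' Variance of the FRET-efficiency distribution from burst indicators
#'
#' \eqn{Var(E) = (1 - E)(E - E_\tau)}: the spread of the underlying
#' efficiency distribution of a single-molecule event, computable from the
#' two measured indicators alone. Zero for a static species (E = Etau);
#' negative values (possible for shot-noise or linker artifacts) are
#' flagged with a warning but returned unchanged.
#'
#' @param E intensity-based efficiency.
#' @param Etau lifetime-based efficiency `1 - tauF/tauD0`.
#' @param tol tolerance below which E < Etau is not flagged.
#' @return Var(E), same length as inputs.
#' @export
varianceFromIndicators <- function(E, Etau, tol = 1e-9) {
  if (any(Etau - E > tol))
    warning("E < Etau: unphysical indicator pair (shot noise or linker ",
            "artifacts); returning the negative variance unchanged")
  (1 - E) * (E - Etau)
}
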