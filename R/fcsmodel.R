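#' MixtureModel: dynamic molecules plus a static background
#'
#' A fraction `pd` of molecules carries the kinetic network `net` (dynamic
#' molecules, equilibrium fractions `xd`), while the remaining `1 - pd` are
#' static with state fractions `xs`. The total species fractions are
#' \eqn{x = p_d x_d + (1-p_d) x_s}.
#'
#' @slot net a [KineticNetwork-class].
#' @slot pd fraction of dynamic molecules, in \[0,1\].
#' @slot xs static-state fractions (sum to 1).
#' @export
setClass("MixtureModel",
  representation(net = "KineticNetwork", pd = "numeric", xs = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- nStates(object@net)
    if (length(object@xs) != n) msg <- c(msg, "xs must have one entry per state")
    if (object@pd < 0 || object@pd > 1) msg <- c(msg, "pd must be in [0,1]")
    if (any(object@xs < 0) || abs(sum(object@xs) - 1) > 1e-8)
      msg <- c(msg, "xs must be nonnegative and sum to 1")
    if (length(msg)) msg else TRUE
  })

#' @rdname MixtureModel-class
#' @param net a [KineticNetwork-class].
#' @param pd dynamic molecule fraction.
#' @param xs static fractions (default uniform).
#' @export
mixtureModel <- function(net, pd = 1, xs = NULL) {
  n <- nStates(net)
  if (is.null(xs)) xs <- rep(1 / n, n)
  new("MixtureModel", net = net, pd = pd, xs = xs)
}

#' @describeIn MixtureModel-class dynamic-state equilibrium fractions
#' @param model a MixtureModel
#' @export
dynamicFractions <- function(model) {
  if (model@pd == 0) return(setNames(rep(NA_real_, nStates(model@net)),
                                     stateLabels(model@net)))
  equilibriumFractions(model@net)
}

#' @describeIn MixtureModel-class total species fractions
#'   \eqn{p_d x_d + (1-p_d) x_s}
#' @export
totalFractions <- function(model) {
  xd <- if (model@pd > 0) equilibriumFractions(model@net) else
    rep(0, nStates(model@net))
  model@pd * xd + (1 - model@pd) * model@xs
}

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel: pd = %g over %d states (%s)\n", object@pd,
              nStates(object@net),
              paste(stateLabels(object@net), collapse = ", ")))
  cat("  total fractions:",
      paste(signif(totalFractions(object), 4), collapse = ", "), "\n")
})

#' DetectionModel: confocal detection and photon-color parameters
#'
#' @slot Q0 donor molecular brightness scale, kHz (cancels in normalized
#'   correlation functions).
#' @slot gamma detection/quantum-yield correction factor (> 0).
#' @slot alpha donor-to-red crosstalk fraction, in \[0,1).
#' @slot tdiff diffusion time, ms.
#' @slot s aspect ratio w0/z0 of the Gaussian observation volume, (0,1\].
#' @slot N mean number of molecules in the observation volume.
#' @export
setClass("DetectionModel",
  representation(Q0 = "numeric", gamma = "numeric", alpha = "numeric",
                 tdiff = "numeric", s = "numeric", N = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
    if (object@alpha < 0 || object@alpha >= 1)
      msg <- c(msg, "alpha must be in [0,1)")
    if (object@s <= 0 || object@s > 1) msg <- c(msg, "s must be in (0,1]")
    if (object@tdiff <= 0) msg <- c(msg, "tdiff must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname DetectionModel-class
#' @param Q0 donor brightness, kHz.
#' @param gamma gamma correction factor.
#' @param alpha crosstalk fraction.
#' @param tdiff diffusion time, ms.
#' @param s aspect ratio w0/z0.
#' @param N mean molecules in the volume.
#' @export
detectionModel <- function(Q0 = 200, gamma = 1, alpha = 0, tdiff = 5,
                           s = 0.25, N = 1) {
  new("DetectionModel", Q0 = Q0, gamma = gamma, alpha = alpha,
      tdiff = tdiff, s = s, N = N)
}

setMethod("show", "DetectionModel", function(object) {
  cat(sprintf(
    "DetectionModel: Q0 = %g kHz, gamma = %g, alpha = %g, tdiff = %g ms, s = %g, N = %g\n",
    object@Q0, object@gamma, object@alpha, object@tdiff, object@s, object@N))
})

#' Per-species green and red signal vectors
#'
#' \eqn{q_G = Q_0 (1 - E)}, \eqn{q_R = Q_0 (\gamma E + \alpha (1 - E))}.
#'
#' @param det a [DetectionModel-class].
#' @param E vector of species FRET efficiencies.
#' @return list with numeric vectors `G` and `R` (kHz).
#' @export
signalVectors <- function(det, E) {
  list(G = det@Q0 * (1 - E),
       R = det@Q0 * (det@gamma * E + det@alpha * (1 - E)))
}

#' CorrelationCurve: a correlation function with uncertainties
#'
#' @slot lag lag times, ms (strictly increasing).
#' @slot G correlation values (normalized; tends to 1 at long lags).
#' @slot sigma per-point standard errors (may be NA for model curves).
#' @slot pair channel or species pair label, e.g. "GG", "GR" or "LF-HF".
#' @export
setClass("CorrelationCurve",
  representation(lag = "numeric", G = "numeric", sigma = "numeric",
                 pair = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@G) != length(object@lag))
      msg <- c(msg, "lag and G lengths differ")
    if (is.unsorted(object@lag, strictly = TRUE))
      msg <- c(msg, "lag grid must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' @rdname CorrelationCurve-class
#' @param lag,G,sigma,pair see slots.
#' @export
correlationCurve <- function(lag, G, sigma = rep(NA_real_, length(G)),
                             pair = "GG") {
  new("CorrelationCurve", lag = lag, G = G, sigma = sigma, pair = pair)
}

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve [%s]: %d lags from %g to %g ms\n",
              object@pair, length(object@lag), min(object@lag),
              max(object@lag)))
})

#' @describeIn CorrelationCurve-class lag grid accessor
#' @param x a CorrelationCurve
#' @export
lagTimes <- function(x) x@lag

#' @describeIn CorrelationCurve-class correlation values accessor
#' @export
corrValues <- function(x) x@G

#' Multi-tau quasi-logarithmic lag grid
#'
#' @param from,to lag range in ms.
#' @param pointsPerCascade lags per octave cascade (default 16).
#' @return strictly increasing lag vector, ms.
#' @export
multiTauGrid <- function(from = 1e-4, to = 100, pointsPerCascade = 16) {
  lags <- seq(from, from * 2, length.out = pointsPerCascade + 1)[-1]
  w <- from * 2
  out <- lags
  while (w < to) {
    step <- 2 * w / pointsPerCascade
    lags <- seq(w + step, min(2 * w, to), by = step)
    out <- c(out, lags)
    w <- w * 2
  }
  unique(out[out <= to])
}

#' 3D Gaussian diffusion factor of the correlation function
#'
#' \eqn{G_{diff}(t_c) = (1 + t_c/t_{diff})^{-1}
#' (1 + s^2 t_c/t_{diff})^{-1/2}} for a 3D Gaussian detection profile with
#' aspect ratio \eqn{s = w_0/z_0}.
#'
#' @param tc lag times, ms (>= 0).
#' @param tdiff diffusion time, ms.
#' @param s aspect ratio.
#' @return diffusion factor values, 1 at tc = 0, strictly decreasing.
#' @export
diffusionTerm <- function(tc, tdiff, s = 0.25) {
  stopifnot(all(tc >= 0), tdiff > 0)
  (1 + tc / tdiff)^-1 * (1 + s^2 * tc / tdiff)^-0.5
}

## species correlation matrix G(tc) = pd exp(K tc) Xd + (1-pd) Xs and its
## long-time limit pd xd xd^T + (1-pd) Xs
.corrMatrix <- function(model, tc, es = NULL) {
  n <- nStates(model@net)
  Xs <- diag(model@xs, n)
  if (model@pd == 0) return(Xs)
  xd <- equilibriumFractions(model@net)
  if (is.null(es)) es <- eigenDecompose(model@net)
  model@pd * (propagator(es, tc) %*% diag(xd, n)) + (1 - model@pd) * Xs
}

.corrMatrixInf <- function(model) {
  n <- nStates(model@net)
  Xs <- diag(model@xs, n)
  if (model@pd == 0) return(Xs)
  xd <- equilibriumFractions(model@net)
  model@pd * (xd %o% xd) + (1 - model@pd) * Xs
}

#' Contrast factors between species pairs
#'
#' \eqn{\partial_{ab}^{ij} = \frac{(S_a^{(i)} - S_a^{(j)})(S_b^{(i)} -
#' S_b^{(j)})}{\bar S_a \bar S_b}} with signal means taken over the total
#' species fractions. For a two-state system with ideal detection these
#' reduce to \eqn{(E^{(1)}-E^{(2)})^2/(1-\bar E)^2} (GG),
#' \eqn{(E^{(1)}-E^{(2)})^2/\bar E^2} (RR) and the negative geometric mean
#' for the cross channels.
#'
#' @param Sa,Sb per-species signal vectors.
#' @param x total species fractions.
#' @return n x n matrix of contrast factors.
#' @export
contrastFactors <- function(Sa, Sb, x) {
  Sam <- sum(Sa * x); Sbm <- sum(Sb * x)
  if (Sam == 0 || Sbm == 0) stop("zero mean signal")
  outer(Sa, Sa, `-`) * outer(Sb, Sb, `-`) / (Sam * Sbm)
}

#' Kinetic part of the correlation function
#'
#' Computes \eqn{G_{k,ab}(t_c) = S_a^T G(t_c) S_b / (\bar S_a \bar S_b)}
#' with \eqn{G(t_c) = p_d e^{K t_c} X_d + (1-p_d) X_s}. Two equivalent
#' evaluation paths are provided: the direct matrix path (`"matrix"`) and
#' the spectral amplitude expansion
#' \eqn{1 + A^{(0)}_{ab} + \sum_l A^{(l)}_{ab} e^{\lambda^{(l)} t_c}}
#' (`"spectral"`); they agree to numerical precision and serve as mutual
#' checks.
#'
#' @param model a [MixtureModel-class].
#' @param Sa,Sb per-species signal vectors (length n).
#' @param tc lag grid, ms.
#' @param method `"spectral"` (default) or `"matrix"`.
#' @return numeric vector of kinetic correlation values.
#' @export
kineticCorrelation <- function(model, Sa, Sb, tc,
                               method = c("spectral", "matrix")) {
  method <- match.arg(method)
  x <- totalFractions(model)
  Sam <- sum(Sa * x); Sbm <- sum(Sb * x)
  if (Sam == 0 || Sbm == 0) stop("zero mean signal")
  if (method == "matrix") {
    es <- if (model@pd > 0) eigenDecompose(model@net) else NULL
    vapply(tc, function(t)
      drop(Sa %*% .corrMatrix(model, t, es) %*% Sb) / (Sam * Sbm),
      numeric(1))
  } else {
    amp <- kineticAmplitudes(model, Sa, Sb)
    out <- rep(1 + amp$A0, length(tc))
    for (l in seq_along(amp$A)) {
      if (abs(amp$A[l]) < 1e-14) next   # prune numerically absent terms
      out <- out + amp$A[l] * exp(amp$lambda[l] * tc)
    }
    out
  }
}

#' Amplitude expansion of the kinetic correlation
#'
#' Static residual \eqn{A^{(0)}_{ab}} (long-time limit of the kinetic term
#' minus one) and per-relaxation amplitudes
#' \eqn{A^{(l)}_{ab} = S_a^T (p_d \Gamma^{(l)} X_d) S_b / (\bar S_a \bar
#' S_b)}, derived from the spectral projectors.
#'
#' @inheritParams kineticCorrelation
#' @return list with `A0`, vector `A`, eigenvalues `lambda` (1/ms) and
#'   relaxation times `tR` (ms).
#' @export
kineticAmplitudes <- function(model, Sa, Sb) {
  n <- nStates(model@net)
  x <- totalFractions(model)
  Sam <- sum(Sa * x); Sbm <- sum(Sb * x)
  if (Sam == 0 || Sbm == 0) stop("zero mean signal")
  A0 <- drop(Sa %*% .corrMatrixInf(model) %*% Sb) / (Sam * Sbm) - 1
  if (model@pd == 0)
    return(list(A0 = A0, A = numeric(0), lambda = numeric(0),
                tR = numeric(0)))
  es <- eigenDecompose(model@net)
  xd <- equilibriumFractions(model@net)
  nz <- which(es@eigenvalues != 0)
  A <- vapply(nz, function(l)
    model@pd * drop(Sa %*% (es@projectors[[l]] %*% diag(xd, n)) %*% Sb) /
      (Sam * Sbm), numeric(1))
  list(A0 = A0, A = A, lambda = es@eigenvalues[nz], tR = -1 / es@eigenvalues[nz])
}

#' Full color-FCS model curve
#'
#' \eqn{G_{ab}(t_c) = \frac{1}{N} G_{diff}(t_c) G_{k,ab}(t_c) + 1} with
#' signal vectors from [signalVectors].
#'
#' @param model a [MixtureModel-class].
#' @param det a [DetectionModel-class].
#' @param pair one of "GG", "RR", "GR", "RG".
#' @param E species FRET efficiencies (one per network state).
#' @param tc lag grid, ms (default multi-tau).
#' @param method evaluation path, see [kineticCorrelation].
#' @return a [CorrelationCurve-class].
#' @export
colorFcsCurve <- function(model, det, pair = c("GG", "RR", "GR", "RG"), E,
                          tc = multiTauGrid(), method = "spectral") {
  pair <- match.arg(pair)
  sv <- signalVectors(det, E)
  Sa <- sv[[substr(pair, 1, 1)]]
  Sb <- sv[[substr(pair, 2, 2)]]
  Gk <- kineticCorrelation(model, Sa, Sb, tc, method = method)
  G <- diffusionTerm(tc, det@tdiff, det@s) * Gk / det@N + 1
  correlationCurve(tc, G, pair = pair)
}

#' Correlation amplitudes from single-burst FRET indicators
#'
#' Converts the indicator pair (E, Etau) of a burst into the kinetic
#' correlation amplitudes at zero lag,
#' \eqn{G_{k,GG}(0) = Var(E)/(1-E)^2}, \eqn{G_{k,RR}(0) = Var(E)/E^2},
#' \eqn{G_{k,GR}(0) = -Var(E)/(E(1-E))}, with
#' \eqn{Var(E) = (1-E)(E-E_\tau)}. The identity
#' \eqn{G_{GR}(0)^2 = G_{GG}(0) G_{RR}(0)} holds exactly.
#'
#' @param E intensity-based efficiency, in (0,1).
#' @param Etau lifetime-based efficiency.
#' @return data.frame with columns GG, RR, GR.
#' @export
amplitudesFromIndicators <- function(E, Etau) {
  if (any(E <= 0 | E >= 1)) stop("E must lie strictly inside (0,1)")
  v <- varianceFromIndicators(E, Etau)
  data.frame(GG = v / (1 - E)^2, RR = v / E^2, GR = -v / (E * (1 - E)))
}

#' Closed-form two-state kinetic correlation
#'
#' The closed two-state form
#' \eqn{G_{k,ab} = 1 + \partial^{12}_{ab}\{x^{(1)}(1-x^{(1)}) +
#' p_d x_d^{(1)}(1-x_d^{(1)}) (e^{-(k_{12}+k_{21})t_c} - 1)\}}, used as the
#' independent closed-form check of the matrix path.
#'
#' @param model a two-state [MixtureModel-class].
#' @param Sa,Sb signal vectors of length 2.
#' @param tc lag grid, ms.
#' @return kinetic correlation values.
#' @export
twoStateKineticCorrelation <- function(model, Sa, Sb, tc) {
  stopifnot(nStates(model@net) == 2)
  x <- totalFractions(model)
  d <- contrastFactors(Sa, Sb, x)[1, 2]
  K <- rateMatrix(model@net)
  k <- K[1, 2] + K[2, 1]
  xd1 <- if (model@pd > 0) equilibriumFractions(model@net)[1] else 0
  1 + d * (x[1] * (1 - x[1]) +
           model@pd * xd1 * (1 - xd1) * (exp(-k * tc) - 1))
}

#' The (pd, k12) ambiguity manifold of a binary exchange
#'
#' For fixed experimental observables - relaxation time
#' \eqn{t_R = 1/(k_{12}+k_{21})}, kinetic amplitude product
#' \eqn{c = p_d x_d^{(1)} x_d^{(2)}} and total fractions x - the family
#' \eqn{p_d(k_{12}) = c\, t_R^{-2} / (k_{12} (t_R^{-1} - k_{12}))}
#' of microscopic parameter sets produces identical correlation functions.
#' Members with any fraction outside \[0,1\] are flagged nonphysical.
#'
#' @param tR relaxation time, ms.
#' @param amp amplitude product \eqn{p_d x_d^{(1)} x_d^{(2)}}.
#' @param xTotal total fractions of the two exchanging species (length 2),
#'   used to back out the static fractions.
#' @param k12 grid of candidate rates, 1/ms (defaults to a grid inside
#'   (0, 1/tR)).
#' @return data.frame with columns k12, k21, pd, xd1, xs1, xs2, physical.
#' @export
ambiguityManifold <- function(tR, amp, xTotal,
                              k12 = seq(0.05, 0.95, by = 0.025) / tR) {
  k <- 1 / tR
  k21 <- k - k12
  xd1 <- k12 / k
  pd <- amp / (xd1 * (1 - xd1))
  xs1 <- (xTotal[1] - pd * xd1) / (1 - pd)
  xs2 <- (xTotal[2] - pd * (1 - xd1)) / (1 - pd)
  # clamp roundoff-negative static fractions
  xs1[xs1 > -1e-12 & xs1 < 0] <- 0
  xs2[xs2 > -1e-12 & xs2 < 0] <- 0
  physical <- pd >= 0 & pd <= 1 & xs1 >= 0 & xs2 >= 0 &
    xs1 + xs2 <= 1 + 1e-12
  data.frame(k12 = k12, k21 = k21, pd = pd, xd1 = xd1,
             xs1 = xs1, xs2 = xs2, physical = physical)
}
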