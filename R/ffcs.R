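#' FilterSet: species filters over (channel x micro-time) patterns
#'
#' Filtered-FCS separates species contributions to the correlation function
#' by weighting every photon according to its detection channel and TCSPC
#' micro time. Given the conditional pattern \eqn{p^{(i)}} of each species
#' over the pooled (channel, micro-time-bin) index and the mixture
#' histogram \eqn{W(t) = \sum_i w_i p^{(i)}(t)}, the filters are the
#' weighted least-squares pseudo-inverse
#' \eqn{F = (P^T D P)^{-1} P^T D} with \eqn{D = diag(1/W)}, which makes the
#' expected filtered photon count of species j equal \eqn{\delta_{ij}}
#' times its true count (unbiasedness, \eqn{F P = I} exactly).
#'
#' @slot filters nSpecies x nIndex matrix of filter weights.
#' @slot patterns nIndex x nSpecies matrix of conditional patterns.
#' @slot labels species labels.
#' @slot nBins micro-time bins per channel.
#' @slot microRange micro-time range, ns.
#' @slot conditionNumber condition number of the weighted design.
#' @export
setClass("FilterSet",
  representation(filters = "matrix", patterns = "matrix",
                 labels = "character", nBins = "integer",
                 microRange = "numeric", conditionNumber = "numeric"),
  validity = function(object) {
    FP <- object@filters %*% object@patterns
    if (max(abs(FP - diag(nrow(FP)))) > 1e-8)
      "filters violate the unbiasedness identity F P = I" else TRUE
  })

setMethod("show", "FilterSet", function(object) {
  cat(sprintf(
    "FilterSet: %d species (%s), %d micro-time bins/channel, cond = %.3g\n",
    length(object@labels), paste(object@labels, collapse = ", "),
    object@nBins, object@conditionNumber))
})

#' Model decay patterns of a species set
#'
#' Noise-free conditional patterns over the pooled (channel, micro-time)
#' index built from the species decay models: the green part is the donor
#' decay with lifetime \eqn{\tau_{D0}(1-E^{(i)})} weighted by the green
#' photon fraction, the red part the acceptor decay weighted by the red
#' fraction (per the detection model's gamma and alpha). Each pattern sums
#' to 1.
#'
#' @param E species FRET efficiencies.
#' @param det a [DetectionModel-class].
#' @param tauD0,tauA donor-only and acceptor lifetimes, ns.
#' @param nBins micro-time bins per channel (coarse binning stabilizes the
#'   filters; default 64).
#' @param microRange micro-time range, ns.
#' @param labels species labels.
#' @return nIndex x nSpecies pattern matrix (green bins first).
#' @export
speciesPatterns <- function(E, det = detectionModel(), tauD0 = 4, tauA = 1,
                            nBins = 64, microRange = 25, labels = NULL) {
  if (is.null(labels)) labels <- paste0("S", seq_along(E))
  w <- microRange / nBins
  edges <- seq(0, microRange, by = w)
  binMass <- function(tau) {
    m <- exp(-edges[-length(edges)] / tau) - exp(-edges[-1] / tau)
    m / (1 - exp(-microRange / tau))
  }
  sv <- signalVectors(det, E)
  P <- vapply(seq_along(E), function(i) {
    tot <- sv$G[i] + sv$R[i]
    c(sv$G[i] / tot * binMass(tauD0 * (1 - E[i])),
      sv$R[i] / tot * binMass(tauA))
  }, numeric(2 * nBins))
  colnames(P) <- labels
  P
}

#' Build filtered-FCS species filters
#'
#' @param patterns nIndex x nSpecies matrix of conditional patterns (e.g.
#'   from [speciesPatterns] or from normalized sub-ensemble decays).
#' @param weights mixture weights of the species (photon fractions; sum
#'   to 1).
#' @param nBins micro-time bins per channel.
#' @param microRange micro-time range, ns.
#' @param condWarn condition number above which a warning is emitted.
#' @return a [FilterSet-class].
#' @export
buildFilters <- function(patterns, weights, nBins = nrow(patterns) / 2,
                         microRange = 25, condWarn = 1e4) {
  ns <- ncol(patterns)
  stopifnot(length(weights) == ns)
  weights <- weights / sum(weights)
  W <- drop(patterns %*% weights)
  use <- W > 1e-12
  if (!any(use)) stop("mixture histogram empty where patterns live")
  D <- 1 / W[use]
  Pu <- patterns[use, , drop = FALSE]
  M <- crossprod(Pu, Pu * D)            # P^T D P
  cond <- kappa(M, exact = TRUE)
  if (!is.finite(cond) || cond > 1e12) {
    # name the most collinear pair
    cors <- abs(stats::cor(patterns))
    diag(cors) <- 0
    ij <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    lb <- colnames(patterns)
    if (is.null(lb)) lb <- paste0("S", seq_len(ns))
    stop("degenerate species patterns: ", lb[ij[1]], " and ", lb[ij[2]],
         " are collinear (identical lifetimes?)")
  }
  if (cond > condWarn)
    warning(sprintf("ill-conditioned filter design (condition number %.3g)",
                    cond))
  Fu <- solve(M, t(Pu * D))             # (P^T D P)^{-1} P^T D
  filt <- matrix(0, ns, nrow(patterns))
  filt[, use] <- Fu
  lb <- colnames(patterns)
  if (is.null(lb)) lb <- paste0("S", seq_len(ns))
  new("FilterSet", filters = filt, patterns = patterns, labels = lb,
      nBins = as.integer(nBins), microRange = microRange,
      conditionNumber = cond)
}

#' Per-photon filter weights
#'
#' Maps each photon of a stream to its (channel, micro-time bin) index and
#' returns the filter weight of every species for every photon.
#'
#' @param stream a [PhotonStream-class].
#' @param filters a [FilterSet-class].
#' @return nPhotons x nSpecies matrix of weights.
#' @export
photonFilterWeights <- function(stream, filters) {
  nb <- filters@nBins
  w <- filters@microRange / nb
  bin <- pmin(nb, floor(stream@microTime / w) + 1L)
  idx <- ifelse(stream@channel == 0L, bin, nb + bin)
  t(filters@filters[, idx, drop = FALSE])
}

#' Species auto- and cross-correlation functions
#'
#' Correlates the filter-weighted photon streams for every ordered species
#' pair, yielding the species autocorrelation (sACF) and cross-correlation
#' (sCCF) matrix of filtered-FCS.
#'
#' @param stream a [PhotonStream-class].
#' @param filters a [FilterSet-class].
#' @param pairs optional character matrix/list of pairs; default all
#'   unordered pairs plus autocorrelations.
#' @param ... passed to [correlateStream].
#' @return named list of [CorrelationCurve-class] objects (names like
#'   "LF-HF").
#' @export
speciesCorrelations <- function(stream, filters, pairs = NULL, ...) {
  Wm <- photonFilterWeights(stream, filters)
  lb <- filters@labels
  ns <- length(lb)
  if (is.null(pairs)) {
    pairs <- list()
    for (i in seq_len(ns)) for (j in i:ns)
      pairs[[length(pairs) + 1]] <- c(i, j)
  }
  out <- list()
  for (p in pairs) {
    nm <- paste(lb[p[1]], lb[p[2]], sep = "-")
    out[[nm]] <- correlateStream(stream, Wm[, p[1]], Wm[, p[2]],
                                 pair = nm, ...)
  }
  out
}

#' Fit the rise of a species cross-correlation
#'
#' For two species that cannot be the same molecule at the same instant,
#' the kinetic part of the cross-correlation vanishes at zero lag and rises
#' to a positive plateau as exchange mixes the species. The effective
#' single-relaxation model
#' \eqn{G(t) = 1 + B + P\,G_{diff}(t)\,(1 - e^{-t/t_{rise}})} (plateau
#' \eqn{P \ge 0}) is well conditioned and its `tRise` ranks direct versus
#' indirect exchange pathways: indirect pairs rise later.
#'
#' @param curve a [CorrelationCurve-class].
#' @param tdiff0 initial diffusion time, ms.
#' @param s aspect ratio.
#' @param tRiseRange allowed rise-time range, ms.
#' @param nStarts random restarts.
#' @return list with `tRise` (ms), `plateau`, `tdiff`, `baseline`,
#'   `chi2r`, `fit`.
#' @export
fitRiseTime <- function(curve, tdiff0 = 4, s = 0.25,
                        tRiseRange = c(0.01, 1.5), nStarts = 5) {
  tc <- curve@lag; y <- curve@G
  sig <- curve@sigma
  bad <- !is.finite(sig) | sig <= 0
  if (any(bad)) sig[bad] <- stats::median(sig[!bad])
  # parameters: log plateau, log tdiff, log tRise, baseline
  model <- function(p)
    1 + p[4] + exp(p[1]) * diffusionTerm(tc, exp(p[2]), s) *
      (1 - exp(-tc / exp(p[3])))
  resid <- function(p) (model(p) - y) / sig
  plateau0 <- max(mean(y[tc > 0.5 & tc < 2]) - mean(y[tc < 0.02]), 0.02)
  p0 <- c(log(plateau0), log(tdiff0), log(0.1), 0)
  lowerB <- c(-12, log(tdiff0) - 1.5, log(tRiseRange[1]), -0.3)
  upperB <- c(4, log(tdiff0) + 1.5, log(tRiseRange[2]), 0.3)
  p0 <- pmin(pmax(p0, lowerB), upperB)
  best <- NULL
  for (st in seq_len(nStarts)) {
    p <- if (st == 1) p0 else
      pmin(pmax(p0 + rnorm(4, sd = 0.5), lowerB), upperB)
    fit <- tryCatch(
      minpack.lm::nls.lm(p, fn = resid, lower = lowerB, upper = upperB,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("rise-time fit failed")
  p <- best$par
  list(tRise = exp(p[3]), plateau = exp(p[1]), tdiff = exp(p[2]),
       baseline = p[4], chi2r = best$deviance / max(length(y) - 4, 1),
       fit = model(p))
}

#' Fit species correlation curves
#'
#' Global fit of a set of species correlation curves with a shared
#' diffusion time and a shared set of relaxation times, free amplitudes
#' per curve (model \eqn{1 + \frac{1}{N}G_{diff}(1 + A_0 + \sum_r A_r
#' e^{-t/t_{R,r}})}); also reports, per curve, a single-exponential
#' effective rise time used to rank direct vs indirect exchange pathways.
#'
#' @param curves list of [CorrelationCurve-class] objects on a shared lag
#'   grid.
#' @param nRelaxations number of shared relaxation times.
#' @param s aspect ratio.
#' @param tdiff0 initial diffusion time, ms.
#' @param tR0 initial relaxation times, ms.
#' @param nStarts random restarts for the global fit.
#' @return list with shared `tdiff`, `tR`, per-curve amplitude table
#'   `amplitudes`, `chi2r`, and `riseTimes` (per-curve single-exponential
#'   fits).
#' @export
fitSpeciesCorrelations <- function(curves, nRelaxations = 1, s = 0.25,
                                   tdiff0 = 4, tR0 = NULL, nStarts = 4) {
  nc <- length(curves)
  if (nRelaxations >= length(curves[[1]]@lag))
    stop("over-parameterized model")
  nr <- nRelaxations
  if (is.null(tR0)) tR0 <- 0.1 * 3^(seq_len(nr) - 1)
  tc <- curves[[1]]@lag
  Y <- vapply(curves, function(cu) cu@G, numeric(length(tc)))
  S <- vapply(curves, function(cu) {
    s_ <- cu@sigma
    s_[!is.finite(s_) | s_ <= 0] <- stats::median(s_[is.finite(s_) & s_ > 0])
    s_
  }, numeric(length(tc)))
  # parameters: log tdiff, log tR (nr), then per curve
  # (logN, A0, A_r..., baseline)
  perCurve <- 3 + nr
  model <- function(p) {
    td <- exp(p[1]); tR <- exp(p[1 + seq_len(nr)])
    gd <- diffusionTerm(tc, td, s)
    sapply(seq_len(nc), function(ci) {
      q <- p[1 + nr + (ci - 1) * perCurve + seq_len(perCurve)]
      kin <- rep(1 + q[2], length(tc))
      for (r in seq_len(nr)) kin <- kin + q[2 + r] * exp(-tc / tR[r])
      1 + q[perCurve] + gd * kin / exp(q[1])
    })
  }
  resid <- function(p) as.vector((model(p) - Y) / S)
  p0 <- c(log(tdiff0), log(tR0),
          unlist(lapply(seq_len(nc), function(ci)
            c(log(1 / max(abs(Y[1, ci] - 1), 0.05)), 0, rep(-0.2, nr), 0))))
  lowerB <- rep(-Inf, length(p0)); upperB <- rep(Inf, length(p0))
  idxTR <- 1 + seq_len(nr)
  lowerB[idxTR] <- log(5e-4); upperB[idxTR] <- log(20)
  idxB <- 1 + nr + (seq_len(nc) - 1) * perCurve + perCurve
  lowerB[idxB] <- -0.3; upperB[idxB] <- 0.3
  best <- NULL
  for (st in seq_len(nStarts)) {
    p <- if (st == 1) p0 else
      pmin(pmax(p0 + rnorm(length(p0), sd = 0.4), lowerB), upperB)
    fit <- tryCatch(
      minpack.lm::nls.lm(p, fn = resid, lower = lowerB, upper = upperB,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("species correlation fit failed")
  p <- best$par
  tR <- sort(exp(p[1 + seq_len(nr)]), decreasing = TRUE)
  amp <- t(vapply(seq_len(nc), function(ci) {
    q <- p[1 + nr + (ci - 1) * perCurve + seq_len(perCurve)]
    c(N = exp(q[1]), A0 = q[2],
      setNames(q[2 + seq_len(nr)], paste0("A", seq_len(nr))),
      baseline = q[perCurve])
  }, numeric(perCurve)))
  rownames(amp) <- names(curves)
  rise <- vapply(curves, function(cu) {
    f <- tryCatch(fitFcsCurve(cu, nRelaxations = 1, tdiff0 = exp(p[1]),
                              s = s, fixTdiff = exp(p[1]), nStarts = 3),
                  error = function(e) list(tR = NA_real_))
    f$tR[1]
  }, numeric(1))
  dof <- max(length(Y) - length(p), 1)
  list(tdiff = exp(p[1]), tR = tR, amplitudes = amp,
       chi2r = best$deviance / dof, riseTimes = rise)
}
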