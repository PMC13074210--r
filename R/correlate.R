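#' Correlate a photon stream
#'
#' Multi-tau correlation of two (optionally weighted) photon selections of
#' the same stream. For color-FCS the weights are the channel indicators;
#' for filtered-FCS they are per-photon species filter weights. The curve
#' itself is estimated from the full stream (finite-measurement
#' normalization bias scales with the inverse total duration, so it is
#' negligible there); per-point uncertainties come from block averaging -
#' the stream is split into `nBlocks` equal-duration segments, each is
#' correlated separately, and the standard error of the blockwise mean is
#' reported as sigma.
#'
#' @param stream a [PhotonStream-class].
#' @param wa,wb per-photon weights (numeric vectors of length nPhotons) or
#'   a channel pair string like `"GR"` (G = green indicator, R = red).
#' @param binWidth base bin width, ms.
#' @param pointsPerCascade lags per multi-tau cascade.
#' @param maxLag largest lag, ms (capped at a tenth of the block length).
#' @param nBlocks number of blocks for the uncertainty estimate.
#' @param pair label stored on the curve.
#' @return a [CorrelationCurve-class].
#' @export
correlateStream <- function(stream, wa = "G", wb = "R", binWidth = 0.005,
                            pointsPerCascade = 16, maxLag = 50,
                            nBlocks = 16, pair = NULL) {
  t <- stream@macroTime
  stopifnot(length(t) > 0)
  lab <- ""
  chw <- function(w) {
    if (is.character(w)) {
      lab <<- paste0(lab, w)
      switch(w, G = as.numeric(stream@channel == 0L),
                R = as.numeric(stream@channel == 1L),
             stop("unknown channel ", w))
    } else w
  }
  if (is.character(wa) && nchar(wa) == 2 && identical(wb, "R")) {
    # allow correlateStream(stream, "GR")
    wb <- substr(wa, 2, 2); wa <- substr(wa, 1, 1)
  }
  va <- chw(wa); vb <- chw(wb)
  if (is.null(pair)) pair <- if (nzchar(lab)) lab else "ww"
  dur <- max(t)
  blockLen <- dur / nBlocks
  maxLag <- min(maxLag, blockLen / 10)
  full <- cpp_multitau(t, va, vb, binWidth, dur, pointsPerCascade, maxLag)
  acc <- matrix(NA_real_, length(full$lag), nBlocks)
  for (b in seq_len(nBlocks)) {
    lo <- (b - 1) * blockLen
    sel <- t >= lo & t < lo + blockLen
    if (sum(sel) < 10) next
    res <- cpp_multitau(t[sel] - lo, va[sel], vb[sel], binWidth, blockLen,
                        pointsPerCascade, maxLag)
    n <- min(length(res$G), nrow(acc))
    if (isTRUE(all.equal(res$lag[seq_len(n)], full$lag[seq_len(n)])))
      acc[seq_len(n), b] <- res$G[seq_len(n)]
  }
  nOk <- rowSums(!is.na(acc))
  se <- apply(acc, 1, sd, na.rm = TRUE) / sqrt(pmax(nOk, 1))
  keep <- nOk >= max(2, nBlocks / 2)
  if (!any(keep)) stop("correlation failed: no usable blocks")
  correlationCurve(full$lag[keep], full$G[keep], se[keep], pair = pair)
}

#' Fit a diffusion + kinetics model to a correlation curve
#'
#' Model \eqn{G(t_c) = 1 + B + \frac{1}{N} G_{diff}(t_c)\,(1 + A_0 +
#' \sum_r A_r e^{-t_c/t_{R,r}})} with the 3D Gaussian diffusion factor.
#' Kinetic amplitudes may be negative (anti-correlated cross terms). The
#' small additive baseline B absorbs the finite-measurement normalization
#' bias of correlation estimators (set `baseline = FALSE` to pin B = 0).
#'
#' @param curve a [CorrelationCurve-class] with finite sigma.
#' @param nRelaxations number of kinetic exponentials (0 for pure
#'   diffusion).
#' @param tdiff0,tR0 initial guesses (ms).
#' @param s aspect ratio (fixed).
#' @param fixTdiff optional fixed diffusion time.
#' @param baseline fit the additive offset B (default TRUE); bounded to
#'   `baselineMax` in magnitude.
#' @param tRRange allowed relaxation-time range, ms.
#' @param baselineMax bound on |B|.
#' @param nStarts random restarts.
#' @return list with `N`, `tdiff`, `A0`, `A`, `tR` (sorted decreasing),
#'   `baseline`, `chi2r`, and fitted values `fit`.
#' @export
fitFcsCurve <- function(curve, nRelaxations = 1, tdiff0 = 5,
                        tR0 = NULL, s = 0.25, fixTdiff = NULL,
                        baseline = TRUE, tRRange = c(5e-4, 20),
                        baselineMax = 0.3, nStarts = 5) {
  tc <- curve@lag; y <- curve@G
  sig <- curve@sigma
  if (all(is.na(sig))) sig <- rep(1e-3, length(y))
  sig[!is.finite(sig) | sig <= 0] <- max(sig[is.finite(sig) & sig > 0], 1e-6)
  if (is.null(tR0))
    tR0 <- tdiff0 / 50 * 2^(seq_len(nRelaxations) - 1)
  nr <- nRelaxations
  model <- function(p) {
    N <- exp(p[1])
    td <- if (is.null(fixTdiff)) exp(p[2]) else fixTdiff
    off <- if (is.null(fixTdiff)) 2 else 1
    A0 <- p[off + 1]
    kin <- rep(1 + A0, length(tc))
    if (nr > 0) {
      A <- p[off + 1 + seq_len(nr)]
      tR <- exp(p[off + 1 + nr + seq_len(nr)])
      for (r in seq_len(nr)) kin <- kin + A[r] * exp(-tc / tR[r])
    }
    B <- if (baseline) p[length(p)] else 0
    1 + B + diffusionTerm(tc, td, s) * kin / N
  }
  resid <- function(p) (model(p) - y) / sig
  amp0 <- max(abs(y[1] - 1), 0.1)
  p0 <- c(log(1 / amp0), if (is.null(fixTdiff)) log(tdiff0), 0,
          if (nr > 0) c(rep(0.3, nr), log(tR0)),
          if (baseline) 0)
  lowerB <- rep(-Inf, length(p0)); upperB <- rep(Inf, length(p0))
  off0 <- if (is.null(fixTdiff)) 2 else 1
  if (nr > 0) {
    idxTR <- off0 + 1 + nr + seq_len(nr)
    lowerB[idxTR] <- log(tRRange[1]); upperB[idxTR] <- log(tRRange[2])
  }
  if (baseline) {
    lowerB[length(p0)] <- -baselineMax; upperB[length(p0)] <- baselineMax
  }
  p0 <- pmin(pmax(p0, lowerB), upperB)
  best <- NULL
  for (sidx in seq_len(nStarts)) {
    p <- if (sidx == 1) p0 else
      pmin(pmax(p0 + rnorm(length(p0), sd = 0.5), lowerB), upperB)
    fit <- tryCatch(
      minpack.lm::nls.lm(p, fn = resid, lower = lowerB, upper = upperB,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("FCS fit failed")
  p <- best$par
  N <- exp(p[1])
  td <- if (is.null(fixTdiff)) exp(p[2]) else fixTdiff
  off <- if (is.null(fixTdiff)) 2 else 1
  A0 <- p[off + 1]
  A <- if (nr > 0) p[off + 1 + seq_len(nr)] else numeric(0)
  tR <- if (nr > 0) exp(p[off + 1 + nr + seq_len(nr)]) else numeric(0)
  ord <- order(-tR)
  dof <- max(length(y) - length(p), 1)
  list(N = N, tdiff = td, A0 = A0, A = A[ord], tR = tR[ord],
       baseline = if (baseline) p[length(p)] else 0,
       chi2r = best$deviance / dof, fit = model(p), lag = tc)
}
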