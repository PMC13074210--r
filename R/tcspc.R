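#' DecayHistogram: a TCSPC fluorescence decay
#'
#' Micro-time histogram of photon arrival delays. Counts are nonnegative
#' integers for measured/simulated data and reals for model curves.
#'
#' @slot time bin centers, ns (uniform spacing).
#' @slot counts counts (or model values) per bin.
#' @export
setClass("DecayHistogram",
  representation(time = "numeric", counts = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@time) != length(object@counts))
      msg <- c(msg, "time and counts lengths differ")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
    if (length(object@time) > 2) {
      d <- diff(object@time)
      if (max(abs(d - d[1])) > 1e-9 * d[1])
        msg <- c(msg, "bin width must be uniform")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname DecayHistogram-class
#' @param time,counts see slots.
#' @export
decayHistogram <- function(time, counts)
  new("DecayHistogram", time = time, counts = counts)

setMethod("show", "DecayHistogram", function(object) {
  cat(sprintf("DecayHistogram: %d bins over [%g, %g] ns, %g counts\n",
              length(object@time), min(object@time), max(object@time),
              sum(object@counts)))
})

#' Default TCSPC micro-time grid
#'
#' @param range micro-time range, ns.
#' @param nBins number of bins (default 4096).
#' @return vector of bin centers, ns.
#' @export
microTimeGrid <- function(range = 25, nBins = 4096) {
  w <- range / nBins
  seq(w / 2, range - w / 2, by = w)
}

#' Donor fluorescence decay of a species mixture
#'
#' \eqn{f_{D|D}^{DA}(t) = \sum_i x^{(i)} \exp(-t / (\tau_{D0}(1-E^{(i)})))}
#' - species-fraction weighting exactly, not fluorescence weighting (the
#' photon-weighted alternative is available via `weighting = "photon"` for
#' comparison). Linear in the fractions.
#'
#' @param x total species fractions (sum to 1).
#' @param E species FRET efficiencies; species with E = 1 (zero lifetime)
#'   are excluded with a warning.
#' @param tauD0 donor-only lifetime, ns.
#' @param t micro-time grid, ns.
#' @param weighting `"species"` (as defined) or `"photon"` (fractions
#'   multiplied by relative photon yield \eqn{1-E^{(i)}}, renormalized).
#' @return model decay values on `t`, f(0) = 1.
#' @export
decayModel <- function(x, E, tauD0, t = microTimeGrid(),
                       weighting = c("species", "photon")) {
  weighting <- match.arg(weighting)
  stopifnot(length(x) == length(E), tauD0 > 0)
  if (abs(sum(x) - 1) > 1e-6) stop("fractions must sum to 1")
  drop <- E >= 1
  if (any(drop)) {
    warning("species with E = 1 (zero lifetime) excluded from the decay")
    x <- x[!drop] / sum(x[!drop]); E <- E[!drop]
  }
  w <- switch(weighting, species = x,
              photon = x * (1 - E) / sum(x * (1 - E)))
  tau <- tauD0 * (1 - E)
  colSums(w * exp(-outer(1 / tau, t)))
}

#' Poisson realization of a model decay
#'
#' Scales the model to `totalCounts` expected photons and draws Poisson
#' counts per bin; reproducible under a fixed seed.
#'
#' @param model model decay values (nonnegative).
#' @param totalCounts expected total photon count (> 0).
#' @param t bin centers, ns.
#' @param seed optional integer seed.
#' @return a [DecayHistogram-class].
#' @export
poissonDecay <- function(model, totalCounts, t = microTimeGrid(),
                         seed = NULL) {
  stopifnot(totalCounts > 0, all(model >= 0),
            length(model) == length(t))
  if (!is.null(seed)) set.seed(seed)
  mu <- if (sum(model) > 0) model * (totalCounts / sum(model)) else model
  decayHistogram(t, rpois(length(mu), mu))
}

#' Sub-ensemble decay of selected bursts
#'
#' Histogram of donor-channel micro times of photons belonging to the
#' selected bursts.
#'
#' @param stream a [PhotonStream-class].
#' @param bursts burst table from [detectBursts].
#' @param select logical or integer selection of burst rows (default all).
#' @param range,nBins micro-time histogram settings.
#' @return a [DecayHistogram-class].
#' @export
subensembleDecay <- function(stream, bursts, select = TRUE,
                             range = 25, nBins = 256) {
  if (nrow(bursts) == 0) stop("empty burst selection")
  sel <- bursts[select, , drop = FALSE]
  sel <- sel[!is.na(sel$start), , drop = FALSE]
  if (nrow(sel) == 0) stop("empty burst selection")
  keep <- logical(length(stream@macroTime))
  idx <- findInterval(stream@macroTime, sel$start)
  ok <- idx >= 1
  keep[ok] <- stream@macroTime[ok] <= sel$stop[idx[ok]]
  keep <- keep & stream@channel == 0L   # donor channel
  mt <- stream@microTime[keep]
  w <- range / nBins
  cnt <- tabulate(pmin(nBins, floor(mt / w) + 1L), nbins = nBins)
  decayHistogram(microTimeGrid(range, nBins), cnt)
}

#' Intensity-weighted mean lifetime of a decay
#'
#' Second moment over first moment of the lifetime distribution, computed
#' from the decay as \eqn{\int t f(t) dt / \int f(t) dt} (valid when the
#' micro-time range covers the decay).
#'
#' @param hist a [DecayHistogram-class] or model values with `t` given.
#' @param t bin centers if `hist` is a bare numeric vector.
#' @return mean delay time, ns.
#' @export
meanArrivalTime <- function(hist, t = NULL) {
  if (is(hist, "DecayHistogram")) { t <- hist@time; f <- hist@counts }
  else f <- hist
  sum(t * f) / sum(f)
}

#' Fit a multi-exponential model to a decay histogram
#'
#' Fits \eqn{f(t) = A \sum_i x_i e^{-t/\tau_i}} with Poisson weights
#' \eqn{\sigma = \sqrt{max(counts, 1)}} by bounded Levenberg-Marquardt.
#' Fractions are parameterized on the simplex; lifetimes are bounded to
#' (0.01, tauD0). With `tauD0` given, component efficiencies
#' \eqn{E_i = 1 - \tau_i/\tau_{D0}} are reported.
#'
#' @param hist a [DecayHistogram-class].
#' @param nComponents model order, 1 to 3.
#' @param tauD0 donor-only lifetime, ns (used for bounds and E).
#' @param init optional list with `tau` (ns) and `x` (fractions).
#' @param nStarts number of random restarts around the default init.
#' @return list with `tau`, `x`, `E`, `amplitude`, `chi2r`.
#' @export
fitDecay <- function(hist, nComponents = 2, tauD0 = 4, init = NULL,
                     nStarts = 4) {
  stopifnot(nComponents >= 1, nComponents <= 3)
  t <- hist@time; y <- hist@counts
  sig <- sqrt(pmax(y, 1))
  modelFun <- function(tau, x) {
    m <- colSums(x * exp(-outer(1 / tau, t)))
    a <- sum(y * m / sig^2) / sum(m^2 / sig^2)   # analytic amplitude
    a * m
  }
  unpack <- function(p) {
    tau <- exp(p[seq_len(nComponents)])
    if (nComponents > 1) {
      z <- c(p[-seq_len(nComponents)], 0)
      x <- exp(z) / sum(exp(z))
    } else x <- 1
    list(tau = tau, x = x)
  }
  resid <- function(p) {
    u <- unpack(p)
    (modelFun(u$tau, u$x) - y) / sig
  }
  mt <- meanArrivalTime(hist)
  tau0 <- if (!is.null(init)) init$tau else
    mt * seq(0.5, 1.6, length.out = nComponents)
  x0 <- if (!is.null(init)) init$x else rep(1 / nComponents, nComponents)
  p0 <- c(log(tau0), if (nComponents > 1) log(x0[-nComponents] / x0[nComponents]))
  best <- NULL
  for (s in seq_len(nStarts)) {
    p <- if (s == 1) p0 else p0 + rnorm(length(p0), sd = 0.4)
    fit <- tryCatch(
      minpack.lm::nls.lm(p, fn = resid,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("decay fit failed to converge")
  u <- unpack(best$par)
  ord <- order(u$tau)
  tau <- u$tau[ord]; x <- if (length(u$x) > 1) u$x[ord] else u$x
  m <- colSums(x * exp(-outer(1 / tau, t)))
  a <- sum(y * m / sig^2) / sum(m^2 / sig^2)
  dof <- length(y) - length(best$par) - 1
  list(tau = tau, x = x, E = 1 - tau / tauD0, amplitude = a,
       chi2r = best$deviance / dof)
}
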