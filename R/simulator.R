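#' PhotonStream: time-ordered single-photon data
#'
#' @slot macroTime photon arrival times, ms, nondecreasing.
#' @slot channel integer, 0 = green/donor, 1 = red/acceptor.
#' @slot microTime TCSPC delay, ns, in \[0, microRange).
#' @slot microRange micro-time range, ns.
#' @export
setClass("PhotonStream",
  representation(macroTime = "numeric", channel = "integer",
                 microTime = "numeric", microRange = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@channel) != length(object@macroTime) ||
        length(object@microTime) != length(object@macroTime))
      msg <- c(msg, "column lengths differ")
    if (is.unsorted(object@macroTime)) msg <- c(msg, "macro times unsorted")
    if (length(object@microTime) &&
        (min(object@microTime) < 0 ||
         max(object@microTime) >= object@microRange))
      msg <- c(msg, "micro times outside [0, microRange)")
    if (length(msg)) msg else TRUE
  })

#' @rdname PhotonStream-class
#' @param macroTime,channel,microTime,microRange see slots.
#' @export
photonStream <- function(macroTime, channel, microTime, microRange = 25)
  new("PhotonStream", macroTime = as.numeric(macroTime),
      channel = as.integer(channel), microTime = as.numeric(microTime),
      microRange = microRange)

setMethod("show", "PhotonStream", function(object) {
  n <- length(object@macroTime)
  cat(sprintf("PhotonStream: %d photons over %.3f s (%.1f%% green)\n",
              n, if (n) max(object@macroTime) / 1000 else 0,
              if (n) 100 * mean(object@channel == 0L) else NA))
})

#' @describeIn PhotonStream-class number of photons
#' @param x a PhotonStream
#' @export
nPhotons <- function(x) length(x@macroTime)

#' Simulation configuration
#'
#' Collects everything the photon-level Monte Carlo needs: the species set,
#' the static/dynamic mixture, detection parameters, lifetimes, box geometry
#' and integration settings. The diffusion coefficient is set from the
#' diffusion time via \eqn{D = w_0^2/(4 t_{diff})}; the observation volume
#' is the 3D Gaussian \eqn{W(r) = \exp(-2(x^2+y^2)/w_0^2 - 2z^2/z_0^2)};
#' molecules move in a periodic box of `boxXY` w0 by `boxXY` w0 by `boxZ`
#' z0. The number of molecules follows from the target mean occupancy `N`
#' of the effective volume \eqn{V_{eff} = \pi^{3/2} w_0^2 z_0} unless given
#' explicitly.
#'
#' @param E species FRET efficiencies.
#' @param labels species labels.
#' @param net [KineticNetwork-class] for the dynamic molecules (or NULL for
#'   a fully static mixture).
#' @param pd fraction of dynamic molecules.
#' @param xs static-state fractions (default uniform).
#' @param det a [DetectionModel-class].
#' @param tauD0 donor-only lifetime, ns.
#' @param tauA acceptor lifetime, ns.
#' @param microRange micro-time range, ns.
#' @param boxXY,boxZ box half-extent multipliers (units of w0 / z0).
#' @param nMolecules override the molecule count.
#' @param xd initial-state fractions of the dynamic molecules; defaults to
#'   the equilibrium fractions of `net`. Must be given explicitly when the
#'   dynamic exchange covers only a subset of the species (the network is
#'   reducible over the full species set).
#' @param dt time step, ms; must not exceed a tenth of the fastest
#'   relaxation time and of the diffusion time.
#' @param duration total simulated time, ms.
#' @return a list of class `"fkSimulationConfig"`.
#' @export
simulationConfig <- function(E, labels = names(E), net = NULL, pd = 0,
                             xs = NULL, det = detectionModel(),
                             tauD0 = 4, tauA = 1, microRange = 25,
                             boxXY = 6, boxZ = 6, nMolecules = NULL,
                             xd = NULL, dt = NULL, duration = 10000) {
  n <- length(E)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  if (is.null(xs)) xs <- rep(1 / n, n)
  stopifnot(length(xs) == n, pd >= 0, pd <= 1)
  if (pd > 0 && is.null(net)) stop("dynamic mixture requires a network")
  if (!is.null(net) && nStates(net) != n)
    stop("network size must match the species set")
  if (is.null(nMolecules)) {
    veff <- pi^1.5 / det@s            # in units of w0^3: pi^{3/2} z0 (w0=1)
    vbox <- boxXY^2 * boxZ / det@s
    nMolecules <- max(2L, as.integer(round(det@N * vbox / veff)))
  }
  if (pd > 0 && is.null(xd)) {
    if (!.isIrreducible(net))
      stop("reducible network: give xd (initial dynamic fractions) ",
           "explicitly")
    xd <- equilibriumFractions(net)
  }
  tRmin <- if (!is.null(net) && pd > 0) {
    ev <- eigenDecompose(net)@eigenvalues
    if (any(ev != 0)) 1 / max(abs(ev)) else Inf
  } else Inf
  dtMax <- min(tRmin, det@tdiff) / 10
  if (is.null(dt)) dt <- min(dtMax, 0.005)
  if (dt > dtMax * (1 + 1e-9))
    stop(sprintf("time step %g ms unstable; must be <= %g ms", dt, dtMax))
  structure(list(E = E, labels = labels, net = net, pd = pd, xs = xs,
                 det = det, tauD0 = tauD0, tauA = tauA,
                 microRange = microRange, boxXY = boxXY, boxZ = boxZ,
                 nMolecules = nMolecules, xd = xd, dt = dt,
                 duration = duration),
            class = "fkSimulationConfig")
}

## deterministic largest-remainder allocation of counts to fractions
.allocate <- function(nTot, frac) {
  raw <- nTot * frac
  base <- floor(raw)
  rem <- nTot - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a photon stream
#'
#' Runs the photon-level Monte Carlo defined by a [simulationConfig].
#' Dynamic/static molecule counts and their initial states are allocated
#' deterministically by largest remainder (so the realized mixture matches
#' the configured fractions as closely as the molecule count allows); all
#' stochastic draws use R's RNG, so `set.seed()` before the call makes the
#' stream bit-reproducible.
#'
#' @param cfg a config from [simulationConfig].
#' @param seed optional integer seed.
#' @return a [PhotonStream-class].
#' @export
simulateStream <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "fkSimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(cfg$E)
  nMol <- cfg$nMolecules
  nDyn <- as.integer(round(cfg$pd * nMol))
  K <- if (!is.null(cfg$net)) rateMatrix(cfg$net) else matrix(0, n, n)
  xd <- if (nDyn > 0) cfg$xd else rep(1 / n, n)
  initDyn <- rep(seq_len(n) - 1L, .allocate(nDyn, xd))
  initStat <- rep(seq_len(n) - 1L, .allocate(nMol - nDyn, cfg$xs))
  init <- c(initDyn, initStat)
  det <- cfg$det
  res <- cpp_simulate_stream(nMol, nDyn, init, K, cfg$E,
                             det@gamma, det@alpha, det@Q0,
                             cfg$tauD0, cfg$tauA, cfg$microRange,
                             det@tdiff, det@s, cfg$boxXY, cfg$boxZ,
                             cfg$dt, cfg$duration)
  photonStream(res$macro, res$channel, res$micro, cfg$microRange)
}

#' Sliding-window burst search
#'
#' Photons with at least `minNeighbors` photons inside a `window`-wide
#' interval centered on them are burst photons; runs of burst photons
#' separated by gaps shorter than the window are grouped into bursts, and
#' bursts with at least `minPhotons` photons are kept. Per burst the table
#' reports green/red counts, the ideal intensity FRET efficiency
#' E = NR/(NG+NR), the intensity-weighted mean donor micro time tauF (ns)
#' and the duration.
#'
#' @param stream a [PhotonStream-class].
#' @param minPhotons minimum photons per burst (default 60).
#' @param window sliding window length, ms (default 0.5).
#' @param minNeighbors minimum photons in the window (default 5).
#' @return data.frame with one row per burst: start, stop, duration (ms),
#'   NG, NR, E, tauF (ns).
#' @export
detectBursts <- function(stream, minPhotons = 60, window = 0.5,
                         minNeighbors = 5) {
  t <- stream@macroTime
  if (!length(t)) {
    warning("empty photon stream: no bursts")
    return(data.frame(start = numeric(0), stop = numeric(0),
                      duration = numeric(0), NG = integer(0),
                      NR = integer(0), E = numeric(0), tauF = numeric(0)))
  }
  flag <- cpp_burst_flag(t, window, minNeighbors)
  idx <- which(flag)
  if (!length(idx)) {
    warning("no bursts found")
    return(detectBursts(photonStream(numeric(0), integer(0), numeric(0),
                                     stream@microRange)))
  }
  newBurst <- c(TRUE, diff(t[idx]) > window)
  bid <- cumsum(newBurst)
  ch <- stream@channel[idx]
  mt <- stream@microTime[idx]
  tb <- t[idx]
  sp <- split(seq_along(idx), bid)
  rows <- lapply(sp, function(ii) {
    ng <- sum(ch[ii] == 0L); nr <- length(ii) - ng
    if (ng + nr < minPhotons) return(NULL)
    data.frame(start = tb[ii[1]], stop = tb[ii[length(ii)]],
               duration = tb[ii[length(ii)]] - tb[ii[1]],
               NG = ng, NR = nr, E = nr / (ng + nr),
               tauF = if (ng > 0) mean(mt[ii][ch[ii] == 0L]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no bursts above the photon threshold")
    out <- data.frame(start = numeric(0), stop = numeric(0),
                      duration = numeric(0), NG = integer(0),
                      NR = integer(0), E = numeric(0), tauF = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Two-dimensional burst histogram with FRET-line overlays
#'
#' Bins bursts in one of the standard coordinate systems: `"lifetime"`
#' (tauF vs E), `"moment"` (m1 = 1-E vs m2 = (1-E)(1-Etau)) or
#' `"variance"` (E vs Var(E) = (1-E)(E-Etau)).
#'
#' @param bursts burst table from [detectBursts].
#' @param tauD0 donor-only lifetime, ns.
#' @param axes coordinate system.
#' @param nBins bins per axis.
#' @return list with `xMids`, `yMids`, `counts` (matrix), `axes`, and the
#'   axis values `x`, `y` per burst.
#' @export
histogram2d <- function(bursts, tauD0 = 4,
                        axes = c("lifetime", "moment", "variance"),
                        nBins = 41) {
  axes <- match.arg(axes)
  stopifnot(nrow(bursts) > 0)
  Etau <- 1 - bursts$tauF / tauD0
  co <- switch(axes,
    lifetime = list(x = bursts$tauF, y = bursts$E,
                    xlim = c(0, tauD0), ylim = c(0, 1)),
    moment = list(x = 1 - bursts$E, y = (1 - bursts$E) * (1 - Etau),
                  xlim = c(0, 1), ylim = c(0, 1)),
    variance = list(x = bursts$E,
                    y = varianceFromIndicators(bursts$E, pmin(Etau, bursts$E)),
                    xlim = c(0, 1), ylim = c(0, 0.25)))
  bx <- seq(co$xlim[1], co$xlim[2], length.out = nBins + 1)
  by <- seq(co$ylim[1], co$ylim[2], length.out = nBins + 1)
  ix <- cut(co$x, bx, include.lowest = TRUE, labels = FALSE)
  iy <- cut(co$y, by, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(ix) & !is.na(iy)
  cnt <- matrix(0L, nBins, nBins)
  for (i in which(ok)) cnt[ix[i], iy[i]] <- cnt[ix[i], iy[i]] + 1L
  list(xMids = (bx[-1] + bx[-length(bx)]) / 2,
       yMids = (by[-1] + by[-length(by)]) / 2,
       counts = cnt, axes = axes, x = co$x, y = co$y)
}

#' FRET-efficiency histograms for fixed time windows
#'
#' Cuts the stream (or each burst) into consecutive windows of length T,
#' keeps windows with at least `minPhotons` photons, and histograms
#' E = NR/(NG+NR) per window for each requested T.
#'
#' @param stream a [PhotonStream-class].
#' @param windows window lengths, ms.
#' @param minPhotons minimum photons per window.
#' @param bursts optional burst table; when given, windows are cut within
#'   bursts only.
#' @param breaks histogram break points on \[0,1\].
#' @return named list (one element per window length) with `counts`
#'   (histogram), `mids`, `E` (per-window efficiencies), and `F` (photon
#'   counts per window).
#' @export
timeWindowHistograms <- function(stream, windows = c(1, 2, 3),
                                 minPhotons = 20, bursts = NULL,
                                 breaks = seq(0, 1, by = 0.02)) {
  out <- list()
  for (Tw in windows) {
    wins <- cutWindows(stream, Tw, minPhotons, bursts)
    E <- wins$NR / (wins$NG + wins$NR)
    h <- hist(E, breaks = breaks, plot = FALSE)
    out[[sprintf("T=%gms", Tw)]] <-
      list(T = Tw, counts = h$counts, mids = h$mids, E = E,
           F = wins$NG + wins$NR)
  }
  out
}

#' Cut a photon stream into fixed-length windows
#'
#' @inheritParams timeWindowHistograms
#' @param T window length, ms.
#' @return data.frame with NG, NR per retained window.
#' @export
cutWindows <- function(stream, T, minPhotons = 20, bursts = NULL) {
  t <- stream@macroTime; ch <- stream@channel
  if (!is.null(bursts) && nrow(bursts)) {
    res <- list()
    for (b in seq_len(nrow(bursts))) {
      lo <- bursts$start[b]
      nw <- floor((bursts$stop[b] - lo) / T)
      if (nw < 1) next
      sel <- t >= lo & t < lo + nw * T
      w <- floor((t[sel] - lo) / T)
      ng <- tabulate(w + 1L, nbins = nw); dim(ng) <- NULL
      ngG <- vapply(seq_len(nw) - 1L, function(k)
        sum(ch[sel][w == k] == 0L), integer(1))
      nAll <- tabulate(w + 1L, nbins = nw)
      res[[length(res) + 1]] <- data.frame(NG = ngG, NR = nAll - ngG)
    }
    out <- if (length(res)) do.call(rbind, res) else
      data.frame(NG = integer(0), NR = integer(0))
  } else {
    w <- floor(t / T)
    nw <- max(w) + 1L
    nAll <- tabulate(w + 1L, nbins = nw)
    nG <- tabulate(w[ch == 0L] + 1L, nbins = nw)
    out <- data.frame(NG = nG, NR = nAll - nG)
  }
  out[out$NG + out$NR >= minPhotons, , drop = FALSE]
}
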