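#' Configurations of the seven reference simulations
#'
#' Heterogeneous mixtures of static and dynamic FRET species used
#' throughout the package's validation suite. Species efficiencies default
#' to E_LF = 0.2, E_MF = 0.5, E_HF = 0.8 (plus a static MF' species at
#' 0.35 in the all-static mixture), donor-only lifetime 4 ns:
#' \describe{
#'   \item{1}{four static species (LF, MF, MF', HF), t_diff = 5 ms}
#'   \item{2}{three static species plus a dynamic MF = LF exchange with
#'     k = 5/5 1/ms, t_diff = 5 ms}
#'   \item{3}{three static species plus a dynamic HF = LF exchange with
#'     k(HF to LF) = 6.3, k(LF to HF) = 3.7 1/ms, t_diff = 5 ms}
#'   \item{4}{three static species plus a dynamic binary LF = HF exchange
#'     at 5/5 1/ms, t_diff = 3.8 ms}
#'   \item{5, 6, 7}{three static species plus a dynamic species exchanging
#'     over the full linear chains MF = HF = LF, HF = MF = LF and
#'     MF = LF = HF (all rates 5 1/ms), t_diff = 3.8 ms}
#' }
#' The fraction of dynamic molecules defaults to 0.4 and the static
#' background is split evenly.
#'
#' @param which simulation number, 1-7.
#' @param duration simulated time, ms.
#' @param Q0 donor brightness, kHz.
#' @param N mean molecules in the observation volume.
#' @param pd dynamic molecule fraction (ignored for simulation 1).
#' @param boxXY lateral box size in units of w0 (see [simulationConfig]).
#' @return an `fkSimulationConfig` (see [simulationConfig]).
#' @export
fixtureConfig <- function(which, duration = 30000, Q0 = 250, N = 1,
                          pd = 0.4, boxXY = 6) {
  stopifnot(which %in% 1:7)
  E3 <- c(LF = 0.2, MF = 0.5, HF = 0.8)
  chain <- function(a, b, c) {
    # linear chain a = b = c, all rates 5/ms, over species LF, MF, HF
    kineticNetwork(3, data.frame(
      from = c(a, b, b, c), to = c(b, a, c, b), rate = 5),
      labels = names(E3))
  }
  pairNet <- function(i, j, kij, kji) {
    # exchange between species i and j only (reducible over 3 states):
    # k(i<-j) = kij etc., expressed as from/to rows
    kineticNetwork(3, data.frame(from = c(j, i), to = c(i, j),
                                 rate = c(kij, kji)), labels = names(E3))
  }
  xdPair <- function(i, j, kij, kji) {
    xd <- numeric(3)
    xd[i] <- kij / (kij + kji); xd[j] <- 1 - xd[i]
    xd
  }
  if (which == 1) {
    det <- detectionModel(Q0 = Q0, N = N, tdiff = 5)
    return(simulationConfig(c(LF = 0.2, MF = 0.5, MFp = 0.35, HF = 0.8),
                            pd = 0, xs = rep(0.25, 4), det = det,
                            boxXY = boxXY, duration = duration))
  }
  cfg <- switch(as.character(which),
    "2" = list(net = pairNet(2, 1, 5, 5), xd = xdPair(2, 1, 5, 5),
               tdiff = 5),
    "3" = list(net = pairNet(1, 3, 6.3, 3.7), xd = xdPair(1, 3, 6.3, 3.7),
               tdiff = 5),
    "4" = list(net = pairNet(1, 3, 5, 5), xd = xdPair(1, 3, 5, 5),
               tdiff = 3.8),
    "5" = list(net = chain("MF", "HF", "LF"), xd = NULL, tdiff = 3.8),
    "6" = list(net = chain("HF", "MF", "LF"), xd = NULL, tdiff = 3.8),
    "7" = list(net = chain("MF", "LF", "HF"), xd = NULL, tdiff = 3.8))
  det <- detectionModel(Q0 = Q0, N = N, tdiff = cfg$tdiff)
  simulationConfig(E3, net = cfg$net, pd = pd, xs = rep(1 / 3, 3),
                   det = det, boxXY = boxXY, xd = cfg$xd,
                   duration = duration)
}

#' Regenerate a reference simulation on disk
#'
#' Simulates the requested fixture, detects bursts, and writes the photon
#' stream container, burst table and a YAML manifest of all parameters to
#' `dir`. Deterministic under a fixed seed.
#'
#' @param which simulation numbers (subset of 1-7).
#' @param seed integer seed.
#' @param dir output directory.
#' @param ... passed to [fixtureConfig].
#' @return invisibly, the manifest paths.
#' @export
makeFixtures <- function(which = 1:7, seed = 1, dir = tempdir(), ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (w in which) {
    cfg <- fixtureConfig(w, ...)
    stream <- simulateStream(cfg, seed = seed + w)
    bursts <- detectBursts(stream)
    base <- file.path(dir, sprintf("simulation%d", w))
    writePhotonStream(stream, paste0(base, ".photons"),
                      provenance = list(fixture = w, seed = seed + w))
    writeBurstTable(bursts, paste0(base, "_bursts.tsv"))
    man <- list(fixture = w, seed = seed + w,
                E = as.list(cfg$E), pd = cfg$pd,
                xs = as.list(cfg$xs),
                rates_per_ms = if (!is.null(cfg$net)) {
                  K <- rateMatrix(cfg$net)
                  off <- which(K > 0 & row(K) != col(K), arr.ind = TRUE)
                  lapply(seq_len(nrow(off)), function(r)
                    sprintf("%s,%s,%g", cfg$labels[off[r, 2]],
                            cfg$labels[off[r, 1]], K[off[r, 1], off[r, 2]]))
                } else list(),
                tdiff_ms = cfg$det@tdiff, Q0_kHz = cfg$det@Q0,
                tauD0_ns = cfg$tauD0, duration_ms = cfg$duration,
                nMolecules = cfg$nMolecules, dt_ms = cfg$dt,
                nPhotons = nPhotons(stream), nBursts = nrow(bursts))
    mp <- paste0(base, "_manifest.yaml")
    yaml::write_yaml(man, mp)
    out <- c(out, mp)
  }
  invisible(out)
}
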