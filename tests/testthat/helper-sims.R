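## Shared simulated datasets, built once per test run on first use.
.fkTestCache <- new.env(parent = emptyenv())

cachedSim <- function(name, maker) {
  if (!exists(name, envir = .fkTestCache))
    assign(name, maker(), envir = .fkTestCache)
  get(name, envir = .fkTestCache)
}

## bright single static species, E = 0.4
staticStream <- function() cachedSim("staticStream", function() {
  # wide box: diffusion-tail accuracy needs the box to dwarf the
  # diffusion length at the longest fitted lags
  cfg <- simulationConfig(c(0.4), pd = 0, xs = 1,
                          det = detectionModel(Q0 = 300, tdiff = 2, N = 0.5),
                          boxXY = 10, duration = 12000)
  list(cfg = cfg, stream = simulateStream(cfg, seed = 101))
})

## static three-species mixture (no kinetics at all)
staticMixStream <- function() cachedSim("staticMix", function() {
  cfg <- simulationConfig(c(LF = 0.2, MF = 0.5, HF = 0.8), pd = 0,
                          xs = rep(1 / 3, 3),
                          det = detectionModel(Q0 = 300, tdiff = 2, N = 0.5),
                          duration = 10000)
  list(cfg = cfg, stream = simulateStream(cfg, seed = 103))
})

## fast symmetric two-state exchange, pure dynamic
fastTwoStateStream <- function() cachedSim("fastTwoState", function() {
  net <- kineticNetwork(2, data.frame(from = c(1, 2), to = c(2, 1),
                                      rate = 10))
  cfg <- simulationConfig(c(0.2, 0.8), net = net, pd = 1,
                          det = detectionModel(Q0 = 300, tdiff = 1.5, N = 0.5),
                          duration = 8000)
  list(cfg = cfg, stream = simulateStream(cfg, seed = 102))
})

## Simulation-2 analogue at the suite's ideal-SNR settings, with bursts,
## decay and the four color correlation curves (shared by the global-fit,
## PDA, MCMC and degeneracy checks)
sim2Data <- function() cachedSim("sim2Data", function() {
  cfg <- fixtureConfig(2, duration = 80000, Q0 = 600, N = 0.5, boxXY = 10)
  stream <- simulateStream(cfg, seed = 2022)
  bursts <- detectBursts(stream)
  decay <- subensembleDecay(stream, bursts)
  curves <- lapply(c("GG", "GR", "RG", "RR"), function(pr)
    correlateStream(stream, substr(pr, 1, 1), substr(pr, 2, 2),
                    binWidth = 0.002, pair = pr))
  names(curves) <- c("GG", "GR", "RG", "RR")
  list(cfg = cfg, stream = stream, bursts = bursts,
       data = globalData(decay, curves))
})

## Simulation-2 analogue at the standard burst-regime brightness, windowed
## for dynamic PDA (shot-noise-limited photon counts per window)
pdaWindows <- function() cachedSim("pdaWindows", function() {
  cfg <- fixtureConfig(2, duration = 40000)
  stream <- simulateStream(cfg, seed = 2023)
  bursts <- detectBursts(stream)
  tw <- timeWindowHistograms(stream, windows = c(1, 2, 3),
                             minPhotons = 20, bursts = bursts)
  list(cfg = cfg, windows = tw)
})

## filtered-FCS cross-correlations of a reference fixture
ffcsCross <- function(which, seed) {
  cachedSim(paste0("ffcs", which), function() {
    cfg <- fixtureConfig(which, duration = 22000)
    stream <- simulateStream(cfg, seed = seed)
    pat <- speciesPatterns(cfg$E, det = cfg$det, tauD0 = cfg$tauD0,
                           tauA = cfg$tauA, labels = names(cfg$E))
    x <- cfg$pd * cfg$xd + (1 - cfg$pd) * cfg$xs
    fl <- buildFilters(pat, x)
    sc <- speciesCorrelations(stream, fl,
                              pairs = list(c(1, 2), c(1, 3), c(2, 3)),
                              binWidth = 0.002, maxLag = 20)
    list(cfg = cfg, filters = fl, curves = sc)
  })
}
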