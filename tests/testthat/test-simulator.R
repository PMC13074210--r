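test_that("simulation configs validate their stability constraints", {
  net <- kineticNetwork(2, data.frame(from = c(1, 2), to = c(2, 1),
                                      rate = 50))
  # dt must stay below a tenth of the fastest relaxation time (10 us here)
  expect_error(simulationConfig(c(0.2, 0.8), net = net, pd = 1,
                                dt = 0.005, duration = 100), "unstable")
  ok <- simulationConfig(c(0.2, 0.8), net = net, pd = 1, duration = 100)
  expect_lte(ok$dt, 0.001)
  # reducible networks need explicit initial dynamic fractions
  red <- kineticNetwork(3, data.frame(from = c(1, 2), to = c(2, 1),
                                      rate = 5))
  expect_error(simulationConfig(c(0.2, 0.5, 0.8), net = red, pd = 0.5,
                                duration = 100), "xd")
  expect_silent(simulationConfig(c(0.2, 0.5, 0.8), net = red, pd = 0.5,
                                 xd = c(0.5, 0.5, 0), duration = 100))
})

test_that("a fixed seed reproduces the photon stream bit for bit", {
  cfg <- simulationConfig(c(0.4), pd = 0, xs = 1,
                          det = detectionModel(Q0 = 150, tdiff = 2, N = 0.5),
                          duration = 500)
  s1 <- simulateStream(cfg, seed = 9)
  s2 <- simulateStream(cfg, seed = 9)
  expect_identical(s1@macroTime, s2@macroTime)
  expect_identical(s1@channel, s2@channel)
  expect_identical(s1@microTime, s2@microTime)
})

test_that("static single-species streams reproduce their inputs", {
  sim <- staticStream()
  st <- sim$stream
  # channel split: red fraction equals E
  expect_equal(mean(st@channel == 1L), 0.4, tolerance = 0.01)
  bursts <- detectBursts(st)
  expect_equal(mean(bursts$E), 0.4, tolerance = 0.02)
  # recovered diffusion time within 10 percent
  gg <- correlateStream(st, "G", "G")
  f <- fitFcsCurve(gg, nRelaxations = 0, tdiff0 = 2)
  expect_equal(f$tdiff, sim$cfg$det@tdiff, tolerance = 0.1)
  # burst population sits on the static FRET-line
  Etau <- 1 - bursts$tauF / 4
  expect_lt(abs(median(bursts$E - Etau)), 0.03)
})

test_that("fast two-state exchange collapses onto a shifted population", {
  sim <- fastTwoStateStream()
  bursts <- detectBursts(sim$stream)
  expect_gt(nrow(bursts), 50)
  expect_equal(mean(bursts$E), 0.5, tolerance = 0.03)
  # single population shifted off the static line at x = 0.5
  ds <- (bursts$E - (1 - bursts$tauF / 4)) / 2
  expect_gt(median(ds, na.rm = TRUE), 0.05)
  # expected shift at x = 0.5 is 0.09 for the 0.2/0.8 pair
  expect_equal(median(ds, na.rm = TRUE), 0.09, tolerance = 0.25)
  h <- histogram2d(bursts, tauD0 = 4)
  # essentially all bursts fall inside the histogram range
  expect_gte(sum(h$counts), 0.98 * nrow(bursts))
  expect_lte(sum(h$counts), nrow(bursts))
})

test_that("burst search honours its thresholds and degenerate inputs", {
  empty <- photonStream(numeric(0), integer(0), numeric(0))
  expect_warning(b <- detectBursts(empty), "empty|no bursts")
  expect_equal(nrow(b), 0)
  sim <- staticStream()
  b1 <- detectBursts(sim$stream, minPhotons = 60)
  b2 <- detectBursts(sim$stream, minPhotons = 120)
  expect_gt(nrow(b1), nrow(b2))
  expect_true(all(b1$NG + b1$NR >= 60))
  expect_true(all(b1$E >= 0 & b1$E <= 1))
})

test_that("mean burst efficiency matches the mixture expectation", {
  sim <- sim2Data()
  # expected mean E from the REALIZED molecule allocation (largest
  # remainder over a finite molecule count)
  nMol <- sim$cfg$nMolecules
  nDyn <- as.integer(round(sim$cfg$pd * nMol))
  dynStates <- fretKinetics:::.allocate(nDyn, sim$cfg$xd)
  statStates <- fretKinetics:::.allocate(nMol - nDyn, sim$cfg$xs)
  E <- sim$cfg$E
  expE <- (sum(dynStates * c(0.35, 0.35, 0.35)) +   # dynamic pair mean
           sum(statStates * E)) / nMol
  b <- sim$bursts
  se <- sd(b$E) / sqrt(nrow(b))
  expect_lt(abs(mean(b$E) - expE), 3 * se + 0.01)
})

test_that("time-window histograms narrow with photon count", {
  sim <- staticStream()
  tw <- timeWindowHistograms(sim$stream, windows = c(0.5, 2),
                             minPhotons = 15)
  w1 <- tw[[1]]; w2 <- tw[[2]]
  # widths shrink as 1 / sqrt(mean photons per window)
  ratio <- sd(w1$E) / sd(w2$E)
  expected <- sqrt(mean(w2$F) / mean(w1$F))
  expect_equal(ratio, expected, tolerance = 0.25)
  # shot-noise width at the longer window
  expect_equal(sd(w2$E), sqrt(0.4 * 0.6 / mean(w2$F)), tolerance = 0.3)
})

test_that("window cutting respects burst boundaries and totals", {
  sim <- staticStream()
  bursts <- detectBursts(sim$stream)
  w <- cutWindows(sim$stream, T = 0.5, minPhotons = 10, bursts = bursts)
  expect_true(all(w$NG + w$NR >= 10))
  expect_lte(sum(w$NG + w$NR), sum(bursts$NG + bursts$NR))
  wAll <- cutWindows(sim$stream, T = 1, minPhotons = 0)
  expect_equal(sum(wAll$NG + wAll$NR), nPhotons(sim$stream))
})
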