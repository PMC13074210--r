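refTwoState <- function(k12 = 3, k21 = 1, pd = 0.6, xs = c(0.5, 0.5)) {
  mixtureModel(kineticNetwork(2, data.frame(from = c(2, 1), to = c(1, 2),
                                            rate = c(k12, k21))),
               pd = pd, xs = xs)
}

test_that("diffusion factor follows the 3D Gaussian form", {
  expect_equal(diffusionTerm(0, 5), 1)
  expect_equal(diffusionTerm(5, 5, s = 0.25), 0.5 * 1.0625^-0.5,
               tolerance = 1e-12)
  g <- diffusionTerm(multiTauGrid(), 5)
  expect_true(all(diff(g) < 0))
})

test_that("mixture fractions combine dynamic and static parts", {
  mm <- refTwoState()
  expect_equal(unname(totalFractions(mm)),
               0.6 * c(0.75, 0.25) + 0.4 * c(0.5, 0.5))
  expect_equal(sum(totalFractions(mm)), 1)
  expect_error(mixtureModel(kineticNetwork(2), pd = 1.2), "pd")
})

test_that("kinetic correlation agrees between its two evaluation paths", {
  tc <- multiTauGrid(1e-4, 20)
  det <- detectionModel()
  # two-state mixtures and three-state detailed-balance networks
  set.seed(41)
  for (r in 1:10) {
    n <- sample(2:3, 1)
    net <- if (n == 2)
      kineticNetwork(2, data.frame(from = c(2, 1), to = c(1, 2),
                                   rate = runif(2, 0.5, 8)))
    else randomDetailedBalanceNetwork(3)
    xs <- runif(n); xs <- xs / sum(xs)
    mm <- mixtureModel(net, pd = runif(1), xs = xs)
    E <- sort(runif(n, 0.05, 0.95))
    sv <- signalVectors(det, E)
    for (pair in list(c("G", "G"), c("G", "R"), c("R", "R"))) {
      g1 <- kineticCorrelation(mm, sv[[pair[1]]], sv[[pair[2]]], tc,
                               method = "spectral")
      g2 <- kineticCorrelation(mm, sv[[pair[1]]], sv[[pair[2]]], tc,
                               method = "matrix")
      expect_lt(max(abs(g1 - g2)), 1e-10)
    }
  }
})

test_that("two-state closed form matches the matrix path exactly", {
  tc <- multiTauGrid(1e-4, 50)
  det <- detectionModel()
  sv <- signalVectors(det, c(0.8, 0.2))
  mm <- refTwoState()
  for (pair in list(c("G", "G"), c("G", "R"), c("R", "R"))) {
    g <- kineticCorrelation(mm, sv[[pair[1]]], sv[[pair[2]]], tc)
    gc <- twoStateKineticCorrelation(mm, sv[[pair[1]]], sv[[pair[2]]], tc)
    expect_lt(max(abs(g - gc)), 1e-12)
  }
  # pure static mixture: no decay, constant 1 + A0
  mm0 <- mixtureModel(kineticNetwork(2), pd = 0, xs = c(0.3, 0.7))
  g0 <- kineticCorrelation(mm0, sv$G, sv$G, tc, method = "matrix")
  expect_equal(diff(range(g0)), 0, tolerance = 1e-12)
})

test_that("contrast factors reproduce the closed-form two-state values", {
  det <- detectionModel()
  sv <- signalVectors(det, c(0.8, 0.2))
  x <- c(0.5, 0.5)
  expect_equal(contrastFactors(sv$G, sv$G, x)[1, 2], 1.44)
  expect_equal(contrastFactors(sv$R, sv$R, x)[1, 2], 1.44)
  expect_equal(contrastFactors(sv$G, sv$R, x)[1, 2], -1.44)
  # identical species: zero contrast
  svE <- signalVectors(det, c(0.5, 0.5))
  expect_equal(contrastFactors(svE$G, svE$G, x)[1, 2], 0)
  # cross amplitude carries no independent information
  set.seed(42)
  for (r in 1:20) {
    E <- runif(2, 0.05, 0.95)
    xr <- runif(1, 0.1, 0.9); xr <- c(xr, 1 - xr)
    sv <- signalVectors(det, E)
    dgg <- contrastFactors(sv$G, sv$G, xr)[1, 2]
    drr <- contrastFactors(sv$R, sv$R, xr)[1, 2]
    dgr <- contrastFactors(sv$G, sv$R, xr)[1, 2]
    expect_equal(dgr, -sqrt(dgg * drr), tolerance = 1e-12)
  }
})

test_that("relaxation structure of the kinetic amplitudes is n - 1 terms", {
  det <- detectionModel()
  # two-state pure dynamic: single exponential at rate k12 + k21
  net <- kineticNetwork(2, data.frame(from = c(2, 1), to = c(1, 2),
                                      rate = c(3.3, 1.7)))
  mm <- mixtureModel(net, pd = 1, xs = c(0.5, 0.5))
  sv <- signalVectors(det, c(0.8, 0.2))
  amp <- kineticAmplitudes(mm, sv$G, sv$R)
  expect_length(amp$A, 1)
  expect_equal(-amp$lambda, 5, tolerance = 1e-9)
  expect_equal(amp$A0, 0, tolerance = 1e-12)   # no static residual
  # three-state symmetric chain: relaxation times 66.7 and 200 us
  chain <- kineticNetwork(3, data.frame(
    from = c("MF", "LF", "LF", "HF"), to = c("LF", "MF", "HF", "LF"),
    rate = 5), labels = c("MF", "LF", "HF"))
  mm3 <- mixtureModel(chain, pd = 1, xs = rep(1 / 3, 3))
  sv3 <- signalVectors(det, c(0.5, 0.2, 0.8))
  amp3 <- kineticAmplitudes(mm3, sv3$G, sv3$R)
  expect_equal(sort(amp3$tR), c(1 / 15, 0.2), tolerance = 1e-10)
})

test_that("full color-FCS curves normalize and anti-correlate", {
  det <- detectionModel(tdiff = 5, N = 1)
  net <- kineticNetwork(2, data.frame(from = c(1, 2), to = c(2, 1),
                                      rate = 5))
  mm <- mixtureModel(net, pd = 1, xs = c(0.5, 0.5))
  tc <- c(multiTauGrid(1e-4, 100), 1e5)   # one far point for the limit
  gr <- colorFcsCurve(mm, det, "GR", E = c(0.2, 0.8), tc = tc)
  expect_s4_class(gr, "CorrelationCurve")
  expect_equal(corrValues(gr)[length(tc)], 1, tolerance = 1e-3)
  # cross correlation dips below its long-time plateau at short lags
  plateauIdx <- which(tc > 1 & tc < 2)
  expect_lt(corrValues(gr)[1], mean(corrValues(gr)[plateauIdx]))
  # single species: pure diffusion
  mm1 <- mixtureModel(kineticNetwork(1), pd = 0, xs = 1)
  g1 <- colorFcsCurve(mm1, det, "GG", E = 0.4, tc = tc)
  expect_equal(corrValues(g1), 1 + diffusionTerm(tc, 5) / 1,
               tolerance = 1e-12)
  # dual-path agreement on the full curve
  gr2 <- colorFcsCurve(mm, det, "GR", E = c(0.2, 0.8), tc = tc,
                       method = "matrix")
  expect_lt(max(abs(corrValues(gr) - corrValues(gr2))), 1e-10)
})

test_that("correlation amplitudes derive from the burst indicators", {
  a <- amplitudesFromIndicators(0.5, 0.32)
  expect_equal(a$GG, 0.36)
  expect_equal(a$RR, 0.36)
  expect_equal(a$GR, -0.36)
  expect_equal(a$GR^2, a$GG * a$RR, tolerance = 1e-12)
  a0 <- amplitudesFromIndicators(0.4, 0.4)
  expect_equal(unlist(a0), c(GG = 0, RR = 0, GR = 0))
  expect_error(amplitudesFromIndicators(1, 0.5), "strictly")
  set.seed(43)
  for (r in 1:20) {
    E <- runif(1, 0.1, 0.9); Etau <- E - runif(1, 0, 0.2)
    a <- amplitudesFromIndicators(E, max(Etau, 0.01))
    expect_equal(a$GR^2, a$GG * a$RR, tolerance = 1e-12)
  }
})

test_that("the (pd, k12) manifold leaves the model curves unchanged", {
  det <- detectionModel(tdiff = 5, N = 1)
  tc <- multiTauGrid(1e-4, 20)
  E <- c(0.2, 0.8)
  # reference microscopic parameters
  k12 <- 5; k21 <- 5; pd <- 0.4; tR <- 1 / (k12 + k21)
  xd1 <- k12 / (k12 + k21)
  amp <- pd * xd1 * (1 - xd1)
  ref <- refTwoState(k12, k21, pd = pd, xs = c(0.5, 0.5))
  xTotal <- unname(totalFractions(ref))
  man <- ambiguityManifold(tR, amp, xTotal)
  man <- man[man$physical, ]
  expect_gt(nrow(man), 5)
  gRef <- lapply(c("GG", "GR", "RR"), function(p)
    corrValues(colorFcsCurve(ref, det, p, E = E, tc = tc)))
  for (r in seq(1, nrow(man), by = 4)) {
    xsAlt <- pmax(c(man$xs1[r], man$xs2[r]), 0)
    alt <- refTwoState(man$k12[r], man$k21[r], pd = man$pd[r],
                       xs = xsAlt / sum(xsAlt))
    expect_equal(unname(totalFractions(alt)), xTotal, tolerance = 1e-10)
    gAlt <- lapply(c("GG", "GR", "RR"), function(p)
      corrValues(colorFcsCurve(alt, det, p, E = E, tc = tc)))
    for (i in 1:3) expect_lt(max(abs(gRef[[i]] - gAlt[[i]])), 1e-10)
  }
})
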