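## noise-free synthetic dataset built directly from the model functions
syntheticGlobalData <- function(theta, dynPair = c(2, 1), n = 3,
                                sigmaG = 1e-4) {
  t <- microTimeGrid(25, 256)
  net <- kineticNetwork(2, data.frame(from = c(2, 1), to = c(1, 2),
                                      rate = c(theta$k12, theta$k21)))
  xd2 <- equilibriumFractions(net)
  xd <- numeric(n); xd[dynPair] <- xd2
  x <- theta$pd * xd + (1 - theta$pd) * theta$xs
  m <- decayModel(x, theta$E, theta$tauD0, t)
  decay <- decayHistogram(t, m * (1e7 / sum(m)))
  det <- detectionModel(tdiff = theta$tdiff, N = theta$N)
  tc <- multiTauGrid(1e-3, 50)
  # mixture over the pair subspace plus frozen statics outside it
  curves <- lapply(c("GG", "GR", "RG", "RR"), function(pr) {
    sv <- signalVectors(det, theta$E)
    Sa <- sv[[substr(pr, 1, 1)]]; Sb <- sv[[substr(pr, 2, 2)]]
    Sbar <- c(sum(Sa * x), sum(Sb * x))
    es <- eigenDecompose(net)
    A0 <- drop(theta$pd * (Sa[dynPair] %*% xd2) * (Sb[dynPair] %*% xd2) +
               (1 - theta$pd) * sum(Sa * Sb * theta$xs)) /
      prod(Sbar) - 1
    G1 <- theta$pd * (es@projectors[[2]] %*% diag(xd2, 2))
    A1 <- drop(Sa[dynPair] %*% G1 %*% Sb[dynPair]) / prod(Sbar)
    Gk <- 1 + A0 + A1 * exp(es@eigenvalues[2] * tc)
    correlationCurve(tc, 1 + diffusionTerm(tc, theta$tdiff, 0.25) *
                       Gk / theta$N,
                     sigma = rep(sigmaG, length(tc)), pair = pr)
  })
  names(curves) <- c("GG", "GR", "RG", "RR")
  globalData(decay, curves)
}

thTrue <- list(E = c(0.2, 0.5, 0.8), k12 = 5, k21 = 5,
               xs = rep(1 / 3, 3), pd = 0.4, tdiff = 5, N = 1, tauD0 = 4)

test_that("the global chi-square decomposes and vanishes at the truth", {
  gd <- syntheticGlobalData(thTrue)
  c2 <- chi2Global(thTrue, gd, dynPair = c(2, 1))
  expect_equal(as.numeric(c2),
               attr(c2, "chi2TCSPC") + attr(c2, "chi2FCS"))
  expect_lt(as.numeric(c2), 1e-10)
  # perturbing an efficiency strictly increases chi2
  thP <- thTrue; thP$E[1] <- thP$E[1] + 0.05
  expect_gt(as.numeric(chi2Global(thP, gd, dynPair = c(2, 1))), 1)
})

test_that("omitting the FCS block removes sensitivity along the manifold", {
  gd <- syntheticGlobalData(thTrue)
  # two points on the (pd, k12) manifold share x_total: TCSPC cannot tell
  # them apart while the full chi2 stays flat as well (model identity)
  # total fraction of each exchanging species: 0.4 * 0.5 + 0.6 / 3 = 0.4
  man <- ambiguityManifold(0.1, 0.4 * 0.25, c(0.4, 0.4))
  man <- man[man$physical & abs(man$k12 - 5) > 1, ]
  alt <- thTrue
  alt$k12 <- man$k12[1]; alt$k21 <- man$k21[1]; alt$pd <- man$pd[1]
  # manifold state 1 is the dynPair[1] species (MF); species order LF,MF,HF
  alt$xs <- c(man$xs2[1], man$xs1[1],
              1 - man$xs1[1] - man$xs2[1])
  cT <- attr(chi2Global(thTrue, gd, c(2, 1)), "chi2TCSPC")
  cA <- attr(chi2Global(alt, gd, c(2, 1)), "chi2TCSPC")
  expect_lt(abs(cT - cA), 1e-8)
  expect_lt(as.numeric(chi2Global(alt, gd, c(2, 1))), 1e-8)
})

test_that("the global fit recovers parameters from clean synthetic data", {
  gd <- syntheticGlobalData(thTrue)
  init <- thTrue
  init$k12 <- 3; init$k21 <- 7; init$E <- c(0.25, 0.45, 0.75)
  set.seed(61)
  fit <- fitGlobal(gd, dynPair = c(2, 1), init, fix = c("pd"), nStarts = 4)
  expect_equal(fit$theta$E, thTrue$E, tolerance = 0.01)
  expect_equal(fit$theta$k12 + fit$theta$k21, 10, tolerance = 0.02)
  expect_lt(fit$chi2r, 0.01)
})

test_that("scheme enumeration and labels cover the permutations", {
  sch <- enumerateSchemes(3, c("LF", "MF", "HF"))
  expect_length(sch, 3)
  expect_setequal(vapply(sch, `[[`, character(1), "label"),
                  c("HF,LF<->MF", "MF,LF<->HF", "LF,MF<->HF"))
})

test_that("external estimates resolve the rate ambiguity", {
  # symmetric case: tR = 100 us and known pd give k12 = k21 = 5
  r <- resolveWithPd(tR = 0.1, amp = 0.4 * 0.25, pd = 0.4)
  expect_equal(nrow(r), 1)
  expect_equal(r$k12, 5)
  expect_equal(r$k21, 5)
  # asymmetric truth 6.3 / 3.7 via the dynamic fraction
  tR <- 1 / 10; xd1 <- 6.3 / 10; pdT <- 0.35
  r2 <- resolveWithPd(tR = tR, amp = pdT * xd1 * (1 - xd1), xd1 = xd1)
  expect_equal(r2$k12, 6.3, tolerance = 1e-12)
  expect_equal(r2$k21, 3.7, tolerance = 1e-12)
  expect_equal(r2$pd, pdT, tolerance = 1e-12)
  # known pd but amplitude too large for any xd1: inconsistent
  expect_error(resolveWithPd(tR = 0.1, amp = 0.3, pd = 0.4), "inconsistent")
})

test_that("MCMC sampling is reproducible and respects bounds", {
  gd <- syntheticGlobalData(thTrue, sigmaG = 5e-3)
  m1 <- mcmcSample(gd, c(2, 1), thTrue, nWalkers = 8, nSteps = 12,
                   burnIn = 0.5, seed = 3)
  m2 <- mcmcSample(gd, c(2, 1), thTrue, nWalkers = 8, nSteps = 12,
                   burnIn = 0.5, seed = 3)
  expect_identical(m1$samples, m2$samples)
  expect_true(all(m1$samples$pd >= 0 & m1$samples$pd <= 1))
  expect_true(all(m1$samples$k12 > 0))
})
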