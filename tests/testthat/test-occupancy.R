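test_that("occupancy distribution is normalized across regimes", {
  set.seed(31)
  for (i in 1:50) {
    k <- 10^runif(2, -1, 1.7)
    kT <- 10^runif(1, -2, 3)
    T <- kT / sum(k)
    occ <- occupancyDistribution(k[1], k[2], T)
    mass <- occ@w1 + occ@w0 + sum(occ@xi) / length(occ@x)
    expect_equal(mass, 1, tolerance = 1e-5)
    expect_true(all(occ@xi >= 0))
  }
})

test_that("delta weights and mean follow the two-state formulas", {
  occ <- occupancyDistribution(3, 1, 2)
  expect_equal(occ@w1, 0.75 * exp(-2))
  expect_equal(occ@w0, 0.25 * exp(-6))
  h <- 1 / length(occ@x)
  m <- occ@w1 + sum(occ@x * occ@xi) * h
  expect_equal(m, 0.75, tolerance = 1e-5)   # mean independent of T
  # no-transition limit: deltas carry the equilibrium weights
  occ0 <- occupancyDistribution(1.5, 0.5, 1e-4)
  expect_equal(occ0@w1, 0.75, tolerance = 1e-3)
  expect_lt(sum(occ0@xi) / length(occ0@x), 1e-3)
})

test_that("the dynamic density peaks at the equilibrium fraction for long windows", {
  occ <- occupancyDistribution(3, 1, 100)
  # mode approaches 0.75 for long windows (exact: 0.7519 at kT = 400,
  # which the inversion map pulls back onto 0.75)
  expect_equal(occupancyMode(occ), 0.75, tolerance = 0.005)
  expect_equal(unname(invertMode(occupancyMode(occ), 4, 100)), 0.75,
               tolerance = 1e-3)
  # unimodality for kT > 2
  set.seed(32)
  for (i in 1:10) {
    k <- runif(2, 0.5, 5)
    T <- runif(1, 3, 50) / sum(k)
    occ <- occupancyDistribution(k[1], k[2], T)
    d <- diff(occ@xi)
    # single sign change of the derivative
    expect_lte(sum(diff(sign(d[abs(d) > 1e-12])) != 0), 1)
  }
})

test_that("occupancy density matches a Gillespie trajectory histogram", {
  k12 <- 3; k21 <- 1; T <- 2
  g <- gillespieOccupancy2(k12, k21, T, n = 4e4, seed = 33)
  x1 <- g$x1[g$switched]
  occ <- occupancyDistribution(k12, k21, T)
  br <- seq(0, 1, by = 0.05)
  h <- hist(x1, breaks = br, plot = FALSE)
  # expected bin mass from the analytic density, conditioned on switching
  bin <- cut(occ@x, br, labels = FALSE)
  pxi <- tapply(occ@xi, bin, sum) / length(occ@x)
  pxi <- pxi / sum(pxi)
  ex <- pxi * length(x1)
  keep <- ex > 5
  chi2 <- sum((h$counts[keep] - ex[keep])^2 / ex[keep])
  p <- pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("efficiency distribution preserves the equilibrium mean", {
  for (T in c(0.25, 2, 10, 100)) {
    occ <- occupancyDistribution(3, 1, T)
    ed <- efficiencyDistribution(occ, 0.8, 0.2)
    expect_equal(ed$meanE, 0.65, tolerance = 2e-5)
  }
  # T -> 0: two deltas at the species efficiencies with equilibrium weights
  occ0 <- occupancyDistribution(3, 1, 1e-4)
  ed0 <- efficiencyDistribution(occ0, 0.8, 0.2)
  expect_equal(ed0$deltas$weight, c(0.75, 0.25), tolerance = 1e-3)
  # T -> infinity: variance of the full distribution vanishes
  occI <- occupancyDistribution(3, 1, 500)
  edI <- efficiencyDistribution(occI, 0.8, 0.2)
  h <- 1 / length(occI@x)
  v <- sum((edI$E - 0.65)^2 * edI$density * abs(0.8 - 0.2)) * h +
    sum((edI$deltas$E - 0.65)^2 * edI$deltas$weight)
  expect_lt(v, 1e-3)
  expect_error(efficiencyDistribution(occ0, 0.5, 0.5), "differ")
})

test_that("mode inversion recovers the equilibrium fraction", {
  # limiting fraction: 1/2 at kT -> 0, decreasing in kT
  expect_equal(xdLim(1e-6), 0.5, tolerance = 1e-4)
  kTs <- 10^seq(-2, 3, length.out = 40)
  xl <- xdLim(kTs)
  expect_true(all(diff(xl) < 0))
  expect_true(all(xl <= 0.5 + 1e-12 & xl > 0))
  expect_error(xdLim(0), "kT")
  # long-window regime: kT = 400
  expect_equal(invertMode(0.75, 4, 100), 0.75, tolerance = 0.01)
  # round trip: mode of the density inverted back to x_d
  for (T in c(2, 10)) {
    occ <- occupancyDistribution(3, 1, T)
    xd <- invertMode(occupancyMode(occ), 4, T)
    expect_equal(unname(xd), 0.75, tolerance = 0.03)
  }
})

test_that("the modal efficiency maps linearly to the modal occupancy", {
  expect_equal(modeFromEfficiency(0.65, 0.8, 0.2), 0.75)
  expect_equal(modeFromEfficiency(0.2, 0.8, 0.2), 0)
  expect_warning(xm <- modeFromEfficiency(0.9, 0.8, 0.2), "clamp")
  expect_equal(xm, 1)
  # argmax of the efficiency distribution reproduces the density mode
  occ <- occupancyDistribution(3, 1, 5)
  ed <- efficiencyDistribution(occ, 0.8, 0.2)
  Em <- ed$E[which.max(ed$density)]
  expect_equal(modeFromEfficiency(Em, 0.8, 0.2), occupancyMode(occ),
               tolerance = 2 / length(occ@x))
})
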