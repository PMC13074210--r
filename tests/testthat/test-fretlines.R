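test_that("static FRET-line runs from (tauD0, 0) to (0, 1)", {
  ln <- staticFretLine(4)
  expect_equal(ln$E[ln$tauF == 4], 0)
  expect_equal(ln$E[ln$tauF == 0], 1)
  # every point on the line has zero indicator variance
  expect_equal(varianceFromIndicators(ln$E, 1 - ln$tauF / 4),
               rep(0, nrow(ln)))
})

test_that("dynamic FRET-line interpolates species moments", {
  ln <- dynamicFretLine(0.8, 0.2, 4, x = c(0, 0.5, 1))
  # endpoints are the pure species on the static line
  expect_equal(ln$tauF[ln$x == 0], 3.2)
  expect_equal(ln$E[ln$x == 0], 0.2)
  expect_equal(ln$tauF[ln$x == 1], 0.8)
  expect_equal(ln$E[ln$x == 1], 0.8)
  # 50/50 point: intensity-weighted lifetime is the moment ratio
  expect_equal(ln$E[ln$x == 0.5], 0.5)
  expect_equal(ln$tauF[ln$x == 0.5], 2.72)
  # straight line in moment coordinates
  full <- dynamicFretLine(0.7, 0.15, 4)
  fitLin <- lm(m2 ~ m1, data = full)
  expect_lt(max(abs(residuals(fitLin))), 1e-12)
  expect_error(dynamicFretLine(0.5, 0.5, 4), "differ")
})

test_that("dynamic line never crosses below the static line", {
  set.seed(21)
  for (i in 1:20) {
    E <- sort(runif(2, 0, 0.95))
    ln <- dynamicFretLine(E[2], E[1], 4)
    expect_true(all(ln$E >= 1 - ln$tauF / 4 - 1e-12))
  }
})

test_that("dynamic shift matches its closed-form maximum", {
  # worked example: E = 0.8 / 0.2
  ms <- maxDynamicShift(0.8, 0.2)
  expect_equal(ms$xMax, 2 / 3, tolerance = 1e-12)
  expect_equal(ms$dsMax, 0.1, tolerance = 1e-12)
  expect_equal(dynamicShift(ms$xMax, 0.8, 0.2), 0.1, tolerance = 1e-12)
  expect_equal(dynamicShift(0, 0.8, 0.2), 0)
  expect_equal(dynamicShift(1, 0.8, 0.2), 0)
  expect_equal(maxDynamicShift(0.4, 0.4)$dsMax, 0)
  # brute-force grid maximization oracle on random pairs
  set.seed(22)
  xg <- seq(0, 1, length.out = 20001)
  for (i in 1:50) {
    E <- runif(2, 0, 0.95)
    if (abs(E[1] - E[2]) < 0.05) next
    ds <- dynamicShift(xg, E[1], E[2])
    ms <- maxDynamicShift(E[1], E[2])
    expect_equal(max(ds), ms$dsMax, tolerance = 1e-8)
    expect_equal(xg[which.max(ds)], ms$xMax, tolerance = 1e-4)
  }
})

test_that("dynamic shift equals half the offset above the static line", {
  # ds(x) = (E - Etau)/2 identically: the unique reading of the shift
  # formula consistent with its closed-form maximum
  x <- seq(0.01, 0.99, length.out = 101)
  for (E in list(c(0.8, 0.2), c(0.6, 0.1), c(0.95, 0.4))) {
    ln <- dynamicFretLine(E[1], E[2], 4, x = x)
    expect_equal(ln$ds, (ln$E - ln$Etau) / 2, tolerance = 1e-12)
  }
})

test_that("indicator variance equals the population variance", {
  # static species
  expect_equal(varianceFromIndicators(0.3, 0.3), 0)
  # worked binary example: x = 0.5, E in {0.2, 0.8}
  expect_equal(varianceFromIndicators(0.5, 1 - 2.72 / 4), 0.09,
               tolerance = 1e-12)
  expect_equal(0.5 * 0.5 * (0.8 - 0.2)^2, 0.09)
  # three equal-weight species
  E3 <- c(0.2, 0.5, 0.8); w <- rep(1 / 3, 3); tauD0 <- 4
  tau <- tauD0 * (1 - E3)
  tauF <- sum(w * tau^2) / sum(w * tau)
  v <- varianceFromIndicators(sum(w * E3), 1 - tauF / tauD0)
  expect_equal(v, sum(w * E3^2) - sum(w * E3)^2, tolerance = 1e-12)
  expect_equal(v, 0.06, tolerance = 1e-12)
  # N = 2..5 random mixtures
  set.seed(23)
  for (n in 2:5) for (r in 1:10) {
    E <- runif(n, 0, 0.95)
    w <- runif(n); w <- w / sum(w)
    tau <- tauD0 * (1 - E)
    tauF <- sum(w * tau^2) / sum(w * tau)
    expect_equal(varianceFromIndicators(sum(w * E), 1 - tauF / tauD0),
                 sum(w * E^2) - sum(w * E)^2, tolerance = 1e-12)
  }
  # unphysical pair flagged but returned
  expect_warning(v <- varianceFromIndicators(0.3, 0.5), "unphysical")
  expect_equal(v, (1 - 0.3) * (0.3 - 0.5))
})

test_that("fretIndicators derives the lifetime-based efficiency", {
  ind <- fretIndicators(0.5, 2.72, 4)
  expect_equal(ind$Etau, 0.32)
  expect_warning(fretIndicators(0.5, 5, 4), "tauF")
})
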