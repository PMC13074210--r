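test_that("rate matrices obey the column-sum and sign conventions", {
  net <- kineticNetwork(2, data.frame(from = c(1, 2), to = c(2, 1),
                                      rate = 5))
  expect_equal(rateMatrix(net), matrix(c(-5, 5, 5, -5), 2,
               dimnames = list(c("S1", "S2"), c("S1", "S2"))))
  # three-state chain with LF in the middle
  net3 <- kineticNetwork(3, data.frame(
    from = c("MF", "LF", "LF", "HF"), to = c("LF", "MF", "HF", "LF"),
    rate = 5), labels = c("MF", "LF", "HF"))
  K <- unname(rateMatrix(net3))
  expect_equal(K, matrix(c(-5, 5, 0, 5, -10, 5, 0, 5, -5), 3))
  # no rates: fully static, all eigenvalues zero
  net0 <- kineticNetwork(3)
  expect_equal(rateMatrix(net0), matrix(0, 3, 3,
               dimnames = list(paste0("S", 1:3), paste0("S", 1:3))))
  expect_error(kineticNetwork(2, data.frame(from = 1, to = 2, rate = -1)),
               "rates")
  expect_error(kineticNetwork(2, data.frame(from = 1, to = 1, rate = 2)),
               "[Ss]elf")
  expect_error(kineticNetwork(2, data.frame(from = 1, to = 5, rate = 2)),
               "range")
  set.seed(4)
  for (i in 1:20) {
    net <- randomDetailedBalanceNetwork(3)
    expect_lt(max(abs(colSums(rateMatrix(net)))),
              1e-12 * max(abs(rateMatrix(net))))
  }
})

test_that("equilibrium fractions solve K x = 0 and match a Gillespie CTMC", {
  net <- kineticNetwork(2, data.frame(from = c(2, 1), to = c(1, 2),
                                      rate = c(3, 1)))
  expect_equal(unname(equilibriumFractions(net)), c(0.75, 0.25))
  chain <- kineticNetwork(3, data.frame(
    from = c(1, 2, 2, 3), to = c(2, 1, 3, 2), rate = 5))
  expect_equal(unname(equilibriumFractions(chain)), rep(1 / 3, 3))
  # random detailed-balance network vs a 1e6-jump Gillespie trajectory
  set.seed(7)
  net3 <- randomDetailedBalanceNetwork(3)
  xg <- gillespieEquilibrium(rateMatrix(net3), nJumps = 1e6, seed = 8)
  expect_lt(max(abs(unname(equilibriumFractions(net3)) - as.numeric(xg))),
            0.005)
  # reducible network errors and names the disconnected states
  red <- kineticNetwork(3, data.frame(from = 1, to = 2, rate = 2),
                        labels = c("A", "B", "C"))
  expect_error(equilibriumFractions(red), "C")
})

test_that("equilibrium constant equals the rate ratio for two states", {
  net <- kineticNetwork(2, data.frame(from = c(2, 1), to = c(1, 2),
                                      rate = c(3, 1)))
  expect_equal(equilibriumConstant(net), 1 / 3)
  sym <- kineticNetwork(2, data.frame(from = c(1, 2), to = c(2, 1),
                                      rate = 4))
  expect_equal(equilibriumConstant(sym), 1)
  x <- equilibriumFractions(net)
  expect_equal(unname(x[2] / x[1]), equilibriumConstant(net),
               tolerance = 1e-12)
  expect_error(equilibriumConstant(kineticNetwork(3)), "2 states")
})

test_that("mean efficiency is the fraction-weighted average", {
  expect_equal(meanEfficiency(c(0.75, 0.25), c(0.8, 0.2)), 0.65)
  expect_equal(meanEfficiency(c(1, 0), c(0.8, 0.2)), 0.8)
  expect_equal(meanEfficiency(c(2, 1) / 3, c(0.8, 0.2)), 0.6)
  expect_error(meanEfficiency(c(0.5, 0.5), c(0.1, 0.2, 0.3)), "mismatch")
  expect_error(meanEfficiency(c(0.5, 0.4), c(0.1, 0.2)), "sum")
})

test_that("eigen-decomposition yields the reference relaxation times", {
  sym <- kineticNetwork(2, data.frame(from = c(1, 2), to = c(2, 1),
                                      rate = 5))
  es <- eigenDecompose(sym)
  expect_equal(es@eigenvalues, c(0, -10))
  expect_equal(es@relaxationTimes, 0.1)       # 100 us
  chain <- kineticNetwork(3, data.frame(
    from = c("MF", "LF", "LF", "HF"), to = c("LF", "MF", "HF", "LF"),
    rate = 5), labels = c("MF", "LF", "HF"))
  es3 <- eigenDecompose(chain)
  expect_equal(sort(es3@eigenvalues), c(-15, -5, 0))
  expect_equal(sort(es3@relaxationTimes), c(1 / 15, 0.2), tolerance = 1e-12)
  # n - 1 relaxation times for irreducible networks
  expect_length(es3@relaxationTimes, 2)
})

test_that("spectral projectors reconstruct the matrix exponential", {
  set.seed(11)
  for (i in 1:30) {
    net <- randomDetailedBalanceNetwork(3)
    es <- eigenDecompose(net)
    # projector algebra
    expect_lt(max(abs(Reduce(`+`, es@projectors) - diag(3))), 1e-9)
    for (l in 1:3) for (m in 1:3) {
      prod <- es@projectors[[l]] %*% es@projectors[[m]]
      expect_lt(max(abs(prod - if (l == m) es@projectors[[l]] else 0)),
                1e-8)
    }
    for (t in c(0.05, 0.2, 1)) {
      oracle <- as.matrix(Matrix::expm(Matrix::Matrix(rateMatrix(net) * t)))
      expect_lt(max(abs(propagator(es, t) - oracle)), 1e-10)
    }
  }
})

test_that("exp(Kt) columns are probability vectors", {
  set.seed(12)
  net <- randomDetailedBalanceNetwork(3)
  es <- eigenDecompose(net)
  for (t in c(0.01, 0.1, 1, 10)) {
    P <- propagator(es, t)
    expect_true(all(P > -1e-12))
    expect_equal(colSums(P), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("network configs round-trip through the structured format", {
  net <- kineticNetwork(3, data.frame(
    from = c("MF", "LF", "LF", "HF"), to = c("LF", "MF", "HF", "LF"),
    rate = c(5, 2.5, 1.25, 0.625)), labels = c("MF", "LF", "HF"))
  path <- tempfile(fileext = ".yaml")
  writeKineticNetwork(net, path)
  back <- readKineticNetwork(path)
  expect_identical(stateLabels(back), stateLabels(net))
  expect_equal(rateMatrix(back), rateMatrix(net))
})
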