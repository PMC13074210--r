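#' Dynamic photon distribution analysis model
#'
#' Expected shape of the FRET-efficiency histogram for photons collected in
#' fixed time windows of length T: the occupancy-time distribution of the
#' dynamic pair (pseudo-static deltas plus the Bessel-form density) and the
#' static species deltas define P(E); binomial counting statistics with an
#' empirical photon-number distribution turn P(E) into the distribution of
#' the proximity ratio NR/F.
#'
#' @param T window length, ms.
#' @param E species efficiencies (length n); indices `dynPair` exchange.
#' @param xs static-state fractions (sum to 1).
#' @param pd fraction of dynamic molecules.
#' @param k12 rate into the first dynamic state (from the second), 1/ms.
#' @param k21 rate out of the first dynamic state, 1/ms.
#' @param dynPair indices of the two exchanging species within `E` (first
#'   entry is "state 1").
#' @param gamma,alpha detection corrections mapping E to the red photon
#'   probability \eqn{\epsilon(E) = (\gamma E + \alpha(1-E)) /
#'   (1 - E + \gamma E + \alpha(1-E))}.
#' @param nGrid E-grid points for the dynamic part.
#' @return list of class `"fkPdaModel"`.
#' @export
pdaModel <- function(T, E, xs, pd, k12, k21, dynPair = c(1, 2),
                     gamma = 1, alpha = 0, nGrid = 501) {
  stopifnot(length(xs) == length(E), abs(sum(xs) - 1) < 1e-8,
            pd >= 0, pd <= 1)
  structure(list(T = T, E = E, xs = xs, pd = pd, k12 = k12, k21 = k21,
                 dynPair = dynPair, gamma = gamma, alpha = alpha,
                 nGrid = nGrid),
            class = "fkPdaModel")
}

.epsOfE <- function(E, gamma, alpha) {
  r <- gamma * E + alpha * (1 - E)
  r / (r + 1 - E)
}

## fixed red-probability support of the model: the two dynamic-state values
## (pseudo-static deltas), the affine E(x) image of the occupancy grid, and
## the static species values; independent of the kinetic parameters
.pdaSupport <- function(E, dynPair, nGrid, gamma, alpha) {
  E1 <- E[dynPair[1]]; E2 <- E[dynPair[2]]
  xg <- (seq_len(nGrid) - 0.5) / nGrid
  .epsOfE(c(E1, E2, xg * E1 + (1 - xg) * E2, E), gamma, alpha)
}

## weights on .pdaSupport for a given parameter set
.pdaWeights <- function(model) {
  nG <- model$nGrid
  if (model$pd > 0) {
    occ <- occupancyDistribution(model$k12, model$k21, model$T, nGrid = nG)
    dynW <- c(occ@w1, occ@w0, occ@xi / nG)
  } else dynW <- numeric(nG + 2)
  c(model$pd * dynW, (1 - model$pd) * model$xs)
}

## expected-bin-probability kernel per support point: M[b, e] =
## sum_F p(F) sum_{NR: NR/F in bin b} Binom(NR; F, eps_e); the expensive
## part, parameter-independent, so cached once per window dataset in fits
.pdaKernel <- function(eps, breaks, Fcounts) {
  tf <- table(Fcounts)
  Fs <- as.integer(names(tf))
  pF <- as.numeric(tf) / sum(tf)
  nb <- length(breaks) - 1
  M <- matrix(0, nb, length(eps))
  for (fi in seq_along(Fs)) {
    F <- Fs[fi]
    nr <- 0:F
    bin <- cut(nr / F, breaks, include.lowest = TRUE, labels = FALSE)
    ok <- which(!is.na(bin))
    B <- vapply(eps, function(e) dbinom(nr, F, e), numeric(F + 1))
    agg <- rowsum(B[ok, , drop = FALSE], bin[ok])
    M[as.integer(rownames(agg)), ] <- M[as.integer(rownames(agg)), ] +
      pF[fi] * agg
  }
  M
}

#' Expected PDA histogram of the proximity ratio
#'
#' For each total photon count F in the empirical distribution,
#' \eqn{P(N_R | F) = \sum_E P(E)\, Binom(N_R; F, \epsilon(E))}; the
#' resulting NR/F values are accumulated into the requested E bins and
#' averaged over the photon-number distribution. Sums to 1.
#'
#' @param model an `fkPdaModel` from [pdaModel].
#' @param breaks E-bin edges on \[0,1\].
#' @param Fcounts integer vector of window photon counts (the empirical
#'   photon-number distribution; required).
#' @return vector of expected bin probabilities (length `length(breaks)-1`).
#' @export
pdaHistogram <- function(model, breaks = seq(0, 1, by = 0.02), Fcounts) {
  if (missing(Fcounts) || !length(Fcounts))
    stop("empirical photon-number distribution required")
  eps <- .pdaSupport(model$E, model$dynPair, model$nGrid,
                     model$gamma, model$alpha)
  M <- .pdaKernel(eps, breaks, Fcounts)
  p <- drop(M %*% .pdaWeights(model))
  p / sum(p)
}

#' Fit a static/dynamic mixture by dynamic PDA
#'
#' Minimizes the Pearson chi-square of the observed window histograms
#' (jointly over all window lengths) over the dynamic fraction, the two
#' exchange rates and the static fractions; species efficiencies are fixed
#' (typically from TCSPC). Derivative-free simplex start followed by a
#' quasi-Newton polish, with multi-start initial points. The binomial
#' kernels are computed once per window dataset, so each objective
#' evaluation costs one occupancy-density evaluation and a matrix-vector
#' product.
#'
#' @param windowData named list, one element per window length, each a list
#'   with `T` (ms), `E` (window proximity ratios) and `F` (photon counts),
#'   e.g. the output of [timeWindowHistograms].
#' @param E species efficiencies (fixed).
#' @param dynPair indices of the exchanging pair.
#' @param breaks histogram bin edges.
#' @param init optional list with pd, k12, k21, xs.
#' @param staticOnly fit a purely static model (pd = 0) instead.
#' @param nStarts number of random initial points.
#' @param gamma,alpha detection corrections.
#' @param nGrid E-grid points.
#' @return list with `pd`, `k12`, `k21`, `xs`, `chi2`, `chi2r`, `expected`
#'   histograms and `observed` counts.
#' @export
fitPda <- function(windowData, E, dynPair = c(1, 2),
                   breaks = seq(0, 1, by = 0.02), init = NULL,
                   staticOnly = FALSE, nStarts = 8, gamma = 1, alpha = 0,
                   nGrid = 501) {
  ns <- length(E)
  obs <- lapply(windowData, function(wd)
    hist(wd$E, breaks = breaks, plot = FALSE)$counts)
  nW <- length(windowData)
  eps <- .pdaSupport(E, dynPair, nGrid, gamma, alpha)
  kern <- lapply(windowData, function(wd) .pdaKernel(eps, breaks, wd$F))
  nFree <- if (staticOnly) ns - 1 else 3 + ns - 1
  unpack <- function(p) {
    if (staticOnly) {
      z <- c(p, 0)
      list(pd = 0, k12 = 1, k21 = 1, xs = exp(z) / sum(exp(z)))
    } else {
      z <- c(p[-(1:3)], 0)
      list(pd = 1 / (1 + exp(-p[1])), k12 = exp(p[2]), k21 = exp(p[3]),
           xs = exp(z) / sum(exp(z)))
    }
  }
  expectedFor <- function(u, wi) {
    mdl <- pdaModel(windowData[[wi]]$T, E, u$xs, u$pd, u$k12, u$k21,
                    dynPair, gamma, alpha, nGrid)
    p <- drop(kern[[wi]] %*% .pdaWeights(mdl))
    p / sum(p) * length(windowData[[wi]]$E)
  }
  objective <- function(p) {
    u <- unpack(p)
    if (!staticOnly && (u$k12 > 1e3 || u$k21 > 1e3)) return(1e12)
    tot <- 0
    for (wi in seq_len(nW)) {
      # quadrature-normalization warnings at extreme trial rates are benign
      ex <- suppressWarnings(expectedFor(u, wi))
      use <- ex > 0.5
      tot <- tot + sum((obs[[wi]][use] - ex[use])^2 / ex[use])
    }
    if (!is.finite(tot)) 1e12 else tot
  }
  init0 <- if (!is.null(init))
    with(init, c(if (!staticOnly) c(log(pd / (1 - pd)), log(k12), log(k21)),
                 log(xs[-ns] / xs[ns])))
  else c(if (!staticOnly) c(0, log(5), log(5)), rep(0, ns - 1))
  best <- NULL
  for (st in seq_len(nStarts)) {
    p0 <- if (st == 1) init0 else init0 + rnorm(length(init0), sd = 0.8)
    o1 <- optim(p0, objective, method = "Nelder-Mead",
                control = list(maxit = 500))
    o2 <- tryCatch(optim(o1$par, objective, method = "BFGS",
                         control = list(maxit = 100)),
                   error = function(e) o1)
    o <- if (o2$value < o1$value) o2 else o1
    if (is.null(best) || o$value < best$value) best <- o
  }
  u <- unpack(best$par)
  nBins <- vapply(obs, function(o) sum(o > 0), numeric(1))
  dof <- max(sum(nBins) - nFree, 1)
  expected <- lapply(seq_len(nW), function(wi) expectedFor(u, wi))
  names(expected) <- names(windowData)
  list(pd = u$pd, k12 = u$k12, k21 = u$k21, xs = u$xs,
       chi2 = best$value, chi2r = best$value / dof, expected = expected,
       observed = obs, breaks = breaks)
}
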