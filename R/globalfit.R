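#' Assemble a global TCSPC + FCS dataset
#'
#' @param decay a [DecayHistogram-class] (donor decay).
#' @param curves named list of four [CorrelationCurve-class] objects with
#'   pairs GG, GR, RG, RR (finite sigmas).
#' @return list of class `"fkGlobalData"`.
#' @export
globalData <- function(decay, curves) {
  stopifnot(is(decay, "DecayHistogram"))
  prs <- vapply(curves, function(cu) cu@pair, character(1))
  structure(list(decay = decay, curves = curves, pairs = prs),
            class = "fkGlobalData")
}

#' Kinetic scheme: which species pair exchanges
#'
#' @param dynPair indices of the exchanging pair within the species set.
#' @param labels species labels.
#' @return character scheme label, e.g. "MF,HF<->LF" style list.
#' @export
schemeLabel <- function(dynPair, labels) {
  stat <- setdiff(seq_along(labels), dynPair)
  paste0(paste(labels[stat], collapse = ","),
         if (length(stat)) "," else "",
         labels[dynPair[1]], "<->", labels[dynPair[2]])
}

#' Enumerate binary-exchange kinetic schemes
#'
#' All assignments of one dynamic pair among n species (the remaining
#' species are purely static), mirroring the three permutations of a
#' three-state system.
#'
#' @param nStates number of species.
#' @param labels optional labels.
#' @return list of scheme descriptors (dynPair, label).
#' @export
enumerateSchemes <- function(nStates, labels = NULL) {
  if (is.null(labels)) labels <- paste0("S", seq_len(nStates))
  out <- list()
  for (i in seq_len(nStates - 1)) for (j in (i + 1):nStates)
    out[[length(out) + 1]] <- list(dynPair = c(i, j),
                                   label = schemeLabel(c(i, j), labels))
  out
}

## theta layout for a binary-exchange scheme over n species:
## E (n), k12, k21, xs (n, simplex), pd; detection tdiff, N are fit per
## dataset; s fixed. Internally unconstrained:
## qlogis/log/softmax transforms.
.gfPack <- function(th, n) {
  c(stats::qlogis(th$E), log(th$k12), log(th$k21),
    log(th$xs[-n] / th$xs[n]), stats::qlogis(th$pd),
    log(th$tdiff), log(th$N))
}

.gfUnpack <- function(p, n) {
  # keep trial efficiencies strictly inside (0,1): E = 1 means a zero
  # donor lifetime, which the decay model rejects
  E <- pmin(pmax(stats::plogis(p[seq_len(n)]), 1e-6), 1 - 1e-6)
  k12 <- exp(p[n + 1]); k21 <- exp(p[n + 2])
  z <- c(p[n + 2 + seq_len(n - 1)], 0)
  xs <- exp(z - max(z)); xs <- xs / sum(xs)
  pd <- stats::plogis(p[2 * n + 2])
  list(E = E, k12 = k12, k21 = k21, xs = xs, pd = pd,
       tdiff = exp(p[2 * n + 3]), N = exp(p[2 * n + 4]))
}

.gfModel <- function(th, dynPair, data, s = 0.25) {
  n <- length(th$E)
  net <- kineticNetwork(2, data.frame(from = c(2, 1), to = c(1, 2),
                                      rate = c(th$k12, th$k21)))
  # embed the dynamic pair into the full species set
  xd2 <- equilibriumFractions(net)
  xd <- numeric(n); xd[dynPair] <- xd2
  x <- th$pd * xd + (1 - th$pd) * th$xs
  # decay model scaled to the data
  t <- data$decay@time
  y <- data$decay@counts
  m <- decayModel(x, th$E, th$tauD0, t)
  sig <- sqrt(pmax(y, 1))
  a <- sum(y * m / sig^2) / sum(m^2 / sig^2)
  decayFit <- a * m
  # FCS curves: dynamic molecules live on the pair subspace only, so the
  # transient kinetic term reduces to the two-state decomposition while the
  # static residual runs over the full species set
  mmNet <- net
  det <- detectionModel(tdiff = th$tdiff, s = s, N = th$N)
  sv <- signalVectors(det, th$E)
  Sbar <- list(G = sum(sv$G * x), R = sum(sv$R * x))
  es <- eigenDecompose(mmNet)
  curvesFit <- lapply(data$curves, function(cu) {
    a1 <- substr(cu@pair, 1, 1); b1 <- substr(cu@pair, 2, 2)
    Sa <- sv[[a1]]; Sb <- sv[[b1]]
    # kinetic correlation over the full species set
    GkInf <- (th$pd * (Sa[dynPair] %*% xd2) * (Sb[dynPair] %*% xd2) +
              (1 - th$pd) * sum(Sa * Sb * th$xs)) /
             (Sbar[[a1]] * Sbar[[b1]])
    A0 <- drop(GkInf) - 1
    l <- es@eigenvalues[2]
    G1 <- th$pd * (es@projectors[[2]] %*% diag(xd2, 2))
    A1 <- drop(Sa[dynPair] %*% G1 %*% Sb[dynPair]) /
      (Sbar[[a1]] * Sbar[[b1]])
    Gk <- 1 + A0 + A1 * exp(l * cu@lag)
    1 + diffusionTerm(cu@lag, th$tdiff, s) * Gk / th$N
  })
  list(decayFit = decayFit, curvesFit = curvesFit, x = x, xd = xd2,
       amplitude = a)
}

#' Global chi-square of a parameter set
#'
#' \eqn{\chi^2_{global} = \chi^2_{TCSPC} + \chi^2_{FCS}}: squared weighted
#' residuals of the donor decay (Poisson weights) plus those of all
#' correlation curves (block-bootstrap weights).
#'
#' @param theta list with E (length n), k12, k21 (1/ms), xs (simplex), pd,
#'   tdiff (ms), N, tauD0 (ns).
#' @param data an `fkGlobalData` from [globalData].
#' @param dynPair indices of the exchanging species pair.
#' @param s aspect ratio (fixed).
#' @return scalar chi-square; attributes `chi2TCSPC` and `chi2FCS`.
#' @export
chi2Global <- function(theta, data, dynPair = c(1, 2), s = 0.25) {
  r <- .gfResiduals(theta, data, dynPair, s)
  out <- sum(r$tcspc^2) + sum(r$fcs^2)
  attr(out, "chi2TCSPC") <- sum(r$tcspc^2)
  attr(out, "chi2FCS") <- sum(r$fcs^2)
  out
}

.gfResiduals <- function(theta, data, dynPair, s = 0.25) {
  m <- .gfModel(theta, dynPair, data, s)
  y <- data$decay@counts
  sig <- sqrt(pmax(y, 1))
  rt <- (m$decayFit - y) / sig
  rf <- unlist(lapply(seq_along(data$curves), function(i) {
    cu <- data$curves[[i]]
    sg <- cu@sigma
    if (any(!is.finite(sg) | sg <= 0)) {
      repl <- stats::median(sg[is.finite(sg) & sg > 0])
      if (!is.finite(repl)) stop("sigma = 0 in correlation data")
      sg[!is.finite(sg) | sg <= 0] <- repl
    }
    # per-curve additive baseline (finite-measurement normalization bias of
    # the correlation estimator) profiled out analytically
    w <- 1 / sg^2
    B <- sum(w * (cu@G - m$curvesFit[[i]])) / sum(w)
    (m$curvesFit[[i]] + B - cu@G) / sg
  }))
  list(tcspc = rt, fcs = rf)
}

#' Global TCSPC + FCS fit
#'
#' Bounded Levenberg-Marquardt on the joint residual vector, with
#' multi-start initial points drawn from a Latin hypercube over the
#' parameter bounds. Fixed parameters are held at their `init` values.
#'
#' @param data an `fkGlobalData`.
#' @param dynPair indices of the exchanging pair (the scheme).
#' @param init list with starting values E, k12, k21, xs, pd, tdiff, N,
#'   tauD0 (tauD0 always fixed).
#' @param fix character vector of parameter names to fix (any of "E",
#'   "k12", "k21", "xs", "pd", "tdiff", "N").
#' @param nStarts number of Latin-hypercube starts.
#' @param s aspect ratio.
#' @return list of class `"fkGlobalFit"` with `theta`, `chi2`, `chi2r`,
#'   `dof`, `scheme`, `converged`.
#' @export
fitGlobal <- function(data, dynPair, init, fix = character(0),
                      nStarts = 16, s = 0.25) {
  n <- length(init$E)
  tauD0 <- init$tauD0
  full0 <- .gfPack(init, n)
  fixedMask <- logical(length(full0))
  nmIdx <- list(E = seq_len(n), k12 = n + 1, k21 = n + 2,
                xs = n + 2 + seq_len(n - 1), pd = 2 * n + 2,
                tdiff = 2 * n + 3, N = 2 * n + 4)
  for (f in fix) fixedMask[nmIdx[[f]]] <- TRUE
  resid <- function(pFree) {
    p <- full0; p[!fixedMask] <- pFree
    th <- .gfUnpack(p, n); th$tauD0 <- tauD0
    r <- .gfResiduals(th, data, dynPair, s)
    c(r$tcspc, r$fcs)
  }
  nFree <- sum(!fixedMask)
  best <- NULL
  cube <- lhs::randomLHS(max(nStarts - 1, 1), nFree)
  for (st in seq_len(nStarts)) {
    p <- if (st == 1) full0[!fixedMask] else
      full0[!fixedMask] + (cube[st - 1, ] - 0.5) * 1.5
    fit <- tryCatch(
      minpack.lm::nls.lm(p, fn = resid,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("global fit failed in all starts")
  p <- full0; p[!fixedMask] <- best$par
  th <- .gfUnpack(p, n); th$tauD0 <- tauD0
  ndata <- length(data$decay@counts) +
    sum(vapply(data$curves, function(cu) length(cu@G), numeric(1)))
  dof <- max(ndata - nFree, 1)
  chi2 <- chi2Global(th, data, dynPair, s)
  structure(list(theta = th, chi2 = as.numeric(chi2),
                 chi2TCSPC = attr(chi2, "chi2TCSPC"),
                 chi2FCS = attr(chi2, "chi2FCS"),
                 chi2r = as.numeric(chi2) / dof, dof = dof,
                 dynPair = dynPair, converged = best$info %in% 1:4,
                 par = p, fixedMask = fixedMask, n = n, s = s,
                 tauD0 = tauD0),
            class = "fkGlobalFit")
}

#' Affine-invariant ensemble MCMC over the global posterior
#'
#' Stretch-move ensemble sampler with likelihood
#' \eqn{\exp(-\chi^2_{global}/2)} and uniform priors given by box bounds on
#' the transformed parameters. Reproducible under a fixed seed.
#'
#' @param data an `fkGlobalData`.
#' @param dynPair the scheme.
#' @param init start values (list as in [fitGlobal]), typically a fit
#'   result's `theta`.
#' @param fix fixed parameter names.
#' @param nWalkers,nSteps ensemble size and steps (defaults 64 and 5000;
#'   reduce for quick mapping).
#' @param burnIn fraction of steps discarded.
#' @param stretch stretch parameter a of the move.
#' @param seed optional seed.
#' @param s aspect ratio.
#' @return list with `samples` (data.frame of retained draws: E1..En, k12,
#'   k21, xs1..xsn, pd, tdiff, N, chi2), `acceptance`.
#' @export
mcmcSample <- function(data, dynPair, init, fix = character(0),
                       nWalkers = 64, nSteps = 5000, burnIn = 0.2,
                       stretch = 2, seed = NULL, s = 0.25) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(init$E)
  tauD0 <- init$tauD0
  full0 <- .gfPack(init, n)
  nmIdx <- list(E = seq_len(n), k12 = n + 1, k21 = n + 2,
                xs = n + 2 + seq_len(n - 1), pd = 2 * n + 2,
                tdiff = 2 * n + 3, N = 2 * n + 4)
  fixedMask <- logical(length(full0))
  for (f in fix) fixedMask[nmIdx[[f]]] <- TRUE
  bounds <- 6   # transformed-scale half-width of the uniform prior box
  logPost <- function(pFree) {
    if (any(abs(pFree - full0[!fixedMask]) > bounds)) return(-Inf)
    p <- full0; p[!fixedMask] <- pFree
    th <- .gfUnpack(p, n); th$tauD0 <- tauD0
    c2 <- tryCatch(as.numeric(chi2Global(th, data, dynPair, s)),
                   error = function(e) Inf)
    if (!is.finite(c2)) return(-Inf)
    -c2 / 2
  }
  nFree <- sum(!fixedMask)
  W <- matrix(rnorm(nWalkers * nFree, sd = 0.02), nWalkers, nFree)
  W <- sweep(W, 2, full0[!fixedMask], `+`)
  lp <- apply(W, 1, logPost)
  keepFrom <- ceiling(nSteps * burnIn)
  nAcc <- 0; nProp <- 0
  out <- vector("list", nSteps - keepFrom + 1)
  for (step in seq_len(nSteps)) {
    for (w in seq_len(nWalkers)) {
      other <- sample(setdiff(seq_len(nWalkers), w), 1)
      z <- ((stretch - 1) * runif(1) + 1)^2 / stretch
      prop <- W[other, ] + z * (W[w, ] - W[other, ])
      lpp <- logPost(prop)
      nProp <- nProp + 1
      if (log(runif(1)) < (nFree - 1) * log(z) + lpp - lp[w]) {
        W[w, ] <- prop; lp[w] <- lpp; nAcc <- nAcc + 1
      }
    }
    if (step >= keepFrom) {
      th <- lapply(seq_len(nWalkers), function(w) {
        p <- full0; p[!fixedMask] <- W[w, ]
        .gfUnpack(p, n)
      })
      out[[step - keepFrom + 1]] <- do.call(rbind, lapply(
        seq_len(nWalkers), function(w) {
          t_ <- th[[w]]
          c(setNames(t_$E, paste0("E", seq_len(n))),
            k12 = t_$k12, k21 = t_$k21,
            setNames(t_$xs, paste0("xs", seq_len(n))),
            pd = t_$pd, tdiff = t_$tdiff, N = t_$N, chi2 = -2 * lp[w])
        }))
    }
  }
  samples <- as.data.frame(do.call(rbind, out))
  list(samples = samples, acceptance = nAcc / nProp)
}

#' Resolve the (pd, k12) ambiguity with an external estimate
#'
#' Intersects the degeneracy manifold of a binary exchange (fixed
#' relaxation time tR and amplitude product \eqn{p_d x_d^{(1)} x_d^{(2)}})
#' with an external constraint: either the dynamic fraction `pd` (e.g.
#' from the off-line burst fraction or PDA) or the dynamic-state fraction
#' `xd1` (e.g. from FRET-line mode inversion).
#'
#' @param tR relaxation time, ms.
#' @param amp amplitude product \eqn{p_d x_d^{(1)}(1-x_d^{(1)})}.
#' @param pd known dynamic fraction (give this or `xd1`).
#' @param xd1 known equilibrium fraction of dynamic state 1.
#' @return data.frame with the resolved (k12, k21, pd, xd1); two rows when
#'   only pd is known and the quadratic has two admissible roots.
#' @export
resolveWithPd <- function(tR, amp, pd = NULL, xd1 = NULL) {
  k <- 1 / tR
  if (!is.null(xd1)) {
    pdHat <- amp / (xd1 * (1 - xd1))
    res <- data.frame(k12 = xd1 * k, k21 = (1 - xd1) * k, pd = pdHat,
                      xd1 = xd1)
  } else if (!is.null(pd)) {
    # xd1 (1 - xd1) = amp / pd
    q <- amp / pd
    disc <- 0.25 - q
    if (disc < -1e-12) stop("constraint inconsistent with the manifold")
    disc <- max(disc, 0)
    x1 <- 0.5 + sqrt(disc); x2 <- 0.5 - sqrt(disc)
    xs <- unique(c(x1, x2))
    res <- data.frame(k12 = xs * k, k21 = (1 - xs) * k, pd = pd, xd1 = xs)
  } else stop("provide pd or xd1")
  res[res$pd >= 0 & res$pd <= 1 & res$xd1 > 0 & res$xd1 < 1, , drop = FALSE]
}
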