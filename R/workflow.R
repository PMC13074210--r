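## Three-step analysis workflow: (1) model selection from the 2D burst
## histogram, FRET-lines, color-FCS relaxation count and sub-ensemble
## decays; (2) quantification by global TCSPC+FCS fitting (optionally PDA);
## (3) validation by re-simulation and histogram comparison.

.distanceToDynamicLine <- function(Em, tauFm, E1, E2, tauD0) {
  ln <- dynamicFretLine(E1, E2, tauD0, x = seq(0, 1, length.out = 401))
  min(sqrt(((ln$tauF - tauFm) / tauD0)^2 + (ln$E - Em)^2))
}

#' Run the multi-state analysis workflow
#'
#' Step 1 identifies static and dynamic populations in the burst data
#' (position relative to the static FRET-line), counts FCS relaxation
#' times, estimates species efficiencies from the ensemble decay, and
#' ranks candidate binary-exchange schemes by the distance of the dynamic
#' population to each binary dynamic FRET-line. Step 2 runs the global
#' TCSPC + FCS fit for every admissible candidate. Step 3 re-simulates the
#' selected model and reports the Kolmogorov-Smirnov distance between the
#' observed and re-simulated burst efficiency histograms.
#'
#' @param stream a [PhotonStream-class].
#' @param tauD0 donor-only lifetime, ns.
#' @param knownE optional species efficiencies (skips the decay-based
#'   estimate).
#' @param dsThreshold dynamic-shift threshold separating static from
#'   shifted bursts.
#' @param doGlobalFit run step 2 global fits.
#' @param doValidate run step 3 re-simulation.
#' @param tdiff0 initial diffusion time for fits, ms.
#' @param validateDuration re-simulation length, ms.
#' @param seed seed for the validation simulation.
#' @return list of class `"fkWorkflowReport"`; see Details.
#' @export
runWorkflow <- function(stream, tauD0 = 4, knownE = NULL,
                        dsThreshold = 0.03, doGlobalFit = TRUE,
                        doValidate = TRUE, tdiff0 = 5,
                        validateDuration = 8000, seed = 7) {
  report <- list(provenance = list())
  note <- function(key, txt) report$provenance[[key]] <<- txt

  ## ---- step 1.1: bursts and population classification ----
  bursts <- detectBursts(stream)
  if (nrow(bursts) < 20) {
    warning("too few bursts; partial report")
    report$bursts <- bursts
    class(report) <- "fkWorkflowReport"
    return(report)
  }
  Etau <- 1 - bursts$tauF / tauD0
  ds <- (bursts$E - Etau) / 2
  dynamic <- is.finite(ds) & ds > dsThreshold
  report$bursts <- bursts
  report$dynamicFraction <- mean(dynamic)
  note("populations", sprintf(
    "%d bursts; %.1f%% shifted off the static FRET-line (ds > %.2f)",
    nrow(bursts), 100 * mean(dynamic), dsThreshold))

  ## ---- step 1.2: color-FCS relaxation count ----
  gr <- correlateStream(stream, "G", "R", pair = "GR")
  f1 <- fitFcsCurve(gr, nRelaxations = 1, tdiff0 = tdiff0)
  f2 <- tryCatch(fitFcsCurve(gr, nRelaxations = 2, tdiff0 = tdiff0),
                 error = function(e) NULL)
  # a second relaxation counts only when it clearly improves the fit and
  # both times are well separated from the diffusion timescale
  nRelax <- if (!is.null(f2) && f2$chi2r < 0.7 * f1$chi2r &&
                all(f2$tR < f2$tdiff / 2)) 2L else 1L
  report$fcs <- list(curve = gr, fit1 = f1, fit2 = f2, nRelaxations = nRelax)
  note("fcs", sprintf(
    "GR cross-correlation needs %d relaxation time(s); tR = %s ms",
    nRelax, paste(signif(if (nRelax == 2) f2$tR else f1$tR, 3),
                  collapse = ", ")))

  ## ---- step 1.3: species efficiencies from the ensemble decay ----
  if (is.null(knownE)) {
    dec <- subensembleDecay(stream, bursts)
    df <- fitDecay(dec, nComponents = 3, tauD0 = tauD0)
    knownE <- sort(pmax(pmin(df$E, 0.99), 0.01))
    note("tcspc", sprintf("3-component decay fit: E = %s",
                          paste(signif(knownE, 3), collapse = ", ")))
  }
  E <- sort(knownE)
  labels <- c("LF", "MF", "HF")[seq_along(E)]
  report$speciesE <- setNames(E, labels)

  ## ---- step 1.4: candidate schemes from FRET-line positions ----
  dynB <- bursts[dynamic, , drop = FALSE]
  if (nrow(dynB) >= 10) {
    Em <- modalEfficiency(dynB$E)
    tauFm <- median(dynB$tauF, na.rm = TRUE)
  } else {
    Em <- NA_real_; tauFm <- NA_real_
  }
  schemes <- enumerateSchemes(length(E), labels)
  lineDist <- vapply(schemes, function(sc)
    if (is.na(Em)) NA_real_ else
      .distanceToDynamicLine(Em, tauFm, E[sc$dynPair[1]], E[sc$dynPair[2]],
                             tauD0), numeric(1))
  names(lineDist) <- vapply(schemes, `[[`, character(1), "label")
  admitted <- if (all(is.na(lineDist))) rep(TRUE, length(schemes)) else
    lineDist <= pmax(2 * min(lineDist, na.rm = TRUE), 0.05)
  multiState <- nRelax >= 2 ||
    (!any(is.na(lineDist)) && all(lineDist > 0.05))
  report$candidates <- data.frame(
    scheme = names(lineDist), lineDistance = lineDist,
    admitted = admitted)
  report$dynamicMode <- c(E = Em, tauF = tauFm)
  report$multiStateFlag <- multiState
  note("fretlines", if (multiState)
    "population between limiting binary lines or >1 relaxation time: >= 3-state exchange, route to filtered-FCS"
  else sprintf("FRET-line evidence admits: %s",
               paste(names(lineDist)[admitted], collapse = "; ")))

  ## ---- step 2: quantification ----
  if (doGlobalFit && nrow(bursts) > 0) {
    dec <- subensembleDecay(stream, bursts)
    curves <- lapply(c("GG", "GR", "RG", "RR"), function(pr)
      correlateStream(stream, substr(pr, 1, 1), substr(pr, 2, 2), pair = pr))
    names(curves) <- c("GG", "GR", "RG", "RR")
    gdata <- globalData(dec, curves)
    init <- list(E = E, k12 = 5, k21 = 5, xs = rep(1 / length(E), length(E)),
                 pd = 0.5, tdiff = tdiff0, N = f1$N, tauD0 = tauD0)
    fits <- lapply(schemes, function(sc)
      tryCatch(fitGlobal(gdata, sc$dynPair, init, fix = "E", nStarts = 4),
               error = function(e) NULL))
    names(fits) <- vapply(schemes, `[[`, character(1), "label")
    report$globalFits <- fits
    chi2r <- vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$chi2r, numeric(1))
    physical <- vapply(fits, function(f) {
      if (is.null(f)) return(FALSE)
      all(f$theta$xs >= -1e-6) && f$theta$pd >= 0 && f$theta$pd <= 1 &&
        all(totalAfterFit(f) >= -1e-6)
    }, logical(1))
    report$schemeTable <- data.frame(
      scheme = names(fits), chi2r = chi2r, lineDistance = lineDist,
      admitted = admitted, physical = physical)
    sel <- which(admitted & physical)
    if (!length(sel)) sel <- which(admitted)
    sel <- sel[which.min(lineDist[sel])]
    report$selectedScheme <- names(fits)[sel]
    report$selectedFit <- fits[[sel]]
    note("selection", sprintf(
      "scheme %s selected by FRET-line position (chi2r values alone are degenerate: %s)",
      names(fits)[sel], paste(signif(chi2r, 3), collapse = " vs ")))
  }

  ## ---- step 3: validation by re-simulation ----
  if (doValidate && !is.null(report$selectedFit)) {
    th <- report$selectedFit$theta
    sc <- schemes[[which(vapply(schemes, `[[`, character(1), "label") ==
                         report$selectedScheme)]]
    pr <- sc$dynPair
    net <- kineticNetwork(length(E), data.frame(
      from = pr[c(2, 1)], to = pr, rate = c(th$k12, th$k21)),
      labels = labels)
    xd <- numeric(length(E))
    xd[pr] <- c(th$k12, th$k21) / (th$k12 + th$k21)
    cfg <- simulationConfig(E, labels = labels, net = net, pd = th$pd,
                            xs = pmax(th$xs, 0) / sum(pmax(th$xs, 0)),
                            det = detectionModel(tdiff = th$tdiff),
                            tauD0 = tauD0, xd = xd,
                            duration = validateDuration)
    vstream <- simulateStream(cfg, seed = seed)
    vb <- detectBursts(vstream)
    if (nrow(vb) >= 20) {
      ks <- suppressWarnings(ks.test(bursts$E, vb$E)$statistic)
      report$validation <- list(ksDistance = unname(ks),
                                nBurstsResim = nrow(vb))
      note("validation", sprintf(
        "re-simulated %s: KS distance of burst E histograms = %.3f",
        report$selectedScheme, unname(ks)))
    }
  }
  class(report) <- "fkWorkflowReport"
  report
}

## total fractions implied by a global fit (for physicality screening)
totalAfterFit <- function(fit) {
  th <- fit$theta
  xd <- numeric(fit$n)
  xd[fit$dynPair] <- c(th$k12, th$k21) / (th$k12 + th$k21)
  th$pd * xd + (1 - th$pd) * th$xs
}

#' @export
print.fkWorkflowReport <- function(x, ...) {
  cat("Workflow report\n===============\n")
  for (nm in names(x$provenance))
    cat(sprintf("[%s] %s\n", nm, x$provenance[[nm]]))
  if (!is.null(x$schemeTable)) {
    cat("\nCandidate schemes:\n")
    print(x$schemeTable, row.names = FALSE)
  }
  invisible(x)
}
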