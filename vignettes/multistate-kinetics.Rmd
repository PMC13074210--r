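---
title: "Quantifying multi-state conformational kinetics in diffusion smFRET"
author: "fretKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-state conformational kinetics in diffusion smFRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretKinetics)
```

## The problem

In single-molecule FRET experiments on freely diffusing molecules, each
molecule crosses a confocal observation volume for about a millisecond,
emitting a short burst of photons. If the molecule interconverts between
conformational states with distinct FRET efficiencies during that transit,
its burst-averaged observables mix the states. Worse, real samples usually
contain *both* dynamic molecules and pseudo-static ones — molecules trapped
in a conformation for much longer than the observation time — often with
indistinguishable FRET efficiencies. One-dimensional FRET-efficiency
histograms are then nearly blind to the kinetics: very different mixtures
produce almost identical histograms.

fretKinetics implements an integrative analysis for this regime. Its parts
are deliberately complementary:

* **FRET-lines** in the two-dimensional histogram of intensity-based
  efficiency $E$ versus the intensity-weighted donor lifetime
  $\langle\tau_{DA}\rangle_F$ identify which species exchange
  (connectivity), and the position of a dynamic population along a line
  gives its equilibrium composition.
* **Color-FCS** model functions for $N$-state networks with a static
  background measure the relaxation times $t_R^{(l)}$ — but their
  amplitudes alone cannot untangle the dynamic fraction from the rates.
* **TCSPC decay models** pin the species efficiencies and total fractions.
* A **global fit** of decay plus the four color correlation curves, with
  MCMC mapping of the remaining degeneracies.
* **Dynamic PDA** (photon distribution analysis) and **filtered-FCS**
  resolve what the global fit cannot: the dynamic molecule fraction and the
  connectivity of fast three-state networks.
* A **photon-level Monte Carlo simulator** regenerates complete synthetic
  experiments so that every estimator in the package can be validated
  end-to-end against known ground truth.

## Kinetic networks

A network of $n$ conformational states is a continuous-time Markov chain
with transition rate matrix $K$, using the convention that $K_{ij}$ (R:
`rateMatrix(net)[i, j]`) is the rate of transition *from state $j$ to state
$i$* in ms$^{-1}$, so $\dot x = Kx$ and columns of $K$ sum to zero. The
package keeps this convention everywhere, including file formats. One
worked example used throughout: a two-state system with
$k_{12} = 3\,\mathrm{ms}^{-1}$ (into state 1) and $k_{21} =
1\,\mathrm{ms}^{-1}$ has equilibrium fraction $x_d^{(1)} = k_{12}/(k_{12} +
k_{21}) = 0.75$; with state 1 the high-FRET state ($E^{(1)} = 0.8$,
$E^{(2)} = 0.2$) the mean efficiency is $0.65$. (Assigning state 1 the
*low* efficiency would give 0.35 — the package never reinterprets the
user's state ordering, so the mapping of labels to efficiencies is the
user's responsibility.)

```{r}
net <- kineticNetwork(2, data.frame(from = c(2, 1), to = c(1, 2),
                                    rate = c(3, 1)))
equilibriumFractions(net)
meanEfficiency(c(0.75, 0.25), c(0.8, 0.2))
```

Relaxation times are the negative inverse nonzero eigenvalues of $K$; an
irreducible $n$-state network has $n - 1$ of them. The eigendecomposition
uses a similarity transform by $\sqrt{x_{eq}}$ whenever detailed balance
holds (within $10^{-9}$ relative flux asymmetry), which makes the problem
symmetric — a real spectrum and orthogonal spectral projectors by
construction; a general eigensolver is the fallback for driven networks.
Zero eigenvalues are identified with tolerance $10^{-10}\max|K|$.

## FRET-lines and the dynamic shift

For an ideal (linker-free) dye pair, a single species with efficiency $E$
lies on the static line $E = 1 - \langle\tau_{DA}\rangle_F/\tau_{D0}$.
A binary mixture at species fraction $x$ has

$$E(x) = xE_1 + (1-x)E_2, \qquad
\langle\tau_{DA}\rangle_F(x) = \frac{x\tau_1^2 + (1-x)\tau_2^2}
{x\tau_1 + (1-x)\tau_2},$$

which traces the *dynamic line* — independent of how fast the exchange is.
Its displacement from the static line, the dynamic shift

$$ds(x) = \frac{1}{2}\,\frac{(E_2-E_1)^2\,x(1-x)}
{x(1-E_1) + (1-x)(1-E_2)},$$

is maximal at $x_{max} = \sqrt{1-E_2}/(\sqrt{1-E_1}+\sqrt{1-E_2})$ with
$ds_{max} = \tfrac12(\sqrt{1-E_1}-\sqrt{1-E_2})^2$. A useful identity the
test suite enforces: $ds = (E - E_\tau)/2$, half the vertical offset of
the population above the static line, where $E_\tau = 1 -
\langle\tau_{DA}\rangle_F/\tau_{D0}$. (Note this is $1/\sqrt2$ *times* the
Euclidean point-line distance in normalized coordinates; the $1/2$
normalization is the one consistent with the closed-form maximum, so it is
the one implemented.) The same pair of indicators carries the variance of
the underlying efficiency distribution,
$\mathrm{Var}(E) = (1-E)(E-E_\tau)$, which connects the two-dimensional
histogram to FCS amplitudes (below).

The *moment representation* used for straight-line overlays is defined in
this package as $(m_1, m_2) = (1-E,\ (1-E)(1-E_\tau))$ — both coordinates
are affine in $x$, so binary dynamic lines become exact straight lines.
Other axis conventions exist in the literature; plots state the definition.

## Occupancy-time distributions and mode inversion

Over an observation window $T$, the fraction of time $x^{(1)}$ a two-state
molecule spends in state 1 has a distribution with two delta terms
(molecules that never switched — the pseudo-static contribution) of
weights $w_1 = x_d^{(1)}e^{-k_{21}T}$, $w_0 = x_d^{(2)}e^{-k_{12}T}$, and a
continuous density $\xi_{12}$ involving modified Bessel functions $I_0,
I_1$. The literature prefactor of $\xi_{12}$ is fixed by exact normalization
to $T\,k_{12}k_{21}/(k_{12}+k_{21})$ (verified numerically to $10^{-8}$
over diverse parameters before freezing); Bessel terms are evaluated in
exponentially scaled form $e^{z-a}\,[e^{-z}I_n(z)]$ so the density is
stable to $kT \sim 10^4$. The density lives on a 2001-point midpoint grid
over the open interval $(0,1)$, which integrates the inverse-square-root
endpoint singularities without special handling; a renormalization guard
corrects residual quadrature error only below 0.5%.

The mode $x_m$ of $\xi_{12}$ approaches the equilibrium fraction for long
windows, and for finite $kT$ an approximately linear map recovers
$\hat x_d^{(1)} = x_{d,lim} + (1-2x_{d,lim})x_m$ with the analytic
intercept $x_{d,lim}(kT) = \tfrac32[1 + \tfrac{kT}2(1 +
I_0(kT/2)/I_1(kT/2))]^{-1}$. The analytic map is the default; since the
literature leaves open whether an empirical calibration was used for the
intercept, a calibration-by-simulation fallback is available by regressing
`occupancyMode` output against known fractions from the package's own
simulator. On burst data the observation time is set to the mean burst
duration by default (a diffusion-time proxy; configurable), and the modal
efficiency estimator uses Freedman–Diaconis bins with parabolic refinement
of the argmax.

```{r}
occ <- occupancyDistribution(k12 = 3, k21 = 1, T = 10)
invertMode(occupancyMode(occ), k = 4, T = 10)
```

## Color-FCS model

Diffusion and kinetics factorize:
$G_{ab}(t_c) = 1 + \frac1N G_{diff}(t_c) G_{k,ab}(t_c)$ with the 3D
Gaussian diffusion term $G_{diff} = (1+t_c/t_{diff})^{-1}(1 + s^2
t_c/t_{diff})^{-1/2}$, aspect ratio $s = w_0/z_0 = 0.25$ by default. The
kinetic factor for a mixture of dynamic molecules (fraction $p_d$,
network $K$) and frozen molecules (fractions $x_s$) is

$$G_{k,ab}(t_c) = \frac{S_a^T\,[p_d e^{Kt_c}X_d + (1-p_d)X_s]\,S_b}
{\bar S_a \bar S_b},$$

with per-species signals $q_G = Q_0(1-E)$, $q_R = Q_0(\gamma E +
\alpha(1-E))$. Defaults are the idealized $\gamma = 1$, $\alpha = 0$, no
background; nonzero values are supported throughout. Two evaluation paths
— the direct matrix exponential and the spectral amplitude expansion
$1 + A^{(0)} + \sum_l A^{(l)} e^{\lambda^{(l)}t_c}$ — are both exported
and agree to $10^{-10}$; the static residual $A^{(0)}$ is derived from the
$t_c \to \infty$ limit of the correlation matrix rather than from the
typeset amplitude formula, and is verified against the closed two-state
form. Amplitudes below $10^{-14}$ are pruned.

Why a global analysis is necessary: for a purely dynamic two-state system
the cross amplitude obeys $\partial_{GR} = -\sqrt{\partial_{GG}
\partial_{RR}}$ — it adds nothing — leaving three observables for four
model parameters. With a static background the identifiable combinations
are the relaxation time $t_R = (k_{12}+k_{21})^{-1}$ and the product
$p_d x_d^{(1)} x_d^{(2)}$: the family of microscopic parameter sets along
this manifold (`ambiguityManifold`) produces *identical* model curves, a
fact asserted to $10^{-10}$ in the tests and mapped by MCMC on synthetic
data.

## TCSPC model

The ensemble donor decay is the species-fraction weighted sum
$f(t) = \sum_i x^{(i)} \exp(-t/\tau_{D0}(1-E^{(i)}))$ — weighting by
species fractions exactly as defined, not by photon yield; because the
distinction matters when comparing against photon-weighted estimators, the
photon-weighted variant is available via `weighting = "photon"` in
`decayModel`. Micro times span 0–25 ns in 4096 bins by default. No
instrument response convolution is applied by default (the simulator is
ideal); an optional Gaussian IRF would be a straightforward extension but
is out of scope here. Synthetic decays draw Poisson counts per bin;
sub-ensemble decays histogram the donor micro times of selected bursts.

## Global fit and MCMC

`chi2Global` is the sum of the Poisson-weighted decay residuals and the
uncertainty-weighted residuals of all four color correlation curves. FCS
uncertainties come from block averaging: the stream is split into 16
equal-duration segments, each correlated independently, and the point-wise
standard error of the mean is used as $\sigma_{FCS}$. Finite measurements
bias correlation estimators by a small, nearly lag-independent negative
offset (the sample means in the normalization absorb slow fluctuations);
the fit model therefore carries one additive baseline per curve, profiled
out analytically, exactly as a free offset is standard in FCS fitting.

The optimizer is bounded Levenberg–Marquardt on the residual vector
(`minpack.lm`), with parameters transformed to unconstrained scales
(logit for efficiencies and $p_d$, log for rates and times, softmax for
the static simplex) and multi-start initialization from a Latin hypercube
(16 starts by default). The MCMC sampler is an affine-invariant stretch
ensemble (64 walkers, 5000 steps, 20% burn-in by default; the test suite
runs 24 walkers for 300 steps, which is ample for mapping the
two-dimensional degeneracy surface at the suite's problem sizes) with
likelihood $e^{-\chi^2/2}$ and uniform priors on a transformed-scale box.
Scheme selection across the permutations of "which pair exchanges" is
deliberately **not** automated: the permutations fit equally well, and the
workflow requires the FRET-line evidence to break the tie.

## Dynamic PDA

For windows of length $T$, the package composes the occupancy-efficiency
distribution with binomial counting statistics on a 501-point efficiency
grid: $P(N_R|F) = \sum_E P(E)\,\mathrm{Binom}(N_R; F, \epsilon(E))$, with
the photon-number distribution $P(F)$ taken empirically from the data
windows (standard PDA practice) and $\epsilon(E)$ the red-photon
probability after $\gamma$/$\alpha$ corrections. This composition — an
explicit design choice, since the full dynamic-PDA recursion is not
restated here — is validated against a brute-force Monte Carlo (CTMC
trajectory per window plus binomial draw) by a $\chi^2$ test. Both
whole-stream and within-burst window cutting are provided; within-burst
cutting is the default analysis route since bursts carry the signal. The
fit minimizes Pearson $\chi^2$ jointly over window lengths (1–3 ms by
default) with a simplex start, quasi-Newton polish and multi-start; the
expensive binomial kernels depend only on the fixed efficiency grid and
are cached, so each objective evaluation costs one Bessel-density
evaluation and a matrix–vector product.

## Filtered-FCS

Species filters are built from the (channel × micro-time) decay patterns
by weighted linear least squares, $F = (P^T D P)^{-1} P^T D$ with $D =
\mathrm{diag}(1/W)$ over the pooled histogram — which makes $FP = I$ hold
exactly (unbiasedness), enforced as a class invariant. Patterns come from
the noise-free model decays (species parameters are known in simulation);
a sub-ensemble-derived pattern path exists for experimental use. Filters
use 64 micro-time bins per channel — coarse on purpose, since fine binning
amplifies filter noise. Degenerate patterns (identical lifetimes) raise an
error naming the collinear pair; near-degeneracy reports the condition
number. Species correlations then run through the same multi-tau engine
with per-photon filter weights. The key qualitative signatures: only
exchanging pairs show a rising species cross-correlation, and for linear
chains the indirect pair's rise is delayed relative to both direct pairs.

## The simulator

Molecules perform free Brownian motion (step $\sigma = \sqrt{2D\,dt}$,
$D = w_0^2/4t_{diff}$) with periodic wrapping in a box of $6w_0 \times 6w_0
\times 6z_0$ (configurable); the detection profile is the 3D Gaussian
$W(r) = e^{-2(x^2+y^2)/w_0^2 - 2z^2/z_0^2}$. The box size is a
convergence parameter: once the diffusion length at the longest analyzed
lag approaches the box half-width, periodic images flatten the tail of the
diffusion correlation and the recovered diffusion time drops by up to
\~15%. The default ($6w_0$ laterally) is a speed/accuracy compromise
adequate for kinetic relaxation times well below $t_{diff}$; analyses that
need the diffusion time itself to better than a few percent should use
`boxXY = 10` (the suite's diffusion self-consistency check does, and
recovers $t_{diff}$ to 1%). Each dynamic molecule carries
a CTMC evolved by *exact* exponential waiting times within every diffusion
step, and photons are emitted per constant-state segment as an
inhomogeneous Poisson process with rate $Q_0 W(r)$, split green/red by the
instantaneous state's efficiency; donor micro times are exponential with
$\tau_{D0}(1-E)$, acceptor micro times exponential with a fixed 1 ns
acceptor lifetime (generated but unused by the donor-based analyses).
Static molecules keep a state drawn from $x_s$. Dynamic/static counts and
initial states are allocated by largest remainder, so the realized mixture
matches the configured fractions to within one molecule — important
because the dynamic fraction is itself an estimand. The time step is
validated against a tenth of both the fastest relaxation time and the
diffusion time. All randomness uses R's RNG: a fixed seed reproduces the
photon stream bit for bit.

What the simulator deliberately does not emulate: dye photophysics
(triplet blinking, bleaching), background photons, linker dynamics,
acceptor direct excitation, and detector artifacts (afterpulsing, dead
time). Passing tests therefore demonstrate correctness of the estimators
under ideal photon statistics, not robustness to those experimental
complications — the corrections for which are established elsewhere and
orthogonal to the kinetics machinery here.

Burst detection is a single-channel-sum sliding window (at least 5 photons
within 500 µs centered on each photon, bursts of at least 60 photons by
default). The multi-tau correlator bins photon weights at a 2–5 µs base
width, 16 lags per cascade with factor-2 coarsening, and estimates
uncertainties by correlating 16 equal-duration blocks separately.

## Reference simulations

Seven reference configurations (`fixtureConfig(1:7)`) emulate the
package's validation scenarios: a four-species static mixture; three
static species plus a dynamic pair MF⇌LF at 5/5 ms⁻¹ ($t_{diff}$ = 5 ms);
the same with HF⇌LF at 6.3/3.7 ms⁻¹; a binary LF⇌HF exchange and the
three linear three-state chains, all rates 5 ms⁻¹ ($t_{diff}$ = 3.8 ms).
Species efficiencies default to $E_{LF} = 0.2$, $E_{MF} = 0.5$,
$E_{HF} = 0.8$ (static MF′ at 0.35), $\tau_{D0}$ = 4 ns, dynamic fraction
0.4, even static background — *defaults chosen once as realistic values
for a well-separated three-state system*, since only the rates, diffusion
times and the recovered dynamic fraction are externally pinned reference
values. Problem sizes
used by the validation suite: 25–100 s of simulated stream at 250–600 kHz
molecular brightness and mean occupancy 0.5–1 molecules, which yields a
few thousand bursts and several million photons — the same
high-signal-to-noise regime the reference scenarios describe (the
relaxation-time estimator's sampling error is about 8% at 60 s, so the
rate-recovery checks use 100 s). Recovery
tolerances (rates within 10%, dynamic fraction within 0.03) were fixed
from those scenarios' reported precision, not tuned.

## Numerical choices and degenerate inputs

* Reducible networks: equilibrium and eigen paths error with the names of
  the disconnected states; simulations over a sub-network require explicit
  initial dynamic fractions.
* Fully static networks (all rates zero) are legal everywhere except
  operations that need an equilibrium.
* $E = 1$ species are excluded from decay models (zero lifetime) with a
  warning; efficiencies at the \[0,1) boundary error in FRET-line code.
* Indicator pairs with $E < E_\tau$ (possible under shot noise) are
  flagged unphysical but the negative variance is returned unchanged, so
  downstream averaging over bursts stays unbiased.
* Ties in histogram modes fall back to the raw bin center when the
  parabolic refinement is degenerate.

## Known limitations

The occupancy machinery is two-state only (no closed form is implemented
for three-state occupancy distributions); three-state kinetics are handled
by FCS/fFCS and the global fit instead. The PDA model inherits the
within-burst brightness non-uniformity of real bursts only through the
empirical photon-number distribution, which leaves its absolute Pearson
$\chi^2_r$ miscalibrated on burst-cut windows (relative comparisons —
static vs dynamic models — remain valid, and the recovered parameters are
accurate). PDA assumes shot noise dominates the within-window statistics:
at very high molecular brightness the diffusion-induced brightness
modulation within a window becomes comparable to shot noise and the
recovered dynamic fraction picks up a bias of a few percent — analyze
PDA windows at moderate count rates. Rate recovery by the global fit assumes the diffusion term
separates from kinetics; relaxation times within a factor ~3 of the
diffusion time will show inflated uncertainties.
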