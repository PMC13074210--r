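#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Photon-level Monte Carlo of an smFRET experiment.
// Length unit: w0 (lateral 1/e^2 radius). Time unit: ms. Micro time: ns.
// Molecules perform free Brownian motion with periodic wrapping in a box of
// (boxXY*w0)^2 x (boxZ*z0); dynamic molecules carry a CTMC state evolved with
// exact exponential waiting times inside every diffusion step; photons are
// emitted as an inhomogeneous Poisson process with rate Q(state) * W(r),
// W(r) = exp(-2(x^2+y^2) - 2 z^2/z0eff^2), split green/red by the state's
// FRET efficiency (with gamma and alpha applied). Uses R's RNG throughout so
// a set.seed() call in R makes the stream bit-reproducible.
// [[Rcpp::export]]
List cpp_simulate_stream(int nMol, int nDyn, IntegerVector initState,
                         NumericMatrix K, NumericVector E,
                         double pRedOfState_gamma, double alpha,
                         double Q0, double tauD0, double tauA,
                         double microRange,
                         double tdiff, double sAspect,
                         double boxXY, double boxZ,
                         double dt, double duration) {
  const int n = K.nrow();
  const double D = 1.0 / (4.0 * tdiff);      // w0^2 / (4 tdiff), w0 = 1
  const double z0 = 1.0 / sAspect;
  const double sdStep = std::sqrt(2.0 * D * dt);
  const double Lx = boxXY, Lz = boxZ * z0;
  const int nSteps = (int)std::ceil(duration / dt);

  // per-state photon rates (kHz = photons/ms)
  std::vector<double> qG(n), qR(n), qTot(n), pRed(n), tauDState(n);
  for (int i = 0; i < n; ++i) {
    qG[i] = Q0 * (1.0 - E[i]);
    qR[i] = Q0 * (pRedOfState_gamma * E[i] + alpha * (1.0 - E[i]));
    qTot[i] = qG[i] + qR[i];
    pRed[i] = qTot[i] > 0 ? qR[i] / qTot[i] : 0.0;
    tauDState[i] = tauD0 * (1.0 - E[i]);
  }
  // exit rates and jump probabilities
  std::vector<double> kOut(n);
  for (int j = 0; j < n; ++j) kOut[j] = -K(j, j);

  std::vector<double> macro; std::vector<int> chan;
  std::vector<double> micro;
  macro.reserve(1 << 20); chan.reserve(1 << 20); micro.reserve(1 << 20);

  RNGScope scope;
  for (int m = 0; m < nMol; ++m) {
    double x = (unif_rand() - 0.5) * Lx;
    double y = (unif_rand() - 0.5) * Lx;
    double z = (unif_rand() - 0.5) * Lz;
    int state = initState[m];
    bool dynamic = (m < nDyn);
    for (int step = 0; step < nSteps; ++step) {
      const double t0 = step * dt;
      const double W = std::exp(-2.0 * (x * x + y * y)
                                - 2.0 * (z * z) / (z0 * z0));
      if (W > 1e-8) {
        // piecewise-constant state segments within this step
        double tseg = 0.0;
        int s = state;
        while (tseg < dt) {
          double segEnd = dt;
          int nextState = s;
          if (dynamic && kOut[s] > 0) {
            double wt = exp_rand() / kOut[s];
            if (tseg + wt < dt) {
              segEnd = tseg + wt;
              double u = unif_rand() * kOut[s], acc = 0.0;
              for (int i = 0; i < n; ++i) {
                if (i == s) continue;
                acc += K(i, s);
                if (u <= acc) { nextState = i; break; }
              }
              if (nextState == s) // numerical guard
                for (int i = 0; i < n; ++i) if (i != s) { nextState = i; }
            }
          }
          const double segLen = segEnd - tseg;
          const double mu = qTot[s] * W * segLen;
          int nph = (mu > 0) ? (int)R::rpois(mu) : 0;
          for (int p = 0; p < nph; ++p) {
            macro.push_back(t0 + tseg + unif_rand() * segLen);
            bool red = unif_rand() < pRed[s];
            chan.push_back(red ? 1 : 0);
            double tau = red ? tauA : tauDState[s];
            double mt = exp_rand() * tau;
            while (mt >= microRange) mt = exp_rand() * tau;
            micro.push_back(mt);
          }
          tseg = segEnd;
          s = nextState;
        }
        state = s;
      } else if (dynamic && kOut[state] > 0) {
        // far from focus: propagate state by embedded-chain sampling
        double trem = dt;
        while (true) {
          double wt = exp_rand() / kOut[state];
          if (wt >= trem) break;
          trem -= wt;
          double u = unif_rand() * kOut[state], acc = 0.0;
          int ns = state;
          for (int i = 0; i < n; ++i) {
            if (i == state) continue;
            acc += K(i, state);
            if (u <= acc) { ns = i; break; }
          }
          state = ns;
          if (kOut[state] <= 0) break;
        }
      }
      // Brownian step with periodic wrap
      x += norm_rand() * sdStep;
      y += norm_rand() * sdStep;
      z += norm_rand() * sdStep;
      if (x > Lx / 2) x -= Lx; else if (x < -Lx / 2) x += Lx;
      if (y > Lx / 2) y -= Lx; else if (y < -Lx / 2) y += Lx;
      if (z > Lz / 2) z -= Lz; else if (z < -Lz / 2) z += Lz;
    }
  }
  // time-sort the pooled photons
  const int np = macro.size();
  std::vector<int> idx(np);
  for (int i = 0; i < np; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return macro[a] < macro[b]; });
  NumericVector outT(np), outM(np);
  IntegerVector outC(np);
  for (int i = 0; i < np; ++i) {
    outT[i] = macro[idx[i]];
    outC[i] = chan[idx[i]];
    outM[i] = micro[idx[i]];
  }
  return List::create(_["macro"] = outT, _["channel"] = outC,
                      _["micro"] = outM);
}

// Multi-tau correlator for weighted photon streams.
// Bins the two weight streams at binWidth (ms), correlates lags 1..m at the
// finest level, then repeatedly coarsens by 2 correlating lags m/2+1..m,
// with symmetric mean normalization per lag. Returns G(tc) on the
// quasi-logarithmic grid, G -> 1 for uncorrelated signals.
// [[Rcpp::export]]
List cpp_multitau(NumericVector t, NumericVector wa, NumericVector wb,
                  double binWidth, double duration, int m, double maxLag) {
  long nb = (long)std::ceil(duration / binWidth);
  if (nb < 4 * m) stop("stream too short for correlator settings");
  std::vector<double> A(nb, 0.0), B(nb, 0.0);
  const int np = t.size();
  for (int i = 0; i < np; ++i) {
    long b = (long)(t[i] / binWidth);
    if (b < 0) b = 0;
    if (b >= nb) b = nb - 1;
    A[b] += wa[i];
    B[b] += wb[i];
  }
  std::vector<double> lags, G;
  double width = binWidth;
  int level = 0;
  while (true) {
    long n = A.size();
    int k0 = (level == 0) ? 1 : m / 2 + 1;
    if (n < 2L * m + 2) break;
    bool done = false;
    for (int k = k0; k <= m; ++k) {
      double lag = k * width;
      if (lag > maxLag) { done = true; break; }
      long cnt = n - k;
      double sab = 0.0, sa = 0.0, sb = 0.0;
      for (long i = 0; i < cnt; ++i) {
        sab += A[i] * B[i + k];
        sa += A[i];
        sb += B[i + k];
      }
      if (sa <= 0 || sb <= 0) continue;
      lags.push_back(lag);
      G.push_back(sab * (double)cnt / (sa * sb));
    }
    if (done) break;
    // coarsen by factor 2
    long nh = n / 2;
    for (long i = 0; i < nh; ++i) {
      A[i] = A[2 * i] + A[2 * i + 1];
      B[i] = B[2 * i] + B[2 * i + 1];
    }
    A.resize(nh); B.resize(nh);
    width *= 2;
    ++level;
    if (width * (m / 2 + 1) > maxLag) break;
  }
  return List::create(_["lag"] = NumericVector(lags.begin(), lags.end()),
                      _["G"] = NumericVector(G.begin(), G.end()));
}

// Sliding-time-window burst flag: photon i is flagged when at least
// minNeighbors photons (including itself) fall inside the window of length
// win centered on it.
// [[Rcpp::export]]
LogicalVector cpp_burst_flag(NumericVector t, double win, int minNeighbors) {
  const int n = t.size();
  LogicalVector out(n);
  int lo = 0, hi = 0;
  for (int i = 0; i < n; ++i) {
    while (t[i] - t[lo] > win / 2) ++lo;
    while (hi < n - 1 && t[hi + 1] - t[i] <= win / 2) ++hi;
    out[i] = (hi - lo + 1) >= minNeighbors;
  }
  return out;
}
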