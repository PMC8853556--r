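#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Artificial-centering hit-and-run chain in null-space coordinates.
//
// The polytope is {t : A t <= b} (k-dimensional coordinates after the
// steady-state equalities have been eliminated). Directions are drawn as
// (random warmup point - running center), which adapts step geometry to
// the polytope's anisotropy (thin growth-yield slabs etc.). The running
// center is updated with every accepted state. Uses R's RNG, so set.seed
// on the R side makes chains reproducible.
//
// A: m x k, b: m, W: k x nw warmup points, t0: k start point.
// Returns k x nSamples matrix of states recorded every `thinning` steps
// after `burnin` initial steps.
// [[Rcpp::export(name = ".achrChain")]]
NumericMatrix achrChain(NumericMatrix A, NumericVector b, NumericMatrix W,
                        NumericVector t0, int nSamples, int thinning,
                        int burnin) {
    const int m = A.nrow(), k = A.ncol(), nw = W.ncol();
    const double dirTol = 1e-11;
    NumericMatrix out(k, nSamples);
    std::vector<double> t(t0.begin(), t0.end());
    std::vector<double> center(k, 0.0);
    for (int i = 0; i < nw; ++i)
        for (int j = 0; j < k; ++j) center[j] += W(j, i) / nw;
    double centerCount = nw;

    std::vector<double> d(k), slack(m);
    long totalSteps = (long)burnin + (long)nSamples * thinning;
    int recorded = 0, stepInThin = 0;
    bool warmedUp = false;
    long stepsDone = 0;

    while (recorded < nSamples) {
        // direction from a random warmup point through the center
        double norm = 0.0;
        for (int tries = 0; tries < 50 && norm < dirTol; ++tries) {
            int wi = (int)std::floor(R::runif(0.0, 1.0) * nw);
            if (wi >= nw) wi = nw - 1;
            norm = 0.0;
            for (int j = 0; j < k; ++j) {
                d[j] = W(j, wi) - center[j];
                norm += d[j] * d[j];
            }
            norm = std::sqrt(norm);
        }
        if (norm < dirTol) {
            // degenerate (point-like) polytope: record the current state
            for (int j = 0; j < k; ++j) out(j, recorded) = t[j];
            ++recorded;
            continue;
        }
        for (int j = 0; j < k; ++j) d[j] /= norm;

        double tmin = -std::numeric_limits<double>::infinity();
        double tmax = std::numeric_limits<double>::infinity();
        for (int i = 0; i < m; ++i) {
            double ad = 0.0, at = 0.0;
            for (int j = 0; j < k; ++j) {
                ad += A(i, j) * d[j];
                at += A(i, j) * t[j];
            }
            double s = b[i] - at;
            if (s < 0.0) s = 0.0;  // numerical guard on active faces
            if (ad > dirTol) {
                double u = s / ad;
                if (u < tmax) tmax = u;
            } else if (ad < -dirTol) {
                double u = -s / (-ad);
                if (u > tmin) tmin = u;
            }
        }
        if (!std::isfinite(tmin) || !std::isfinite(tmax) || tmax <= tmin) {
            // numerically empty segment: stay put this step
            tmin = 0.0; tmax = 0.0;
        }
        double u = (tmax > tmin) ? R::runif(tmin, tmax) : 0.0;
        for (int j = 0; j < k; ++j) t[j] += u * d[j];

        centerCount += 1.0;
        for (int j = 0; j < k; ++j)
            center[j] += (t[j] - center[j]) / centerCount;

        ++stepsDone;
        if (!warmedUp) {
            if (stepsDone >= burnin) { warmedUp = true; stepInThin = 0; }
            continue;
        }
        if (++stepInThin >= thinning) {
            for (int j = 0; j < k; ++j) out(j, recorded) = t[j];
            ++recorded;
            stepInThin = 0;
        }
        if (stepsDone > totalSteps + 1000) break;  // safety, unreachable
    }
    return out;
}
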