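#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Maximal-arc t statistic over a (circularized) series.
//
// Breakpoint positions i < j in [0, n] define the arc x[(i+1)..j] (1-based);
// the complement wraps around the circle.  The statistic is the two-sample
// pooled-variance t comparing the mean inside the arc against the mean
// outside.  Both pieces must hold at least min_width observations.  Ties are
// broken toward the lexicographically smallest (i, j) by strict improvement
// while scanning i ascending, then j ascending.
//
// Internally the scan maximizes c = u^2 * n / (k (n-k)) with
// u = S[j] - S[i] - k * mean, a strictly increasing transform of t for a
// fixed series multiset: t^2 = c (n-2) / (TSS - c) with TSS the total sum
// of squares about the mean.  TSS is invariant under permutation, so a
// permuted series exceeds the observed t as soon as any of its arcs
// reaches the observed c — which allows an early exit (c_stop) inside the
// permutation scans.
struct ScanResult {
    int i, j;
    double c_max;
};

static ScanResult arc_scan(const std::vector<double>& x,
                           const std::vector<double>& cinv,
                           double mean, int min_width,
                           double c_stop = R_PosInf) {
    const int n = static_cast<int>(x.size());
    ScanResult res = {-1, -1, -1.0};
    if (n < 2 * min_width) return res;

    std::vector<double> S(n + 1, 0.0);
    for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t] - mean;

    // Arcs with j = n are skipped: (i, n] is the complement of (0, i] and
    // describes the same circular split, so enumerating it would leave the
    // lexicographic tie-break between exact-duplicate arcs to floating-point
    // noise.
    const int k_lo = min_width, k_hi = n - min_width;
    for (int i = 0; i <= n - 1 - k_lo; ++i) {
        const double Si = S[i];
        const int j_hi = std::min(n - 1, i + k_hi);
        for (int j = i + k_lo; j <= j_hi; ++j) {
            const double u = S[j] - Si;
            const double c = u * u * cinv[j - i];
            if (c > res.c_max) {
                res.c_max = c;
                res.i = i;
                res.j = j;
                if (c >= c_stop) return res;
            }
        }
    }
    return res;
}

static void make_cinv(int n, std::vector<double>& cinv) {
    cinv.assign(n + 1, 0.0);
    for (int k = 1; k < n; ++k)
        cinv[k] = static_cast<double>(n) /
            (static_cast<double>(k) * (n - k));
}

// c -> t on the original scale; guards the degenerate sp2 = 0 case.
static double c_to_t(double c, double tss, int n) {
    if (n <= 2) return 0.0;
    double resid = tss - c;
    if (resid < 1e-12 * tss) resid = 1e-12 * tss;  // near-perfect split
    if (resid <= 0.0) return 0.0;
    return std::sqrt(c * (n - 2.0) / resid);
}

// [[Rcpp::export(name = ".cbs_arc_scan")]]
List cbs_arc_scan_cpp(NumericVector x, int min_width) {
    const int n = x.size();
    std::vector<double> xv(x.begin(), x.end()), cinv;
    make_cinv(n, cinv);
    double mean = 0.0, tss = 0.0;
    for (double v : xv) mean += v;
    mean /= n;
    for (double v : xv) tss += (v - mean) * (v - mean);
    if (tss <= 0.0)  // constant series: no informative arc
        return List::create(_["i"] = -1, _["j"] = -1, _["t_max"] = 0.0);
    ScanResult res = arc_scan(xv, cinv, mean, min_width);
    double t_max = res.i < 0 ? 0.0 : c_to_t(res.c_max, tss, n);
    return List::create(_["i"] = res.i, _["j"] = res.j,
                        _["t_max"] = t_max);
}

// Permutation significance of the best split, with two-sided sequential
// early stopping:
//   * early acceptance when no permutation statistic has reached the
//     observed maximum after ceil(early_mult/alpha) permutations (the
//     exact p is then bounded well below alpha);
//   * early rejection when the exceedance count makes p >= alpha certain,
//     or when a normal lower confidence bound on p clears alpha.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".cbs_split_test")]]
List cbs_split_test_cpp(NumericVector x, int min_width, double alpha,
                        int nperm, double early_mult) {
    const int n = x.size();
    std::vector<double> xv(x.begin(), x.end()), cinv;
    make_cinv(n, cinv);
    double mean = 0.0, tss = 0.0;
    for (double v : xv) mean += v;
    mean /= n;
    for (double v : xv) tss += (v - mean) * (v - mean);
    if (tss <= 0.0)
        return List::create(_["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                            _["t_max"] = 0.0, _["p"] = 1.0,
                            _["nperm_used"] = 0);
    ScanResult obs = arc_scan(xv, cinv, mean, min_width);
    if (obs.i < 0)
        return List::create(_["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                            _["t_max"] = 0.0, _["p"] = 1.0,
                            _["nperm_used"] = 0);
    const double t_obs = c_to_t(obs.c_max, tss, n);

    RNGScope scope;
    const int k_stop = static_cast<int>(std::ceil(alpha * nperm));
    const int m_accept = static_cast<int>(
        std::min(static_cast<double>(nperm), std::ceil(early_mult / alpha)));
    std::vector<double> y(xv);
    int exceed = 0, m_done = 0;
    for (int m = 1; m <= nperm; ++m) {
        for (int t = n - 1; t > 0; --t) {
            int u = static_cast<int>(unif_rand() * (t + 1));
            if (u > t) u = t;
            std::swap(y[t], y[u]);
        }
        ScanResult perm = arc_scan(y, cinv, mean, min_width, obs.c_max);
        if (perm.i >= 0 && perm.c_max >= obs.c_max) ++exceed;
        m_done = m;
        if (exceed >= k_stop) break;
        if (exceed == 0 && m >= m_accept) break;
        if (exceed >= 10) {
            const double lower =
                (exceed - 2.576 * std::sqrt(static_cast<double>(exceed))) / m;
            if (lower >= alpha) break;
        }
    }
    const double p = (exceed + 1.0) / (m_done + 1.0);
    return List::create(_["i"] = obs.i, _["j"] = obs.j,
                        _["t_max"] = t_obs, _["p"] = p,
                        _["nperm_used"] = m_done);
}
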