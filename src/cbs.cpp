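#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Max arc-vs-complement mean-shift statistic over arcs (i, j] of a region
// of length n (0 <= i < j <= n), returned as the squared t statistic.
// Constraints keep every resulting segment at least min_width windows wide
// (the arc, and each nonempty flank). For fixed arc length k the statistic
// is |S[j] - S[i] - k*mu| * sqrt(n / (k (n-k))) / sigma, so the scan
// tracks the extreme arc sums per k and applies the scale once.
//
// When `track` is false the caller only needs to know whether the maximum
// reaches `stop_at`; the scan then returns early on the first k whose best
// arc exceeds it.
static double max_arc_stat2(const std::vector<double>& S, int n, double var,
                            int min_width, bool track, double stop_at,
                            int* bi, int* bj) {
    const double mu = S[n] / n;
    double best = -1.0;
    for (int k = min_width; k <= n - min_width; ++k) {
        const double scale = (double)n / ((double)k * (n - k)) / var;
        double best_d2 = -1.0;
        int best_i = -1;
        for (int i = 0; i + k <= n; ++i) {
            if (i > 0 && i < min_width) { i = min_width - 1; continue; }
            const int j = i + k;
            if (j < n && j > n - min_width) {
                // jump to the arc ending exactly at n, if it exists
                if (n - k > i) { i = n - k - 1; continue; }
                break;
            }
            const double d = S[j] - S[i] - k * mu;
            const double d2 = d * d;
            if (d2 > best_d2) { best_d2 = d2; best_i = i; }
        }
        if (best_d2 < 0) continue;
        const double t2 = best_d2 * scale;
        if (t2 > best) {
            best = t2;
            if (track) { *bi = best_i; *bj = best_i + k; }
        }
        if (!track && best >= stop_at) return best;
    }
    return best;
}

static void partial_sums(const std::vector<double>& x, std::vector<double>& S) {
    const int n = (int)x.size();
    S.assign(n + 1, 0.0);
    for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
}

// One circular-binary-segmentation split test on a region.
// Returns the best arc boundaries (0-based region offsets i < j, arc =
// windows i+1..j), the observed statistic, and a permutation p-value with
// early stopping: once `k_stop` permuted maxima reach the observed
// statistic the split can no longer be significant at the caller's alpha
// and permutation stops. Uses R's RNG, so results are reproducible under
// set.seed().
// [[Rcpp::export]]
List cbs_split_test(NumericVector x, int min_width, int n_perm, double alpha) {
    const int n = x.size();
    std::vector<double> v(x.begin(), x.end());

    double mean = 0.0;
    for (double xi : v) mean += xi;
    mean /= n;
    double ss = 0.0;
    for (double xi : v) ss += (xi - mean) * (xi - mean);
    const double var = ss / std::max(1, n - 1);

    if (n < 2 * min_width || var < 1e-24) {
        return List::create(_["significant"] = false, _["i"] = 0, _["j"] = 0,
                            _["stat"] = 0.0, _["p"] = 1.0, _["n_perm"] = 0);
    }

    std::vector<double> S;
    partial_sums(v, S);
    int bi = 0, bj = 0;
    const double obs2 = max_arc_stat2(S, n, var, min_width, true,
                                      R_PosInf, &bi, &bj);
    if (obs2 < 0) {
        return List::create(_["significant"] = false, _["i"] = 0, _["j"] = 0,
                            _["stat"] = 0.0, _["p"] = 1.0, _["n_perm"] = 0);
    }

    const double thresh = obs2 * (1.0 - 1e-12);
    const int k_stop = (int)std::ceil(alpha * n_perm);
    int count = 0, done = 0;
    std::vector<double> perm(v);
    RNGScope scope;
    for (int p = 0; p < n_perm; ++p) {
        // Fisher-Yates shuffle driven by R's RNG
        for (int i = n - 1; i > 0; --i) {
            int j = (int)std::floor(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(perm[i], perm[j]);
        }
        partial_sums(perm, S);
        const double m2 = max_arc_stat2(S, n, var, min_width, false,
                                        thresh, nullptr, nullptr);
        ++done;
        if (m2 >= thresh) {
            ++count;
            if (count >= k_stop) break; // cannot reach significance
        }
    }
    const double pval = (double)count / (double)done;
    const bool sig = (done == n_perm) && (pval < alpha);
    return List::create(_["significant"] = sig, _["i"] = bi, _["j"] = bj,
                        _["stat"] = std::sqrt(obs2), _["p"] = pval,
                        _["n_perm"] = done);
}
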