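#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Symmetrically normalized fluctuation correlation of two co-binned series at
// a binned lag j: G = <A_head B_tail> / (<A_head><B_tail>) - 1, with
// head = bins [0, nb-j) of A and tail = bins [j, nb) of B.
static double corr_at_lag(const std::vector<double> &a,
                          const std::vector<double> &b, int j)
{
    const int nb = (int) a.size();
    const int m = nb - j;
    long double sab = 0.0L, sa = 0.0L, sb = 0.0L;
    for (int t = 0; t < m; ++t) {
        sab += (long double) a[t] * (long double) b[t + j];
        sa  += a[t];
        sb  += b[t + j];
    }
    const long double ma = sa / m, mb = sb / m;
    if (ma == 0.0L || mb == 0.0L)
        stop("correlation normalization undefined: window mean is zero");
    return (double) ((sab / m) / (ma * mb) - 1.0L);
}

// Multi-tau correlator: 32 unit-spaced lags at full resolution, then 16 lags
// per octave with progressive factor-2 co-binning of both channels.
// Returns lag (in lines), the binning factor, and G at each lag.
// [[Rcpp::export]]
List cpp_multitau(NumericVector av, NumericVector bv, int max_level)
{
    std::vector<double> a(av.begin(), av.end());
    std::vector<double> b(bv.begin(), bv.end());

    std::vector<int> lag_lines, bin_factor, n_pairs;
    std::vector<double> values;

    int bin = 1;
    for (int level = 0; level <= max_level; ++level) {
        const int j_lo = (level == 0) ? 1 : 17;
        for (int j = j_lo; j <= 32; ++j) {
            values.push_back(corr_at_lag(a, b, j));
            lag_lines.push_back(j * bin);
            bin_factor.push_back(bin);
            n_pairs.push_back((int) a.size() - j);
        }
        if (level == max_level) break;
        // co-bin both channels by 2 (pairwise means; odd trailing sample dropped)
        const int nb = (int) a.size() / 2;
        for (int t = 0; t < nb; ++t) {
            a[t] = 0.5 * (a[2 * t] + a[2 * t + 1]);
            b[t] = 0.5 * (b[2 * t] + b[2 * t + 1]);
        }
        a.resize(nb);
        b.resize(nb);
        bin *= 2;
    }
    return List::create(_["lag_lines"] = wrap(lag_lines),
                        _["bin"] = wrap(bin_factor),
                        _["value"] = wrap(values),
                        _["n_pairs"] = wrap(n_pairs));
}
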