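#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <unordered_set>
#include <utility>
#include <vector>

using namespace Rcpp;

// Centered statistic of a multinomial state (n1, n2, n3, m - n1 - n2 - n3),
// re-centered with that state's own plug-in occurrence probabilities
// p~_i = (n1 + n2)/m and p~_j = (n1 + n3)/m.  An empty-union state (n1 =
// n2 = n3 = 0) is assigned statistic 0: the empty-union coefficient is
// defined to equal its expectation, so its centered value vanishes.  This
// single function backs both the exact-test region sum and the measure
// concentration lower bound, so the subset inequality between the two
// holds up to summation rounding only.
static inline double state_stat(int n1, int n2, int n3, int m) {
    const int u = n1 + n2 + n3;
    if (u == 0) return 0.0;
    const double pi = static_cast<double>(n1 + n2) / m;
    const double pj = static_cast<double>(n1 + n3) / m;
    const double den = pi + pj - pi * pj; // > 0 whenever u > 0
    const double e = pi * pj / den;
    return std::fabs(static_cast<double>(n1) / u - e);
}

// Log-pmf evaluator for Multinomial(m; q1, q2, q3, q4) with a cached
// lgamma table.  Cells with q = 0 force pmf 0 for any state occupying
// them (returned as -Inf).
struct MultinomPmf {
    int m;
    std::vector<double> lgf;
    double lq[4];
    bool zerocell[4];

    MultinomPmf(int m_, const NumericVector& q) : m(m_), lgf(m_ + 1) {
        for (int k = 0; k <= m; ++k) lgf[k] = std::lgamma(k + 1.0);
        for (int c = 0; c < 4; ++c) {
            zerocell[c] = (q[c] <= 0.0);
            lq[c] = zerocell[c] ? R_NegInf : std::log(q[c]);
        }
    }

    double logp(int n1, int n2, int n3) const {
        const int n[4] = { n1, n2, n3, m - n1 - n2 - n3 };
        double lp = lgf[m];
        for (int c = 0; c < 4; ++c) {
            if (n[c] > 0) {
                if (zerocell[c]) return R_NegInf;
                lp += n[c] * lq[c] - lgf[n[c]];
            }
        }
        return lp;
    }
};

// Exact p-value with the estimated-probability critical region: sum the
// multinomial pmf (cell probabilities from the observed data's plug-in
// p-hats) over all states whose own re-centered statistic is >= t_abs,
// with an absolute floating guard so exact ties are never dropped.
// Returns the region mass and the total mass (the latter ~ 1, used as a
// numerical self-check).
// [[Rcpp::export]]
List exact_region_core(int m, NumericVector cell_probs, double t_abs,
                       double guard) {
    const MultinomPmf pmf(m, cell_probs);
    const double thr = t_abs - guard;
    long double pval = 0.0L, total = 0.0L;
    for (int n1 = 0; n1 <= m; ++n1) {
        for (int n2 = 0; n1 + n2 <= m; ++n2) {
            for (int n3 = 0; n1 + n2 + n3 <= m; ++n3) {
                const double lp = pmf.logp(n1, n2, n3);
                if (lp == R_NegInf) continue;
                const double pr = std::exp(lp);
                total += pr;
                if (state_stat(n1, n2, n3, m) >= thr) pval += pr;
            }
        }
    }
    return List::create(_["pvalue"] = static_cast<double>(pval),
                        _["total"] = static_cast<double>(total));
}

// Exact p-value with known occurrence probabilities: the region statistic
// uses the fixed expectation (empty-union states have statistic 0 because
// the coefficient's fallback value equals that expectation).
// [[Rcpp::export]]
List exact_region_known_core(int m, NumericVector cell_probs,
                             double expectation, double t_abs,
                             double guard) {
    const MultinomPmf pmf(m, cell_probs);
    const double thr = t_abs - guard;
    long double pval = 0.0L, total = 0.0L;
    for (int n1 = 0; n1 <= m; ++n1) {
        for (int n2 = 0; n1 + n2 <= m; ++n2) {
            for (int n3 = 0; n1 + n2 + n3 <= m; ++n3) {
                const double lp = pmf.logp(n1, n2, n3);
                if (lp == R_NegInf) continue;
                const double pr = std::exp(lp);
                total += pr;
                const int u = n1 + n2 + n3;
                const double st =
                    (u == 0) ? 0.0
                             : std::fabs(static_cast<double>(n1) / u -
                                         expectation);
                if (st >= thr) pval += pr;
            }
        }
    }
    return List::create(_["pvalue"] = static_cast<double>(pval),
                        _["total"] = static_cast<double>(total));
}

// Mode of Multinomial(m; q) by hill climbing: start from the
// componentwise-rounded mean (repaired to sum m through the largest
// cell), then repeatedly move one unit between cells while the pmf
// increases.  Unimodality of the multinomial over this neighbor graph
// makes the local maximum global.
// [[Rcpp::export]]
IntegerVector multinomial_mode_core(int m, NumericVector q) {
    int n[4];
    long sum = 0;
    for (int c = 0; c < 4; ++c) {
        double r = std::round(m * q[c]);
        n[c] = static_cast<int>(std::max(0.0, std::min(r, (double)m)));
        sum += n[c];
    }
    int largest = 0;
    for (int c = 1; c < 4; ++c)
        if (q[c] > q[largest]) largest = c;
    n[largest] += static_cast<int>(m - sum);
    while (n[largest] < 0) { // pathological rounding; repair from max cell
        int mx = 0;
        for (int c = 1; c < 4; ++c)
            if (n[c] > n[mx]) mx = c;
        n[mx] += n[largest];
        n[largest] = 0;
        largest = mx;
    }

    const MultinomPmf pmf(m, q);
    double cur = pmf.logp(n[0], n[1], n[2]);
    bool improved = true;
    while (improved) {
        improved = false;
        int bi = -1, bj = -1;
        double best = cur;
        for (int i = 0; i < 4; ++i) {
            if (n[i] == 0) continue;
            for (int j = 0; j < 4; ++j) {
                if (j == i) continue;
                --n[i];
                ++n[j];
                const double lp = pmf.logp(n[0], n[1], n[2]);
                if (lp > best) {
                    best = lp;
                    bi = i;
                    bj = j;
                }
                ++n[i];
                --n[j];
            }
        }
        if (bi >= 0) {
            --n[bi];
            ++n[bj];
            cur = best;
            improved = true;
        }
    }
    return IntegerVector::create(n[0], n[1], n[2], n[3]);
}

// Visited-state marker: a bit-packed cube over (n1, n2, n3) when it fits
// in memory (O(1) lookups, the hot path of the expansion), otherwise an
// unordered hash set keyed by the packed state index.
struct SeenSet {
    bool use_bitmap;
    long long M1;
    std::vector<uint64_t> bits;
    std::unordered_set<long long> hash;

    explicit SeenSet(int m) : M1(m + 1) {
        const long long cube = M1 * M1 * M1;
        use_bitmap = cube <= (1LL << 31);
        if (use_bitmap) bits.assign((cube + 63) >> 6, 0ULL);
    }
    // returns true if newly inserted
    bool insert(long long k) {
        if (use_bitmap) {
            uint64_t& w = bits[k >> 6];
            const uint64_t b = 1ULL << (k & 63);
            if (w & b) return false;
            w |= b;
            return true;
        }
        return hash.insert(k).second;
    }
};

// Measure concentration algorithm.  Starting from the mode, expand
// best-first by pmf (priority queue over the frontier; a state enters the
// frontier when it is first seen as a neighbor of an accepted state)
// until the accumulated mass of the accepted set I_eps reaches 1 - eps or
// the reachable simplex is exhausted.  While accepting states, also
// accumulate the mass of those falling in the critical region (statistic
// >= t_abs - guard): that sum is the lower p-value bound p^L.
// Zero-probability states (a zero-probability cell occupied) are marked
// seen but never enqueued; positive-pmf states remain mutually reachable.
// [[Rcpp::export]]
List mca_core(int m, NumericVector q, double t_abs, double eps,
              double guard, bool keep_states = false) {
    const MultinomPmf pmf(m, q);
    const double thr = t_abs - guard;
    const long long M1 = m + 1;
    std::priority_queue<std::pair<double, long long> > frontier;
    SeenSet seen(m);

    IntegerVector mode = multinomial_mode_core(m, q);
    const long long k0 =
        ((long long)mode[0] * M1 + mode[1]) * M1 + mode[2];
    frontier.push(std::make_pair(pmf.logp(mode[0], mode[1], mode[2]), k0));
    seen.insert(k0);

    long double mass = 0.0L, pl = 0.0L;
    const double target = 1.0 - eps;
    R_xlen_t count = 0;
    std::vector<long long> kept;

    while (!frontier.empty() && static_cast<double>(mass) < target) {
        const std::pair<double, long long> top = frontier.top();
        frontier.pop();
        const long long k = top.second;
        const int n1 = static_cast<int>(k / (M1 * M1));
        const int n2 = static_cast<int>((k / M1) % M1);
        const int n3 = static_cast<int>(k % M1);
        const double pr = std::exp(top.first);
        mass += pr;
        ++count;
        if (state_stat(n1, n2, n3, m) >= thr) pl += pr;
        if (keep_states) kept.push_back(k);

        int n[4] = { n1, n2, n3, m - n1 - n2 - n3 };
        for (int i = 0; i < 4; ++i) {
            if (n[i] == 0) continue;
            for (int j = 0; j < 4; ++j) {
                if (j == i) continue;
                --n[i];
                ++n[j];
                const long long kk =
                    ((long long)n[0] * M1 + n[1]) * M1 + n[2];
                if (seen.insert(kk)) {
                    const double lp = pmf.logp(n[0], n[1], n[2]);
                    if (lp != R_NegInf)
                        frontier.push(std::make_pair(lp, kk));
                }
                ++n[i];
                --n[j];
            }
        }
    }

    List out = List::create(_["p_lower"] = static_cast<double>(pl),
                            _["mass"] = static_cast<double>(mass),
                            _["n_states"] = static_cast<double>(count),
                            _["mode"] = mode);
    if (keep_states) {
        IntegerMatrix st(kept.size(), 4);
        for (R_xlen_t r = 0; r < (R_xlen_t)kept.size(); ++r) {
            const long long k = kept[r];
            st(r, 0) = static_cast<int>(k / (M1 * M1));
            st(r, 1) = static_cast<int>((k / M1) % M1);
            st(r, 2) = static_cast<int>(k % M1);
            st(r, 3) = m - st(r, 0) - st(r, 1) - st(r, 2);
        }
        out["states"] = st;
    }
    return out;
}

// Per-state re-centered statistics for a matrix of states; exposed so the
// R-level enumeration and the brute-force test oracles share the exact
// floating-point path used inside the region sums.
// [[Rcpp::export]]
NumericVector state_statistics_core(IntegerMatrix states, int m) {
    const R_xlen_t n = states.nrow();
    NumericVector out(n);
    for (R_xlen_t r = 0; r < n; ++r)
        out[r] = state_stat(states(r, 0), states(r, 1), states(r, 2), m);
    return out;
}
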