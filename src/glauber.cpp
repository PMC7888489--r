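#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Adjacency-list view of a dense coupling matrix; zero entries are skipped so
// sparse graphs (lattices, thresholded connectomes) cost O(edges) per sweep.
struct AdjList {
    std::vector<std::vector<int> > nbr;
    std::vector<std::vector<double> > wgt;
    explicit AdjList(const NumericMatrix& J) {
        int n = J.nrow();
        nbr.resize(n);
        wgt.resize(n);
        for (int i = 0; i < n; ++i) {
            for (int j = 0; j < n; ++j) {
                double v = J(i, j);
                if (v != 0.0 && i != j) {
                    nbr[i].push_back(j);
                    wgt[i].push_back(v);
                }
            }
        }
    }
};

static inline double local_field(const AdjList& A, const std::vector<int>& s, int i) {
    double h = 0.0;
    const std::vector<int>& nb = A.nbr[i];
    const std::vector<double>& w = A.wgt[i];
    for (size_t k = 0; k < nb.size(); ++k) h += w[k] * s[nb[k]];
    return h;
}

// One Glauber sweep: every spin visited exactly once, in a fresh random
// permutation, flipping with probability 1/(1+exp(beta*dE)) against the
// current (sequentially updated) configuration.  Returns flips performed.
static int sweep_inplace(const AdjList& A, std::vector<int>& s, double beta,
                         std::vector<int>& order) {
    int n = (int) s.size();
    for (int i = 0; i < n; ++i) order[i] = i;
    // Fisher-Yates with R's RNG so set.seed() governs reproducibility
    for (int i = n - 1; i > 0; --i) {
        int j = (int) std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
    }
    int flips = 0;
    for (int k = 0; k < n; ++k) {
        int i = order[k];
        double dE = 2.0 * s[i] * local_field(A, s, i);
        double p = 1.0 / (1.0 + std::exp(beta * dE));
        if (unif_rand() < p) {
            s[i] = -s[i];
            ++flips;
        }
    }
    return flips;
}

// [[Rcpp::export]]
IntegerVector glauber_sweep_cpp(NumericMatrix J, double beta, IntegerVector state) {
    int n = J.nrow();
    AdjList A(J);
    std::vector<int> s(state.begin(), state.end());
    std::vector<int> order(n);
    sweep_inplace(A, s, beta, order);
    return wrap(s);
}

// Run `discard` unrecorded sweeps then `collect` recorded sweeps at fixed beta.
// Returns the T x N sample matrix (one row per sweep), the final state, and the
// per-spin flip count accumulated over the collection phase.
// [[Rcpp::export]]
List glauber_run_cpp(NumericMatrix J, double beta, IntegerVector state,
                     int discard, int collect, bool record = true) {
    int n = J.nrow();
    AdjList A(J);
    std::vector<int> s(state.begin(), state.end());
    std::vector<int> order(n);
    for (int t = 0; t < discard; ++t) sweep_inplace(A, s, beta, order);
    IntegerMatrix samples(record ? collect : 0, n);
    IntegerVector flip_count(n);
    std::vector<int> prev(s);
    for (int t = 0; t < collect; ++t) {
        sweep_inplace(A, s, beta, order);
        if (record) {
            for (int i = 0; i < n; ++i) samples(t, i) = s[i];
        }
        for (int i = 0; i < n; ++i) {
            if (s[i] != prev[i]) ++flip_count[i];
            prev[i] = s[i];
        }
    }
    return List::create(_["samples"] = samples,
                        _["final"] = wrap(s),
                        _["flip_count"] = flip_count);
}
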